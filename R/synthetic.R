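# Synthetic paired miRNA/mRNA cohorts with the statistical structure the
# analyses assume: subtype labels, replicate hybridizations with detection
# dropout, planted class-differential miRNAs, latent-factor co-expression
# modules coupled to designated pivot miRNAs, and planted miRNA-target
# anti-correlation, plus a ground-truth manifest for recovery scoring.
#
# Model: log2 intensities x = baseline_f + class effects + latent-factor
# contributions + N(0, noise_sd) biological noise per sample; each replicate
# array adds independent N(0, tech_sd) measurement noise and is exported on
# the linear scale (2^x).  mRNA profiles are emitted per biological sample on
# the log2 scale (the pipeline accepts already-normalized mRNA matrices).

#' Configuration for a synthetic cohort
#'
#' @param n_samples Number of biological samples (default 100).
#' @param n_mirna Number of miRNA features (default 300).
#' @param n_mrna Number of mRNA genes (default 3000).
#' @param subtype_props Named proportions over the intrinsic subtypes
#'   (must sum to 1); sample counts are assigned by largest-remainder
#'   rounding, then shuffled.
#' @param prolif_props Named proportions for proliferation classes
#'   \code{HP}, \code{LP}, \code{unassigned}.
#' @param replicates Replicate hybridizations per sample (default 2).
#' @param baseline_log2_mean,baseline_log2_sd Per-feature baseline log2
#'   intensity distribution (defaults 8 and 1.5).
#' @param noise_sd Per-sample biological SD on the log2 scale (default 1);
#'   planted effect sizes are expressed in units of this SD.
#' @param tech_sd Replicate measurement SD on the log2 scale (default 0.5).
#' @param de Planted differential-expression spec:
#'   \code{list(n_features, effect_sd, direction, on, group_a, group_b)}
#'   with \code{direction} one of \code{"up"}, \code{"down"}, \code{"both"}
#'   and \code{on} one of \code{"subtype"}, \code{"proliferation"}; or
#'   \code{NULL} for none.
#' @param modules List of co-expression module specs:
#'   \code{list(name, n_genes, loading, pivots, signs, class_effect)} where
#'   \code{pivots} are miRNA indices loading on the module's latent factor
#'   with the given signs, and \code{class_effect} shifts the factor mean by
#'   +/- class_effect/2 between the HP and LP classes (0 = uncoupled).
#' @param targets Planted target-regulation spec:
#'   \code{list(pivot, n_targets, rho)}; target genes are coupled to the
#'   pivot miRNA's expression so their correlation is approximately
#'   \code{-rho}; or \code{NULL}.
#' @param dropout List \code{(midpoint, slope)}: a replicate measurement of
#'   log2 intensity x is called absent with probability
#'   \code{plogis((midpoint - x)/slope)}, so detection increases with
#'   intensity.
#' @param seed Integer seed governing all draws.
#' @return A validated \code{cohort_config} list.
#' @export
cohort_config <- function(n_samples = 100L, n_mirna = 300L, n_mrna = 3000L,
                          subtype_props = c("basal-like" = 0.15,
                                            "luminal-A" = 0.40,
                                            "luminal-B" = 0.15,
                                            "ERBB2-enriched" = 0.11,
                                            "normal-like" = 0.12,
                                            "unclassified" = 0.07),
                          prolif_props = c(HP = 0.25, LP = 0.35,
                                           unassigned = 0.40),
                          replicates = 2L,
                          baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                          noise_sd = 1, tech_sd = 0.5,
                          de = NULL, modules = list(), targets = NULL,
                          dropout = list(midpoint = 4, slope = 1),
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna), subtype_props = subtype_props,
              prolif_props = prolif_props, replicates = as.integer(replicates),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
              tech_sd = tech_sd, de = de, modules = modules, targets = targets,
              dropout = dropout, seed = as.integer(seed))
  problems <- character(0)
  if (cfg$n_samples < 2L) problems <- c(problems, "n_samples must be >= 2")
  if (cfg$n_mirna < 1L) problems <- c(problems, "n_mirna must be positive")
  if (cfg$n_mrna < 1L) problems <- c(problems, "n_mrna must be positive")
  if (cfg$replicates < 1L) problems <- c(problems, "replicates must be positive")
  if (abs(sum(subtype_props) - 1) > 1e-8)
    problems <- c(problems, "subtype_props must sum to 1")
  if (abs(sum(prolif_props) - 1) > 1e-8)
    problems <- c(problems, "prolif_props must sum to 1")
  if (cfg$noise_sd <= 0) problems <- c(problems, "noise_sd must be positive")
  if (cfg$tech_sd < 0) problems <- c(problems, "tech_sd must be non-negative")
  mid_p <- stats::plogis((dropout$midpoint - cfg$baseline_log2_mean) /
                           dropout$slope)
  if (!is.finite(mid_p) || mid_p < 0 || mid_p > 1)
    problems <- c(problems, "dropout probability must lie in [0, 1]")
  if (!is.null(de)) {
    if (is.null(de$n_features) || de$n_features < 1L ||
        de$n_features > cfg$n_mirna)
      problems <- c(problems, "de$n_features must lie in [1, n_mirna]")
    if (is.null(de$effect_sd) || de$effect_sd < 0)
      problems <- c(problems, "de$effect_sd must be non-negative")
  }
  for (mod in modules) {
    if (is.null(mod$name) || is.null(mod$n_genes) || is.null(mod$loading))
      problems <- c(problems, "module specs need name, n_genes, loading")
    else if (mod$n_genes > cfg$n_mrna)
      problems <- c(problems, paste0("module '", mod$name,
                                     "' larger than the mRNA universe"))
  }
  if (!is.null(targets) && (is.null(targets$n_targets) ||
                            targets$n_targets > cfg$n_mrna))
    problems <- c(problems, "targets$n_targets must lie in [1, n_mrna]")
  if (length(problems))
    stop("invalid cohort config:\n  - ", paste(problems, collapse = "\n  - "))
  class(cfg) <- "cohort_config"
  cfg
}

# largest-remainder apportionment of n among proportions
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(-(raw - base))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic paired miRNA/mRNA cohort
#'
#' Draws a cohort under the configured model.  miRNA intensities are emitted
#' per replicate array on the linear scale with present/absent detection
#' calls; mRNA profiles are emitted per biological sample on the log2 scale.
#' The same seed always yields bit-identical output.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A list with elements \code{mirna} (linear-scale
#'   \code{ExpressionMatrix}, one column per replicate array, with
#'   detection), \code{mrna} (log2-scale \code{ExpressionMatrix}, one column
#'   per sample), \code{annotations} (a \code{sample_annotation} data.frame,
#'   one row per replicate array) and \code{truth} (a
#'   \code{synthetic_truth} manifest).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  nS <- config$n_samples; nMi <- config$n_mirna; nG <- config$n_mrna
  sample_ids <- sprintf("S%03d", seq_len(nS))
  mirna_ids <- sprintf("miR-%03d", seq_len(nMi))
  mrna_ids <- sprintf("gene%05d", seq_len(nG))

  subtype <- sample(rep(names(config$subtype_props),
                        apportion(config$subtype_props, nS)))
  prolif <- sample(rep(names(config$prolif_props),
                       apportion(config$prolif_props, nS)))
  ki67 <- mi_cat <- character(nS)
  hp_pairs <- list(c("high", "high"), c("high", "moderate"),
                   c("moderate", "high"))
  lp_pairs <- list(c("negative", "low"), c("negative", "moderate"),
                   c("moderate", "low"))
  un_pairs <- list(c("moderate", "moderate"), c("high", "low"),
                   c("negative", "high"))
  for (s in seq_len(nS)) {
    pool <- switch(prolif[s], HP = hp_pairs, LP = lp_pairs, un_pairs)
    pair <- pool[[sample.int(length(pool), 1L)]]
    ki67[s] <- pair[1L]; mi_cat[s] <- pair[2L]
  }
  p_erneg <- c("basal-like" = 0.9, "luminal-A" = 0.1, "luminal-B" = 0.2,
               "ERBB2-enriched" = 0.5, "normal-like" = 0.3,
               "unclassified" = 0.4)
  er <- ifelse(stats::runif(nS) < p_erneg[subtype], "negative", "positive")
  p_mut <- c("basal-like" = 0.8, "luminal-A" = 0.15, "luminal-B" = 0.3,
             "ERBB2-enriched" = 0.7, "normal-like" = 0.2,
             "unclassified" = 0.4)
  tp53 <- ifelse(stats::runif(nS) < p_mut[subtype], "mutant", "WT")
  ecm <- sample(paste0("ECM", 1:4), nS, replace = TRUE)

  # biological log2 signal: baseline + noise
  base_mi <- stats::rnorm(nMi, config$baseline_log2_mean,
                          config$baseline_log2_sd)
  sig_mi <- matrix(base_mi, nMi, nS) +
    matrix(stats::rnorm(nMi * nS, 0, config$noise_sd), nMi, nS)
  base_g <- stats::rnorm(nG, config$baseline_log2_mean,
                         config$baseline_log2_sd)
  sig_g <- matrix(base_g, nG, nS) +
    matrix(stats::rnorm(nG * nS, 0, config$noise_sd), nG, nS)

  group_of <- function(on) switch(on, subtype = subtype,
                                  proliferation = prolif,
                                  stop("unknown contrast column '", on, "'"))
  de_truth <- NULL
  if (!is.null(config$de)) {
    de <- config$de
    dirn <- de$direction %||% "both"
    feats <- sample.int(nMi, de$n_features)
    dirs <- switch(dirn,
                   up = rep("up", de$n_features),
                   down = rep("down", de$n_features),
                   both = rep_len(c("up", "down"), de$n_features))
    in_a <- group_of(de$on %||% "subtype") == de$group_a
    eff <- de$effect_sd * config$noise_sd
    for (i in seq_along(feats)) {
      delta <- if (dirs[i] == "up") eff else -eff
      sig_mi[feats[i], in_a] <- sig_mi[feats[i], in_a] + delta
    }
    de_truth <- data.frame(feature_id = mirna_ids[feats],
                           on = de$on %||% "subtype",
                           group_a = de$group_a, group_b = de$group_b,
                           effect_sd = de$effect_sd, direction = dirs,
                           stringsAsFactors = FALSE)
  }

  modules_truth <- list(); couplings <- NULL
  used_genes <- integer(0)
  prolif_sign <- ifelse(prolif == "HP", 1, ifelse(prolif == "LP", -1, 0))
  for (mod in config$modules) {
    ce <- mod$class_effect %||% 0
    z <- 0.5 * ce * prolif_sign + stats::rnorm(nS)
    gidx <- sample(setdiff(seq_len(nG), used_genes), mod$n_genes)
    used_genes <- c(used_genes, gidx)
    sig_g[gidx, ] <- sig_g[gidx, ] + mod$loading *
      matrix(z, mod$n_genes, nS, byrow = TRUE)
    signs <- mod$signs %||% rep(1, length(mod$pivots))
    for (j in seq_along(mod$pivots)) {
      pidx <- mod$pivots[j]
      sig_mi[pidx, ] <- sig_mi[pidx, ] + signs[j] * mod$loading * z
    }
    modules_truth[[mod$name]] <- mrna_ids[sort(gidx)]
    couplings <- rbind(couplings, data.frame(
      module = mod$name, pivot_id = mirna_ids[mod$pivots],
      sign = signs, loading = mod$loading, class_effect = ce,
      stringsAsFactors = FALSE))
  }

  targets_truth <- NULL
  if (!is.null(config$targets)) {
    tg <- config$targets
    pidx <- if (is.character(tg$pivot)) match(tg$pivot, mirna_ids)
            else as.integer(tg$pivot)
    if (is.na(pidx) || pidx < 1L || pidx > nMi) stop("unknown target pivot")
    p <- sig_mi[pidx, ]
    tidx <- sample(setdiff(seq_len(nG), used_genes), tg$n_targets)
    rho <- tg$rho
    a <- (rho / sqrt(1 - rho^2)) * (config$noise_sd / stats::sd(p))
    sig_g[tidx, ] <- sig_g[tidx, ] -
      a * matrix(p - mean(p), tg$n_targets, nS, byrow = TRUE)
    targets_truth <- data.frame(pivot_id = mirna_ids[pidx],
                                gene_id = mrna_ids[sort(tidx)], rho = rho,
                                stringsAsFactors = FALSE)
  }

  # replicate arrays with measurement noise, linear scale, detection dropout
  nR <- config$replicates
  array_ids <- as.vector(t(outer(sample_ids, seq_len(nR),
                                 function(s, r) paste0(s, "_r", r))))
  rep_group <- rep(sample_ids, each = nR)
  x <- sig_mi[, rep(seq_len(nS), each = nR), drop = FALSE] +
    matrix(stats::rnorm(nMi * nS * nR, 0, config$tech_sd), nMi, nS * nR)
  dimnames(x) <- list(mirna_ids, array_ids)
  p_absent <- stats::plogis((config$dropout$midpoint - x) /
                              config$dropout$slope)
  detection <- matrix(stats::runif(length(x)) >= p_absent, nrow(x), ncol(x),
                      dimnames = dimnames(x))
  mirna <- expression_matrix(2^x, scale = "linear", detection = detection)

  dimnames(sig_g) <- list(mrna_ids, sample_ids)
  mrna <- expression_matrix(sig_g, scale = "log2")

  annotations <- data.frame(
    sample_id = array_ids,
    subtype = rep(subtype, each = nR), er_status = rep(er, each = nR),
    tp53_status = rep(tp53, each = nR), ecm_class = rep(ecm, each = nR),
    ki67_category = rep(ki67, each = nR),
    mitotic_category = rep(mi_cat, each = nR),
    replicate_group = rep_group, stringsAsFactors = FALSE)
  class(annotations) <- c("sample_annotation", "data.frame")

  truth <- synthetic_truth(seed = config$seed, mirna_ids = mirna_ids,
                           mrna_ids = mrna_ids, sample_ids = sample_ids,
                           de = de_truth, modules = modules_truth,
                           couplings = couplings, targets = targets_truth)
  list(mirna = mirna, mrna = mrna, annotations = annotations, truth = truth)
}

#' Construct a synthetic-truth manifest
#'
#' @param seed Generator seed.
#' @param mirna_ids,mrna_ids,sample_ids Universe id vectors.
#' @param de Planted DE data.frame (feature_id, on, group_a, group_b,
#'   effect_sd, direction) or \code{NULL}.
#' @param modules Named list of module gene-id vectors.
#' @param couplings Data.frame (module, pivot_id, sign, loading,
#'   class_effect) or \code{NULL}.
#' @param targets Data.frame (pivot_id, gene_id, rho) or \code{NULL}.
#' @return A \code{synthetic_truth} object.
#' @export
synthetic_truth <- function(seed = NA_integer_, mirna_ids = character(0),
                            mrna_ids = character(0),
                            sample_ids = character(0), de = NULL,
                            modules = list(), couplings = NULL,
                            targets = NULL) {
  for (df in list(de, couplings, targets)) {
    if (!is.null(df)) stopifnot(is.data.frame(df))
  }
  structure(list(seed = seed, mirna_ids = mirna_ids, mrna_ids = mrna_ids,
                 sample_ids = sample_ids, de = de, modules = modules,
                 couplings = couplings, targets = targets),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d miRNAs, %d mRNAs, %d samples; ",
                     "%d planted DE, %d modules, %d target pairs\n"),
              length(x$mirna_ids), length(x$mrna_ids), length(x$sample_ids),
              if (is.null(x$de)) 0L else nrow(x$de), length(x$modules),
              if (is.null(x$targets)) 0L else nrow(x$targets)))
  invisible(x)
}

#' Generate gene sets from a truth manifest
#'
#' One set per planted module plus random decoy sets drawn from non-module
#' genes (so decoys are disjoint from module cores).
#'
#' @param truth A \code{synthetic_truth}.
#' @param n_decoys Number of decoy sets.
#' @param decoy_size_range Length-2 integer range of decoy set sizes.
#' @param seed Seed for the decoy draws (default derived from the truth
#'   seed).
#' @return A \code{gene_set_collection}.
#' @export
generate_gene_sets <- function(truth, n_decoys,
                               decoy_size_range = c(20L, 100L),
                               seed = truth$seed + 1L) {
  if (!length(truth$mrna_ids)) stop("truth carries no gene universe")
  pool <- setdiff(truth$mrna_ids, unlist(truth$modules, use.names = FALSE))
  if (max(decoy_size_range) > length(pool))
    stop("decoy size exceeds the non-module gene universe")
  set.seed(seed)
  sets <- truth$modules
  if (n_decoys > 0) {
    sizes <- sample(seq(decoy_size_range[1L], decoy_size_range[2L]),
                    n_decoys, replace = TRUE)
    for (i in seq_len(n_decoys)) {
      sets[[sprintf("decoy%03d", i)]] <- sort(sample(pool, sizes[i]))
    }
  }
  gene_set_collection(sets)
}

#' Generate a target context-score table from a truth manifest
#'
#' Planted (pivot, target) pairs receive context scores offset toward more
#' negative values than random background pairs.
#'
#' @param truth A \code{synthetic_truth} containing a target spec.
#' @param n_background_pairs Number of random background (mirna, gene)
#'   pairs.
#' @param offset How much more negative planted scores are than background
#'   (default 0.30; background scores are N(-0.10, 0.05^2)).
#' @param seed Seed for the draws (default derived from the truth seed).
#' @return A \code{target_score_table}.
#' @export
generate_target_table <- function(truth, n_background_pairs = 5000L,
                                  offset = 0.30, seed = truth$seed + 2L) {
  if (is.null(truth$targets)) stop("truth contains no target spec")
  set.seed(seed)
  planted <- truth$targets
  planted_key <- paste(planted$pivot_id, planted$gene_id)
  n_pairs <- length(truth$mirna_ids) * length(truth$mrna_ids)
  if (n_background_pairs > n_pairs - nrow(planted))
    stop("more background pairs requested than distinct (mirna, gene) pairs")
  # draw distinct background pairs, excluding the planted ones
  bg_key <- character(0)
  while (length(bg_key) < n_background_pairs) {
    want <- n_background_pairs - length(bg_key)
    cand <- paste(sample(truth$mirna_ids, 2L * want + 10L, replace = TRUE),
                  sample(truth$mrna_ids, 2L * want + 10L, replace = TRUE))
    cand <- setdiff(unique(cand), c(planted_key, bg_key))
    bg_key <- c(bg_key, utils::head(cand, want))
  }
  bg <- do.call(rbind, strsplit(bg_key, " ", fixed = TRUE))
  mirna <- c(planted$pivot_id, bg[, 1L])
  gene <- c(planted$gene_id, bg[, 2L])
  score <- c(stats::rnorm(nrow(planted), -0.10, 0.05) - offset,
             stats::rnorm(n_background_pairs, -0.10, 0.05))
  target_score_table(mirna, gene, score)
}

#' Write a truth manifest to TSV
#'
#' Flat long-format manifest of all planted structure, for recovery scoring;
#' an empty truth yields a header-only file.  \code{\link{read_truth_report}}
#' round-trips it.
#'
#' @param truth A \code{synthetic_truth}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
truth_report <- function(truth, path) {
  rows <- list()
  add <- function(kind, a = "", b = "", c = "", d = "", e = "", x = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, a = a, b = b, c = c, d = d, e = e, x = x,
      stringsAsFactors = FALSE)
  }
  if (!is.na(truth$seed)) add("seed", x = truth$seed)
  for (id in truth$mirna_ids) add("mirna_id", id)
  for (id in truth$mrna_ids) add("mrna_id", id)
  for (id in truth$sample_ids) add("sample_id", id)
  if (!is.null(truth$de)) for (i in seq_len(nrow(truth$de))) {
    r <- truth$de[i, ]
    add("de", r$feature_id, r$on, r$group_a, r$group_b, r$direction,
        r$effect_sd)
  }
  for (nm in names(truth$modules)) for (g in truth$modules[[nm]])
    add("module_gene", nm, g)
  if (!is.null(truth$couplings)) for (i in seq_len(nrow(truth$couplings))) {
    r <- truth$couplings[i, ]
    add("coupling", r$module, r$pivot_id, e = as.character(r$class_effect),
        x = r$sign * r$loading)
  }
  if (!is.null(truth$targets)) for (i in seq_len(nrow(truth$targets))) {
    r <- truth$targets[i, ]
    add("target", r$pivot_id, r$gene_id, x = r$rho)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), a = character(0), b = character(0),
               c = character(0), d = character(0), e = character(0),
               x = numeric(0))
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth manifest back from TSV
#'
#' @param path Path written by \code{\link{truth_report}}.
#' @return The reconstructed \code{synthetic_truth}.
#' @export
read_truth_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c(rep("character", 6L), "numeric"),
                          stringsAsFactors = FALSE)
  pick <- function(kind) df[df$kind == kind, , drop = FALSE]
  seed_row <- pick("seed")
  de_rows <- pick("de")
  mg <- pick("module_gene")
  cp <- pick("coupling")
  tg <- pick("target")
  modules <- if (nrow(mg)) split(mg$b, factor(mg$a, levels = unique(mg$a)))
             else list()
  modules <- lapply(modules, as.character)
  synthetic_truth(
    seed = if (nrow(seed_row)) as.integer(seed_row$x[1L]) else NA_integer_,
    mirna_ids = pick("mirna_id")$a, mrna_ids = pick("mrna_id")$a,
    sample_ids = pick("sample_id")$a,
    de = if (nrow(de_rows)) data.frame(
      feature_id = de_rows$a, on = de_rows$b, group_a = de_rows$c,
      group_b = de_rows$d, effect_sd = de_rows$x, direction = de_rows$e,
      stringsAsFactors = FALSE) else NULL,
    modules = modules,
    couplings = if (nrow(cp)) data.frame(
      module = cp$a, pivot_id = cp$b, sign = sign(cp$x),
      loading = abs(cp$x), class_effect = as.numeric(cp$e),
      stringsAsFactors = FALSE) else NULL,
    targets = if (nrow(tg)) data.frame(
      pivot_id = tg$a, gene_id = tg$b, rho = tg$x,
      stringsAsFactors = FALSE) else NULL)
}
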