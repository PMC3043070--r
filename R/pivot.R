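# Pivot-miRNA integration: the three ranking schemes feeding mHG enrichment
# (A: differential expression; B: correlation to a pivot miRNA; C: target
# prediction score), the signed miRNA-by-gene-set association matrix, and the
# concordance between differential expression and enrichment signs.

#' Construct a ranked gene list
#'
#' @param gene Character vector of unique gene ids, top of the ranking first.
#' @param score Numeric ranking score aligned with \code{gene}.
#' @param direction One of \code{"descending_correlation"},
#'   \code{"ascending_correlation"}, \code{"ascending_target_score"},
#'   \code{"descending_de_score"}.
#' @return A data.frame of class \code{ranked_list} with a direction
#'   attribute.
#' @export
ranked_list <- function(gene, score,
                        direction = c("descending_correlation",
                                      "ascending_correlation",
                                      "ascending_target_score",
                                      "descending_de_score")) {
  direction <- match.arg(direction)
  if (anyDuplicated(gene)) stop("duplicate gene id in ranking")
  out <- data.frame(gene = as.character(gene), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Rank mRNAs by Spearman correlation to a pivot miRNA
#'
#' Spearman rho (average ranks for ties) of every gene against the pivot
#' expression vector across the shared samples.  Constant genes are assigned
#' rho = 0.  The correlated direction orders by descending rho with ties
#' broken by ascending gene id; the anti-correlated direction is defined as
#' the exact reverse of that ordering, so the two rankings are mirror images.
#'
#' @param pivot Named numeric vector of pivot miRNA expression; names must
#'   equal the sample ids of \code{mrna} in the same order.
#' @param mrna A log2-scale mRNA \code{ExpressionMatrix}.
#' @param direction \code{"descending_correlation"} (correlatees first) or
#'   \code{"ascending_correlation"} (anti-correlatees first).
#' @return A \code{\link{ranked_list}} over all genes of \code{mrna}.
#' @export
spearman_rank_genes <- function(pivot, mrna,
                                direction = c("descending_correlation",
                                              "ascending_correlation")) {
  direction <- match.arg(direction)
  if (is.null(names(pivot)) || !identical(names(pivot), sample_ids(mrna)))
    stop("pivot sample ids must match the mRNA matrix samples (same order)")
  rho <- spearman_to_pivot(pivot, mrna$values)
  genes <- feature_ids(mrna)
  ord <- order(-rho, genes)
  if (direction == "ascending_correlation") ord <- rev(ord)
  ranked_list(genes[ord], rho[ord], direction = direction)
}

# Spearman rho of every row of vals against the pivot vector; ties get
# average ranks; rows (or a pivot) with zero variance yield rho = 0.
spearman_to_pivot <- function(pivot, vals) {
  rp <- rank(pivot)
  rr <- t(apply(vals, 1L, rank))
  if (nrow(vals) == 1L) rr <- matrix(rr, nrow = 1L)
  rho <- suppressWarnings(as.vector(stats::cor(rp, t(rr))))
  rho[!is.finite(rho)] <- 0
  rho
}

#' Per-feature signed differential-expression scores
#'
#' -log10(p) for features up in class A, +log10(p) for features down; the
#' magnitude grows with significance and the sign carries the direction.
#'
#' @param results A \code{differential_result} table.
#' @param p_column Which p-value to use (default \code{"tnom_p"}).
#' @return Named numeric vector of signed scores, one per feature.
#' @export
signed_de_scores <- function(results, p_column = "tnom_p") {
  p <- results[[p_column]]
  s <- ifelse(results$direction == "up", -log10(p), log10(p))
  stats::setNames(s, results$feature_id)
}

#' Rank features by signed differential expression
#'
#' Most up-regulated (smallest p, up) first, most down-regulated last; ties
#' broken by ascending feature id.
#'
#' @inheritParams signed_de_scores
#' @return A \code{\link{ranked_list}} with direction
#'   \code{"descending_de_score"}.
#' @export
rank_by_differential <- function(results, p_column = "tnom_p") {
  if (!nrow(results)) stop("empty differential result")
  s <- signed_de_scores(results, p_column)
  ord <- order(-s, results$feature_id)
  ranked_list(results$feature_id[ord], unname(s)[ord],
              direction = "descending_de_score")
}

#' Rank genes by predicted targeting strength of a pivot miRNA
#'
#' Genes in the universe that appear in the target table are ordered by
#' ascending context score (more negative = stronger predicted targeting);
#' ties are broken by ascending gene id; genes absent from the table are
#' excluded.
#'
#' @param pivot_id miRNA id, which must be present in the table.
#' @param targets A \code{target_score_table}.
#' @param universe Character vector of candidate gene ids.
#' @return A \code{\link{ranked_list}} with direction
#'   \code{"ascending_target_score"}.
#' @export
rank_by_target_score <- function(pivot_id, targets, universe) {
  tt <- targets[targets$mirna == pivot_id, , drop = FALSE]
  if (!nrow(tt)) stop("pivot '", pivot_id, "' absent from the target table")
  tt <- tt[tt$gene %in% universe, , drop = FALSE]
  ord <- order(tt$score, tt$gene)
  ranked_list(tt$gene[ord], tt$score[ord], direction = "ascending_target_score")
}

#' Enrichment of predicted targets among a pivot's anti-correlatees
#'
#' The top predicted targets of the pivot (at most \code{top_n}, default
#' 2000, by most negative context score; all of them if fewer) form the set
#' H, genes are ranked by anti-correlation to the pivot, and the mHG
#' enrichment of H in that ranking is returned.  A significant result
#' indicates that the miRNA's predicted targets are anti-correlated with its
#' expression.
#'
#' @param pivot_id miRNA id present in \code{targets}.
#' @param pivot_expr Named numeric pivot expression vector over the samples
#'   of \code{mrna} (same order).
#' @param mrna A log2-scale mRNA \code{ExpressionMatrix}.
#' @param targets A \code{target_score_table}.
#' @param top_n Maximum number of top targets to use (default 2000).
#' @return A one-row \code{enrichment_result}.
#' @export
target_anticorrelation_enrichment <- function(pivot_id, pivot_expr, mrna,
                                              targets, top_n = 2000L) {
  tt <- targets[targets$mirna == pivot_id, , drop = FALSE]
  if (!nrow(tt)) stop("pivot '", pivot_id, "' absent from the target table")
  ord <- order(tt$score, tt$gene)
  if (nrow(tt) < top_n)
    message("pivot '", pivot_id, "' has ", nrow(tt), " predicted targets (< ",
            top_n, "); all used")
  H <- tt$gene[ord][seq_len(min(top_n, nrow(tt)))]
  ranking <- spearman_rank_genes(pivot_expr, mrna,
                                 direction = "ascending_correlation")
  sets <- gene_set_collection(stats::setNames(list(H),
                                              paste0(pivot_id, "_targets")))
  enrich_ranked_list(ranking, sets)
}

#' Signed association score from a direction pair of enrichments
#'
#' +(-log10 p_pos) if the set is better supported among the positively
#' correlated genes (p_pos <= p_neg), otherwise log10(p_neg) (a negative
#' score).  Both p-values equal to 1 give 0.
#'
#' @param pos,neg Enrichment p-values (numeric) or one-row
#'   \code{enrichment_result} tables for the positively / negatively
#'   correlated direction of the same pivot and set.
#' @return Signed score; positive means enrichment among correlatees.
#' @export
signed_association_score <- function(pos, neg) {
  p_pos <- if (is.data.frame(pos)) pos$p_exact[1L] else as.numeric(pos)
  p_neg <- if (is.data.frame(neg)) neg$p_exact[1L] else as.numeric(neg)
  if (p_pos <= p_neg) -log10(p_pos) else log10(p_neg)
}

#' miRNA-by-gene-set signed association matrix
#'
#' For every (pivot miRNA, gene set) pair, genes are ranked by Spearman
#' correlation to the pivot; the set's mHG enrichment is computed in both the
#' correlated and anti-correlated direction and collapsed into a signed
#' score (\code{\link{signed_association_score}}).  Row and column order are
#' preserved from the inputs.
#'
#' @param pivots A log2-scale miRNA \code{ExpressionMatrix}; every row is
#'   used as a pivot.
#' @param mrna A log2-scale mRNA \code{ExpressionMatrix} over the same
#'   samples (any order; columns are aligned to \code{pivots}).
#' @param sets A \code{gene_set_collection}; sets with empty intersection
#'   with the gene universe are dropped with a warning.
#' @return An \code{association_matrix} object: list with \code{score}
#'   (pivots x sets signed scores), \code{p_pos} and \code{p_neg} (the
#'   underlying exact p-values).
#' @export
association_matrix <- function(pivots, mrna, sets) {
  if (!setequal(sample_ids(pivots), sample_ids(mrna)))
    stop("pivot and mRNA matrices must share the same samples")
  mrna <- mrna[, sample_ids(pivots)]
  genes <- feature_ids(mrna)
  N <- length(genes)
  keep <- vapply(sets, function(g) any(g %in% genes), logical(1L))
  if (any(!keep))
    warning("sets with empty intersection dropped: ",
            paste(names(sets)[!keep], collapse = ", "))
  set_names <- names(sets)[keep]
  if (!length(set_names)) stop("no set intersects the gene universe")
  memberships <- lapply(sets[keep], function(g) genes %in% g)
  rr <- t(apply(mrna$values, 1L, rank))
  pivot_ids <- feature_ids(pivots)
  score <- p_pos <- p_neg <- matrix(
    NA_real_, length(pivot_ids), length(set_names),
    dimnames = list(pivot_ids, set_names))
  for (pi in seq_along(pivot_ids)) {
    rp <- rank(pivots$values[pi, ])
    rho <- suppressWarnings(as.vector(stats::cor(rp, t(rr))))
    rho[!is.finite(rho)] <- 0
    ord <- order(-rho, genes)
    for (si in seq_along(set_names)) {
      lam <- memberships[[si]][ord]
      B <- sum(lam)
      st_pos <- mhg_statistic(lam)
      st_neg <- mhg_statistic(rev(lam))
      pp <- mhg_exact_pvalue(st_pos$s, N, B, log_s = st_pos$log_s)
      pn <- mhg_exact_pvalue(st_neg$s, N, B, log_s = st_neg$log_s)
      p_pos[pi, si] <- pp
      p_neg[pi, si] <- pn
      score[pi, si] <- signed_association_score(pp, pn)
    }
  }
  structure(list(score = score, p_pos = p_pos, p_neg = p_neg),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d pivots x %d gene sets (signed -log10 p)\n",
              nrow(x$score), ncol(x$score)))
  invisible(x)
}

#' @export
as.matrix.association_matrix <- function(x, ...) x$score

#' Concordance between differential expression and enrichment signs
#'
#' Pearson correlation, across miRNAs, between per-miRNA signed
#' differential-expression scores and the signed enrichment scores of one
#' gene set; a strong positive r means miRNAs over-expressed in one class
#' carry the set among their positively correlated genes.
#'
#' @param de_scores Named numeric vector of signed DE scores
#'   (\code{\link{signed_de_scores}}).
#' @param assoc An \code{association_matrix} (or plain signed-score matrix
#'   with miRNA rownames).
#' @param set_name Column (gene set) to correlate against.
#' @return A list of class \code{concordance_result}: \code{set_name},
#'   \code{r}, \code{n_mirnas}.
#' @export
de_enrichment_concordance <- function(de_scores, assoc, set_name) {
  score <- if (inherits(assoc, "association_matrix")) assoc$score else assoc
  if (!set_name %in% colnames(score)) stop("unknown set '", set_name, "'")
  shared <- intersect(names(de_scores), rownames(score))
  if (length(shared) < 3L) stop("fewer than 3 shared miRNAs")
  r <- stats::cor(de_scores[shared], score[shared, set_name])
  structure(list(set_name = set_name, r = unname(r),
                 n_mirnas = length(shared)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance '%s': Pearson r = %.3f over %d miRNAs\n",
              x$set_name, x$r, x$n_mirnas))
  invisible(x)
}
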