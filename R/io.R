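# Tabular readers/writers: TSV expression matrices, GMT gene sets, TargetScan
# style context-score tables, sample annotations, and the generic result
# writer.  Dialect: UTF-8, tab-separated, "." decimal point, no quoting.

#' Read a feature-by-sample expression matrix from TSV
#'
#' First row is the sample header, first column the feature id; row and column
#' order are preserved.  An optional companion file of identical shape supplies
#' present/absent detection calls (0/1 or TRUE/FALSE).
#'
#' @param path Path to the TSV file.
#' @param scale Scale tag to attach, \code{"linear"} or \code{"log2"}.
#' @param detection_path Optional path to a detection-call matrix TSV.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_tsv <- function(path, scale = c("linear", "log2"),
                                detection_path = NULL) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a feature column plus samples")
  fid <- df[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id '", fid[duplicated(fid)][1L], "' in ", path)
  sid <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(vals))
    stop("non-numeric or missing cell at feature '", fid[i[1L]],
         "', sample '", sid[i[2L]], "' in ", path)
  }
  dimnames(vals) <- list(fid, sid)
  det <- NULL
  if (!is.null(detection_path)) {
    dd <- utils::read.delim(detection_path, header = TRUE, sep = "\t",
                            quote = "", check.names = FALSE,
                            stringsAsFactors = FALSE)
    dm <- as.matrix(dd[-1L])
    det <- matrix(as.logical(as.numeric(dm)), nrow = nrow(dm))
    if (!identical(dim(det), dim(vals)))
      stop("detection matrix shape differs from expression matrix")
    dimnames(det) <- dimnames(vals)
  }
  expression_matrix(vals, scale = scale, detection = det)
}

#' Write an expression matrix to TSV
#'
#' @param m An \code{ExpressionMatrix}.
#' @param path Output path for the value matrix.
#' @param detection_path Optional output path for the detection calls (0/1).
#' @param digits Significant digits for values (default 6).
#' @return Invisibly, \code{path}.
#' @export
write_expression_tsv <- function(m, path, detection_path = NULL, digits = 6L) {
  df <- data.frame(feature_id = rownames(m$values),
                   signif(m$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detection_path)) {
    if (is.null(m$detection)) stop("matrix carries no detection calls")
    dd <- data.frame(feature_id = rownames(m$values),
                     m$detection + 0L, check.names = FALSE)
    utils::write.table(dd, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate genes within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A \code{gene_set_collection}: named list of character vectors with
#'   a \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    nm <- fields[1L]
    if (nm %in% names(sets)) stop("duplicate set name '", nm, "'")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " defines an empty set")
    sets[[nm]] <- genes
    desc[nm] <- fields[2L]
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique genes per set).
#' @param descriptions Optional named character vector of descriptions.
#' @return A \code{gene_set_collection} object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(!lengths(sets))) stop("every set must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param sets A \code{gene_set_collection}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (is.null(desc)) "" else desc[[nm]], sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA target context-score table
#'
#' TSV with columns \code{mirna}, \code{gene}, \code{score} (more negative =
#' stronger predicted targeting).  Duplicate (mirna, gene) rows are collapsed
#' to the most negative score.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class \code{target_score_table} with columns
#'   \code{mirna}, \code{gene}, \code{score}.
#' @export
read_target_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  for (col in c("mirna", "gene", "score"))
    if (!col %in% colnames(df))
      stop("target-score table lacks column '", col, "'")
  target_score_table(df$mirna, df$gene, as.numeric(df$score))
}

#' Construct a target context-score table
#'
#' @param mirna Character vector of miRNA ids.
#' @param gene Character vector of gene ids.
#' @param score Numeric prediction scores (more negative = stronger).
#' @return A \code{target_score_table} data.frame; duplicate (mirna, gene)
#'   pairs are collapsed to the most negative score.
#' @export
target_score_table <- function(mirna, gene, score) {
  df <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (any(!is.finite(df$score))) stop("non-finite context score")
  key <- paste(df$mirna, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    df <- df[order(key, df$score), ]
    df <- df[!duplicated(paste(df$mirna, df$gene, sep = "\r")), ]
    rownames(df) <- NULL
  }
  class(df) <- c("target_score_table", "data.frame")
  df
}

#' Write a target context-score table
#' @param tab A \code{target_score_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_target_scores <- function(tab, path) {
  write_table(tab, path)
}

#' Read sample annotations
#'
#' TSV with a \code{sample_id} column plus any subset of: \code{subtype},
#' \code{er_status}, \code{tp53_status}, \code{ecm_class}, \code{ki67_percent}
#' (percent Ki67-positive cells; multiple TMA cores may be given
#' semicolon-separated, the highest is used), \code{mitoses} (count per 10
#' high-power fields), \code{replicate_group}.  Raw percents and counts are
#' mapped to categories: Ki67 negative iff <=1, moderate iff <=10, high
#' otherwise; mitotic index low iff 0-5, moderate iff 6-11, high otherwise.
#' Unrecognized subtype strings map to \code{"unclassified"}.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class \code{sample_annotation}, one row per sample.
#' @export
read_sample_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("annotation table lacks column 'sample_id'")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    stringsAsFactors = FALSE)
  known <- c("basal-like", "luminal-A", "luminal-B", "ERBB2-enriched",
             "normal-like", "unclassified")
  out$subtype <- if ("subtype" %in% colnames(df)) {
    ifelse(df$subtype %in% known, df$subtype, "unclassified")
  } else "unclassified"
  norm_enum <- function(col, allowed, fallback) {
    if (!col %in% colnames(df)) return(rep(fallback, nrow(df)))
    ifelse(df[[col]] %in% allowed, df[[col]], fallback)
  }
  out$er_status <- norm_enum("er_status", c("positive", "negative"), "unknown")
  out$tp53_status <- norm_enum("tp53_status", c("WT", "mutant"), "unknown")
  out$ecm_class <- norm_enum("ecm_class", paste0("ECM", 1:4), "unknown")
  out$ki67_category <- if ("ki67_percent" %in% colnames(df)) {
    vapply(df$ki67_percent, function(v) {
      cores <- suppressWarnings(as.numeric(strsplit(as.character(v), ";")[[1L]]))
      cores <- cores[is.finite(cores)]
      if (!length(cores)) return("missing")
      ki67_category(max(cores))
    }, character(1L), USE.NAMES = FALSE)
  } else if ("ki67_category" %in% colnames(df)) {
    norm_enum("ki67_category", c("negative", "moderate", "high"), "missing")
  } else rep("missing", nrow(df))
  out$mitotic_category <- if ("mitoses" %in% colnames(df)) {
    mm <- suppressWarnings(as.numeric(df$mitoses))
    ifelse(is.finite(mm), mitotic_category(mm), "missing")
  } else if ("mitotic_category" %in% colnames(df)) {
    norm_enum("mitotic_category", c("low", "moderate", "high"), "missing")
  } else rep("missing", nrow(df))
  out$replicate_group <- if ("replicate_group" %in% colnames(df)) {
    as.character(df$replicate_group)
  } else out$sample_id
  class(out) <- c("sample_annotation", "data.frame")
  out
}

#' Categorize a Ki67 staining percentage
#'
#' negative iff <= 1 percent stained cells, moderate iff in (1, 10], high
#' iff > 10.
#'
#' @param percent Numeric vector of percent positive cells.
#' @return Character vector of categories.
#' @export
ki67_category <- function(percent) {
  ifelse(percent <= 1, "negative", ifelse(percent <= 10, "moderate", "high"))
}

#' Categorize a mitotic count
#'
#' low iff 0-5 mitoses, moderate iff 6-11, high iff > 11 (per 10 high-power
#' fields).
#'
#' @param count Numeric vector of mitosis counts.
#' @return Character vector of categories.
#' @export
mitotic_category <- function(count) {
  ifelse(count <= 5, "low", ifelse(count <= 11, "moderate", "high"))
}

#' Write a result table to TSV
#'
#' Header included; numeric columns serialized at 6 significant digits; row
#' order is the table's own documented order (result constructors sort their
#' output deterministically).  An empty table yields a header-only file.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(rows, path, digits = 6L) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
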