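# Preprocessing of raw array matrices: replicate averaging (with the
# present-if-present-in-either detection rule), 75th-percentile scaling,
# log2 transform, detection filtering, and top-variance feature selection.
# Multiplicative scaling is only meaningful on the linear scale, so the
# pipeline order is: average (linear) -> percentile normalize (linear) ->
# log2 -> filter/select.

#' Average replicate hybridizations
#'
#' Collapses replicate array columns to one column per replicate group by the
#' arithmetic mean on the linear scale.  A feature is called present in the
#' averaged sample if it was scored present on at least one member array.
#'
#' @param m A linear-scale \code{ExpressionMatrix}.
#' @param groups Named character vector mapping every sample id of \code{m}
#'   to its replicate group (the collapsed sample id).
#' @return An \code{ExpressionMatrix} with one column per group, in first
#'   appearance order.
#' @export
average_replicates <- function(m, groups) {
  if (m$scale != "linear") stop("replicate averaging requires the linear scale")
  sid <- sample_ids(m)
  if (is.null(names(groups)) || !all(sid %in% names(groups)))
    stop("every sample must be assigned to exactly one replicate group")
  groups <- groups[sid]
  glev <- unique(unname(groups))
  vals <- vapply(glev, function(g) {
    cols <- which(groups == g)
    if (!length(cols)) stop("replicate group '", g, "' has zero members")
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  if (nrow(m$values) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(feature_ids(m), glev)
  det <- NULL
  if (!is.null(m$detection)) {
    det <- vapply(glev, function(g) {
      cols <- which(groups == g)
      rowSums(m$detection[, cols, drop = FALSE]) > 0
    }, logical(nrow(m$values)))
    if (nrow(m$values) == 1L) det <- matrix(det, nrow = 1L)
    dimnames(det) <- dimnames(vals)
  }
  expression_matrix(vals, scale = "linear", detection = det)
}

#' Scale each sample to a common 75th percentile
#'
#' Each sample i is multiplied by a constant c_i such that its 75th percentile
#' (linear interpolation between order statistics) equals a global constant c;
#' by default c is the 75th percentile of the pooled dataset.
#'
#' @param m A linear-scale \code{ExpressionMatrix} with non-negative values.
#' @param c Optional positive target percentile value; defaults to the pooled
#'   75th percentile.
#' @param probs Percentile to normalize to, as a fraction (default 0.75).
#' @return A list with elements \code{matrix} (the scaled
#'   \code{ExpressionMatrix}) and \code{report} (a \code{normalization_report}
#'   with the global constant \code{c} and per-sample factors \code{c_i}).
#' @export
percentile_normalize <- function(m, c = NULL, probs = 0.75) {
  if (m$scale != "linear") stop("percentile normalization requires the linear scale")
  if (any(m$values < 0)) stop("percentile normalization requires non-negative values")
  p_i <- apply(m$values, 2L, stats::quantile, probs = probs, names = FALSE,
               type = 7L)
  zero <- which(p_i <= 0)
  if (length(zero))
    stop("sample '", sample_ids(m)[zero[1L]], "' has a non-positive ",
         probs * 100, "th percentile")
  if (is.null(c)) c <- stats::quantile(m$values, probs = probs, names = FALSE,
                                       type = 7L)
  if (!is.finite(c) || c <= 0) stop("'c' must be a positive real")
  c_i <- c / p_i
  vals <- sweep(m$values, 2L, c_i, `*`)
  dimnames(vals) <- dimnames(m$values)
  report <- structure(
    list(c = unname(c), c_i = stats::setNames(c_i, sample_ids(m)),
         percentile = probs),
    class = "normalization_report")
  list(matrix = expression_matrix(vals, scale = "linear",
                                  detection = m$detection),
       report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("normalization_report: %d samples scaled to %gth percentile = %g\n",
              length(x$c_i), x$percentile * 100, x$c))
  invisible(x)
}

#' Log2-transform a linear matrix
#'
#' Values are replaced by \code{log2(pmax(value, floor))}; the floor (default
#' 1 intensity unit) keeps noise-floor intensities from mapping to -Inf.
#'
#' @param m A linear-scale \code{ExpressionMatrix}.
#' @param floor Positive intensity floor applied before taking logs.
#' @return The log2-scale \code{ExpressionMatrix}.
#' @export
log2_transform <- function(m, floor = 1) {
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  if (!is.finite(floor) || floor <= 0) stop("'floor' must be a positive real")
  vals <- log2(pmax(m$values, floor))
  expression_matrix(vals, scale = "log2", detection = m$detection)
}

#' Filter features by detection rate
#'
#' Removes every feature detected in less than \code{min_fraction} of the
#' samples (features detected in exactly that fraction are retained).
#'
#' @param m An \code{ExpressionMatrix} carrying detection calls.
#' @param min_fraction Minimum detected fraction in (0, 1]; default 0.10.
#' @return The filtered \code{ExpressionMatrix}.
#' @export
detection_filter <- function(m, min_fraction = 0.10) {
  if (is.null(m$detection)) stop("matrix carries no detection calls")
  if (!is.finite(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must lie in (0, 1]")
  keep <- rowMeans(m$detection) >= min_fraction
  m[keep, ]
}

#' Select the features of highest variance
#'
#' Returns the k features with largest sample variance (unbiased, n-1
#' denominator).  Ties at the cutoff are broken by ascending lexicographic
#' feature id; if k exceeds the feature count all features are returned.
#'
#' @param m An \code{ExpressionMatrix}.
#' @param k Positive integer number of features to keep.
#' @return The restricted \code{ExpressionMatrix}, ordered by decreasing
#'   variance.
#' @export
top_variance_select <- function(m, k) {
  if (!is.finite(k) || k < 1) stop("'k' must be a positive integer")
  v <- apply(m$values, 1L, stats::var)
  ord <- order(-v, feature_ids(m))
  m[ord[seq_len(min(k, length(ord)))], ]
}
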