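# TNoM (Threshold Number of Misclassifications) differential expression.
#
# For a feature measured in two sample classes, TNoM is the minimum, over all
# expression thresholds and both label orientations, of the number of samples
# falling on the wrong side of the threshold.  Its null distribution over all
# C(N, B) equiprobable label arrangements is exact and distribution-free and
# is computed by a lattice-path dynamic program (src/dp.cpp), not by
# enumeration.  Ties in expression are kept in stable input order and cuts
# are only placed between distinct values, which is conservative under heavy
# ties.

#' TNoM statistic of a labeled expression vector
#'
#' @param values Numeric vector of per-sample expression.
#' @param labels Binary class labels (logical or 0/1), same length.
#' @return Integer: the minimum number of misclassified samples over all
#'   threshold classifiers (both orientations).
#' @examples
#' tnom_statistic(c(1, 2, 3, 4), c(1, 1, 0, 0))  # 0: perfectly separable
#' tnom_statistic(c(1, 2, 3, 4), c(1, 0, 1, 0))  # 1
#' @export
tnom_statistic <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels)) stop("lengths differ")
  N <- length(values)
  B <- sum(labels)
  o <- order(values)  # stable: ties keep input order
  x <- values[o]; lab <- labels[o]
  # cuts allowed at 0, between distinct consecutive values, and at N
  allowed <- c(0L, which(c(x[-N] != x[-1L], TRUE)))
  b <- c(0L, cumsum(lab))[allowed + 1L]
  e <- allowed + B - 2L * b  # misclassifications with class-1 on the left
  min(pmin(e, N - e))
}

#' Exact cumulative null distribution of TNoM
#'
#' Cumulative probabilities P(TNoM <= k) for k = 0, ..., min(n1, n0) under
#' the null in which all C(n1+n0, n1) label arrangements are equiprobable,
#' computed by counting bounded lattice paths.
#'
#' @param n1,n0 Class sizes (both >= 1).
#' @return Named numeric vector of cumulative probabilities, names "0", "1",
#'   ...; the final entry equals 1.
#' @export
tnom_null_distribution <- function(n1, n0) {
  if (n1 < 1 || n0 < 1) stop("both class sizes must be >= 1")
  cum <- tnom_null_cpp(as.integer(n1), as.integer(n0))
  cum[cum == 0] <- .Machine$double.xmin  # p-values are never reported as 0
  stats::setNames(cum, as.character(seq_along(cum) - 1L))
}

#' Exact TNoM p-value
#'
#' P(TNoM <= observed k) under the exact combinatorial null.
#'
#' @inheritParams tnom_statistic
#' @return The exact p-value in (0, 1].
#' @export
tnom_exact_pvalue <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels); n0 <- length(labels) - n1
  if (n1 < 1 || n0 < 1) stop("both classes must be non-empty")
  k <- tnom_statistic(values, labels)
  unname(tnom_null_distribution(n1, n0)[k + 1L])
}

#' Two-sided Welch t-test p-value
#'
#' Companion parametric p-value for a two-class comparison.  If both classes
#' have zero variance the p-value is 1 for equal means and the smallest
#' positive normal double for unequal means.
#'
#' @inheritParams tnom_statistic
#' @return Two-sided unequal-variance t-test p-value.
#' @export
t_test_pvalue <- function(values, labels) {
  labels <- as.logical(labels)
  x <- values[labels]; y <- values[!labels]
  if (length(x) < 2L || length(y) < 2L)
    stop("both classes must have at least 2 samples")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment, capped at 1, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Vector of q-values aligned with the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression table for a two-class comparison
#'
#' For every feature: the TNoM count k, its exact combinatorial p-value, the
#' Welch t-test p-value, the log2 fold change (mean of class A minus mean of
#' class B on the log2 scale), the direction (up = higher in class A), and
#' the BH q-value across all features.  Output is sorted by ascending TNoM
#' p-value, then feature id.
#'
#' @param m A log2-scale \code{ExpressionMatrix}.
#' @param class_a,class_b Disjoint character vectors of sample ids.
#' @return A data.frame of class \code{differential_result} with columns
#'   \code{feature_id}, \code{k}, \code{tnom_p}, \code{t_p}, \code{log2_fc},
#'   \code{direction}, \code{q}.
#' @export
differential_expression_table <- function(m, class_a, class_b) {
  if (m$scale != "log2") stop("differential expression expects a log2 matrix")
  sid <- sample_ids(m)
  if (!all(class_a %in% sid) || !all(class_b %in% sid))
    stop("classes must be subsets of the matrix's samples")
  if (length(intersect(class_a, class_b)))
    stop("classes overlap: ", intersect(class_a, class_b)[1L])
  nA <- length(class_a); nB <- length(class_b)
  if (nA < 1L || nB < 1L) stop("both classes must be non-empty")
  va <- m$values[, class_a, drop = FALSE]
  vb <- m$values[, class_b, drop = FALSE]
  labels <- c(rep(1L, nA), rep(0L, nB))
  null_cum <- tnom_null_distribution(nA, nB)
  FF <- nrow(m$values)
  k <- integer(FF); t_p <- numeric(FF)
  for (i in seq_len(FF)) {
    vals <- c(va[i, ], vb[i, ])
    k[i] <- tnom_statistic(vals, labels)
    t_p[i] <- if (nA >= 2L && nB >= 2L) t_test_pvalue(vals, labels) else NA_real_
  }
  tnom_p <- unname(null_cum[k + 1L])
  log2_fc <- rowMeans(va) - rowMeans(vb)
  out <- data.frame(feature_id = feature_ids(m), k = k, tnom_p = tnom_p,
                    t_p = t_p, log2_fc = unname(log2_fc),
                    direction = ifelse(log2_fc >= 0, "up", "down"),
                    q = bh_fdr(tnom_p), stringsAsFactors = FALSE)
  out <- out[order(out$tnom_p, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "class_a") <- class_a
  attr(out, "class_b") <- class_b
  class(out) <- c("differential_result", "data.frame")
  out
}
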