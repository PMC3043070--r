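# Minimum-hypergeometric (mHG) enrichment over ranked lists.
#
# Given a ranked universe of N genes of which B belong to a set H, the label
# vector lambda marks the members along the ranking.  The mHG score is the
# minimum over all prefix lengths n of the hypergeometric tail
# HGT(b_n; N, B, n), and its exact p-value -- which needs no correction for
# the multiple prefixes tested -- is computed by a lattice-path dynamic
# program that absorbs label arrangements the first time they attain a tail
# at or below the observed score (src/dp.cpp).

#' Hypergeometric tail probability
#'
#' P(X >= b) for X hypergeometric with population size N, B successes and n
#' draws.  Boundary cases are honored exactly: 1 when b <= 0, 0 when
#' b > min(n, B).
#'
#' @param b Number of successes in the prefix (integer, vectorized).
#' @param N Universe size.
#' @param B Number of set members in the universe.
#' @param n Prefix length (vectorized with \code{b}).
#' @return Tail probabilities.
#' @examples
#' hypergeometric_tail(2, 4, 2, 2)  # 1/6
#' @export
hypergeometric_tail <- function(b, N, B, n) {
  if (length(N) != 1L || length(B) != 1L) stop("N and B must be scalars")
  if (N < 0 || B < 0 || B > N) stop("need 0 <= B <= N")
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
  if (any(b < 0)) stop("need b >= 0")
  out <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
  out[b <= 0] <- 1
  out[b > pmin(n, B)] <- 0
  out
}

#' mHG statistic of a ranked label vector
#'
#' @param lambda Binary membership vector (logical or 0/1) along the ranking,
#'   top of the list first.
#' @return A list with \code{s} (the minimum tail, in (0, 1]; floored at the
#'   smallest positive double if the true minimum underflows), \code{n_star}
#'   (the optimizing prefix length, smallest in case of ties), \code{b_star}
#'   (set members within that prefix) and \code{log_s} (the exact natural log
#'   of the minimum tail, exact even when \code{s} underflows).
#' @examples
#' mhg_statistic(c(1, 1, 0, 0))  # s = 1/6 at n* = 2
#' @export
mhg_statistic <- function(lambda) {
  lambda <- as.integer(as.logical(lambda))
  N <- length(lambda)
  if (N < 1L) stop("lambda must be non-empty")
  B <- sum(lambda)
  if (B == 0L) return(list(s = 1, n_star = 1L, b_star = 0L, log_s = 0))
  b <- cumsum(lambda)
  n <- seq_len(N)
  # log-space tails: prefix minima can fall far below double range
  log_tails <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE,
                             log.p = TRUE)
  n_star <- which.min(log_tails)  # first minimum = smallest n
  log_s <- log_tails[n_star]
  s <- exp(log_s)
  if (s == 0) s <- .Machine$double.xmin
  list(s = s, n_star = n_star, b_star = b[n_star], log_s = log_s)
}

#' Exact mHG p-value
#'
#' P(mHG <= s) over all C(N, B) equiprobable arrangements of the label
#' vector, by dynamic programming over the (n, b) lattice.  Never reported
#' as 0: underflow is floored at the smallest positive normal double with a
#' message.
#'
#' @param s Observed mHG score in (0, 1].
#' @param N Universe size.
#' @param B Number of set members.
#' @param log_s Optional natural log of the observed score; supply it (e.g.
#'   from \code{\link{mhg_statistic}}) when \code{s} may have underflowed.
#' @return Exact p-value in (0, 1]; clamped to be at least \code{s} (the
#'   structural lower bound) and floored at the smallest positive normal
#'   double with a message when it underflows.
#' @examples
#' mhg_exact_pvalue(1/6, 4, 2)  # 1/6
#' @export
mhg_exact_pvalue <- function(s, N, B, log_s = NULL) {
  if (is.null(log_s)) {
    if (!is.finite(s) || s <= 0 || s > 1) stop("s must lie in (0, 1]")
    log_s <- log(s)
  }
  p <- mhg_pvalue_cpp(log_s, as.integer(N), as.integer(B))
  p <- max(p, s)
  if (p == 0) {
    message("mHG p-value underflowed; floored at .Machine$double.xmin")
    p <- .Machine$double.xmin
  }
  p
}

#' Gene-set enrichment over a ranked list
#'
#' For each set: intersect with the ranking universe (sets with empty
#' intersection are skipped with a warning), build the label vector, compute
#' the mHG score and exact p-value, then BH-adjust across all tested sets.
#'
#' @param ranking A \code{ranked_list} (see \code{\link{spearman_rank_genes}})
#'   or a character vector of gene ids ordered top first.
#' @param sets A \code{gene_set_collection}.
#' @return A data.frame of class \code{enrichment_result} with columns
#'   \code{set_name}, \code{s}, \code{n_star}, \code{b_star}, \code{p_exact},
#'   \code{q}, \code{direction}, sorted by ascending \code{p_exact} then set
#'   name.
#' @export
enrich_ranked_list <- function(ranking, sets) {
  genes <- if (inherits(ranking, "ranked_list")) ranking$gene
           else as.character(ranking)
  if (!length(genes)) stop("empty ranking universe")
  direction <- direction_label(
    if (inherits(ranking, "ranked_list")) attr(ranking, "direction") else NULL)
  N <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    lambda <- genes %in% sets[[nm]]
    B <- sum(lambda)
    if (B == 0L) {
      warning("set '", nm, "' has empty intersection with the universe; skipped")
      return(NULL)
    }
    st <- mhg_statistic(lambda)
    data.frame(set_name = nm, s = st$s, n_star = st$n_star,
               b_star = st$b_star,
               p_exact = mhg_exact_pvalue(st$s, N, B, log_s = st$log_s),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- data.frame(set_name = character(0), s = numeric(0),
                      n_star = integer(0), b_star = integer(0),
                      p_exact = numeric(0), q = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_exact)
  out$direction <- direction
  out <- out[order(out$p_exact, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

direction_label <- function(tag) {
  switch(tag %||% "ranked",
         descending_correlation = "correlated",
         ascending_correlation = "anti-correlated",
         "ranked")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
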