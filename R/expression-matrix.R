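#' Construct an expression matrix
#'
#' The basic substrate of the pipeline: a feature-by-sample matrix of finite
#' real intensities with a scale tag (\code{"linear"} or \code{"log2"}) and an
#' optional matrix of present/absent detection calls of identical shape.
#'
#' @param values Numeric matrix with unique, non-empty rownames (feature ids)
#'   and colnames (sample ids); every entry must be finite.
#' @param scale Either \code{"linear"} or \code{"log2"}.
#' @param detection Optional logical matrix of the same shape as \code{values}
#'   giving present (\code{TRUE}) / absent (\code{FALSE}) detection calls.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{scale} and \code{detection}.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("s1", "s2"))), scale = "linear")
#' dim(m)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              detection = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop("non-finite value at feature '", fid[i[1L]],
         "', sample '", sid[i[2L]], "'")
  }
  if (!is.null(detection)) {
    if (!is.logical(detection) || !identical(dim(detection), dim(values)))
      stop("'detection' must be a logical matrix of the same shape as 'values'")
    dimnames(detection) <- dimnames(values)
  }
  structure(list(values = values, scale = scale, detection = detection),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature ids of an expression matrix
#' @param x An \code{ExpressionMatrix}.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An \code{ExpressionMatrix}.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s scale)%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection)) "" else ", with detection calls"))
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param x An \code{ExpressionMatrix}.
#' @param i Feature index (integer, logical or character).
#' @param j Sample index (integer, logical or character).
#' @param ... Unused.
#' @return An \code{ExpressionMatrix} restricted to the selected rows/columns.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE], scale = x$scale,
                    detection = if (is.null(x$detection)) NULL
                                else x$detection[i, j, drop = FALSE])
}
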