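#' Binarize an expression matrix
#'
#' Converts real-valued expression data into the 0/1 matrix the biclustering
#' engine operates on, following the Bimax preprocessing idea: a cell becomes
#' 1 when its expression value is strictly greater than a min/max-derived
#' threshold, otherwise 0.
#'
#' Modes:
#' \describe{
#'   \item{`per_gene_midpoint`}{threshold `(row_min + row_max) / 2` computed
#'     per gene (the default; a gene "reacts" where it sits in the upper half
#'     of its own dynamic range). A constant gene yields an all-zero row
#'     because the comparison is strict.}
#'   \item{`global_midpoint`}{one threshold `(min + max) / 2` from the whole
#'     matrix.}
#'   \item{`as_printed`}{the literal formula `x_min + (x_max + x_min) / 2`
#'     applied per gene. Note this exceeds `x_max` whenever
#'     `3 * x_min > x_max`, so it can zero out rows with large positive
#'     minima; it is retained for fidelity experiments only.}
#' }
#'
#' @param x an [expression_matrix()].
#' @param mode one of `"per_gene_midpoint"`, `"global_midpoint"`,
#'   `"as_printed"`.
#' @return a [binary_matrix()] with the same labels.
#' @export
#' @examples
#' x <- expression_matrix(rbind(c(1, 3), c(5, 5)))
#' binarize(x)$values
binarize <- function(x, mode = c("per_gene_midpoint", "global_midpoint",
                                 "as_printed")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mode <- match.arg(mode)
  v <- x$values
  thr <- switch(
    mode,
    per_gene_midpoint = {
      t_row <- (apply(v, 1L, min) + apply(v, 1L, max)) / 2
      matrix(t_row, nrow(v), ncol(v))
    },
    global_midpoint = matrix((min(v) + max(v)) / 2, nrow(v), ncol(v)),
    as_printed = {
      rmin <- apply(v, 1L, min)
      rmax <- apply(v, 1L, max)
      t_row <- rmin + (rmax + rmin) / 2
      matrix(t_row, nrow(v), ncol(v))
    }
  )
  b <- (v > thr) * 1L
  dimnames(b) <- dimnames(v)
  binary_matrix(b)
}
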