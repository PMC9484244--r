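#' Difference value between two binary rows
#'
#' The difference value between a seed row and another row is the number of
#' positions where the two 0/1 vectors disagree (Hamming distance):
#' `DV(s, i) = sum_j (x_ij XOR x_sj)`.
#'
#' @param a,b binary vectors of equal length.
#' @return non-negative integer count of mismatching positions.
#' @export
#' @examples
#' row_difference_value(c(1, 1, 0, 0), c(1, 1, 1, 0)) # 1
row_difference_value <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  .check_binary_vec(a); .check_binary_vec(b)
  sum(a != b)
}

.check_binary_vec <- function(v) {
  if (!all(v %in% c(0, 1))) stop("vector is not binary", call. = FALSE)
  invisible(v)
}

#' Row adjacency difference matrix
#'
#' The n-by-n symmetric matrix of pairwise difference values between the
#' rows of a binary matrix.
#'
#' @param E a [binary_matrix()].
#' @return an integer matrix of class `DifferenceMatrix` with attribute
#'   `axis = "row"`; symmetric with a zero diagonal.
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' row_difference_matrix(E) # (0, 1; 1, 0)
row_difference_matrix <- function(E) {
  stopifnot(inherits(E, "BinaryMatrix"))
  d <- .pairwise_hamming(E$values)
  dimnames(d) <- list(E$gene_labels, E$gene_labels)
  structure(d, class = c("DifferenceMatrix", class(d)), axis = "row")
}

#' Column adjacency difference matrix
#'
#' The m-by-m matrix of pairwise difference values between the columns of a
#' binary matrix, restricted to a row cluster.
#'
#' @param E a [binary_matrix()].
#' @param rows non-empty vector of row indices (the row cluster I').
#' @return an integer matrix of class `DifferenceMatrix` with attributes
#'   `axis = "column"` and `restricted_rows`.
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' column_difference_matrix(E, rows = c(1, 2))
column_difference_matrix <- function(E, rows) {
  stopifnot(inherits(E, "BinaryMatrix"))
  rows <- .check_rows(E, rows)
  d <- .pairwise_hamming(t(E$values[rows, , drop = FALSE]))
  dimnames(d) <- list(E$condition_labels, E$condition_labels)
  structure(d, class = c("DifferenceMatrix", class(d)), axis = "column",
            restricted_rows = rows)
}

#' @export
print.DifferenceMatrix <- function(x, ...) {
  cat(sprintf("%s adjacency difference matrix (%dx%d)\n",
              attr(x, "axis"), nrow(x), ncol(x)))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y)
  invisible(x)
}

# pairwise Hamming distances between the rows of a 0/1 matrix; for binary
# vectors d(i,j) = k_i + k_j - 2 <x_i, x_j>
.pairwise_hamming <- function(v) {
  k <- rowSums(v)
  d <- outer(k, k, "+") - 2 * tcrossprod(v)
  storage.mode(d) <- "integer"
  unname(d)
}

.check_rows <- function(E, rows) {
  rows <- sort(unique(as.integer(rows)))
  if (!length(rows)) stop("row subset must be non-empty", call. = FALSE)
  if (any(rows < 1L) || any(rows > nrow(E$values))) {
    stop("row indices out of bounds", call. = FALSE)
  }
  rows
}

#' Column values over a row cluster
#'
#' `CV_j` counts the 1s in column j over the rows of the cluster I'; the
#' column with the largest column value is the preferred column seed during
#' expansion.
#'
#' @inheritParams column_difference_matrix
#' @return integer vector of length m with attribute `restricted_rows`.
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' column_values(E, rows = c(1, 2)) # 2 2 1 0
column_values <- function(E, rows) {
  stopifnot(inherits(E, "BinaryMatrix"))
  rows <- .check_rows(E, rows)
  cv <- colSums(E$values[rows, , drop = FALSE])
  storage.mode(cv) <- "integer"
  names(cv) <- E$condition_labels
  structure(cv, restricted_rows = rows)
}
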