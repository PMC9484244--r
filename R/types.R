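#' Construct an expression matrix
#'
#' A real-valued gene-by-condition matrix with unique labels on both axes.
#' Rows are genes, columns are conditions; values are assumed to be
#' pre-processed expression measurements (the package performs no
#' normalisation or log-transform).
#'
#' @param values numeric matrix, genes in rows and conditions in columns.
#' @param gene_labels character vector of row labels; defaults to existing
#'   rownames or `g1..gn`.
#' @param condition_labels character vector of column labels; defaults to
#'   existing colnames or `c1..cm`.
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `gene_labels`, `condition_labels`.
#' @export
#' @examples
#' x <- expression_matrix(matrix(rnorm(6), 2, 3))
#' dim(x$values)
expression_matrix <- function(values, gene_labels = NULL,
                              condition_labels = NULL) {
  m <- .as_labelled_matrix(values, gene_labels, condition_labels, "g", "c")
  if (anyNA(m)) {
    stop("expression matrix contains missing values; impute or drop them ",
         "before loading", call. = FALSE)
  }
  structure(
    list(values = m, gene_labels = rownames(m), condition_labels = colnames(m)),
    class = c("ExpressionMatrix", "ambb_matrix")
  )
}

#' Construct a binary matrix
#'
#' The substrate of the biclustering algorithm: a 0/1 gene-by-condition
#' matrix, where 1 marks a gene reacting under a condition.
#'
#' @inheritParams expression_matrix
#' @return an object of class `BinaryMatrix` with fields `values`,
#'   `gene_labels`, `condition_labels`.
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
binary_matrix <- function(values, gene_labels = NULL,
                          condition_labels = NULL) {
  m <- .as_labelled_matrix(values, gene_labels, condition_labels, "g", "c")
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf(
      "binary matrix entry [%s, %s] (row '%s', column '%s') is %s, not 0/1",
      i, j, rownames(m)[i], colnames(m)[j], format(m[i, j])), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  structure(
    list(values = m, gene_labels = rownames(m), condition_labels = colnames(m)),
    class = c("BinaryMatrix", "ambb_matrix")
  )
}

.as_labelled_matrix <- function(values, gene_labels, condition_labels,
                                rprefix, cprefix) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("matrix values must be numeric", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("matrix must have at least one row and one column", call. = FALSE)
  }
  if (!is.null(gene_labels)) rownames(values) <- gene_labels
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(rprefix, seq_len(nrow(values)))
  }
  if (!is.null(condition_labels)) colnames(values) <- condition_labels
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(cprefix, seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("gene labels must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("condition labels must be unique", call. = FALSE)
  }
  values
}

#' @export
print.ambb_matrix <- function(x, ...) {
  kind <- if (inherits(x, "BinaryMatrix")) "binary" else "expression"
  cat(sprintf("%s matrix: %d genes x %d conditions\n",
              kind, nrow(x$values), ncol(x$values)))
  n <- min(6L, nrow(x$values)); m <- min(8L, ncol(x$values))
  print(x$values[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x$values) > n || ncol(x$values) > m) cat("...\n")
  invisible(x)
}

#' @export
dim.ambb_matrix <- function(x) dim(x$values)

#' Construct a bicluster
#'
#' A pair of index sets (rows, columns) into a host matrix. Indices are
#' 1-based, stored sorted and unique.
#'
#' @param rows integer vector of row indices.
#' @param cols integer vector of column indices.
#' @return an object of class `Bicluster` with fields `rows` and `cols`.
#' @export
#' @examples
#' bicluster(c(1, 2), c(1, 2))
bicluster <- function(rows, cols) {
  rows <- sort(unique(as.integer(rows)))
  cols <- sort(unique(as.integer(cols)))
  if (!length(rows) || !length(cols)) {
    stop("a bicluster must have at least one row and one column",
         call. = FALSE)
  }
  if (any(rows < 1L) || any(cols < 1L)) {
    stop("bicluster indices must be positive", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols), class = "Bicluster")
}

#' @export
print.Bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %dx%d\n  rows: %s\n  cols: %s\n",
              length(x$rows), length(x$cols),
              paste(x$rows, collapse = " "), paste(x$cols, collapse = " ")))
  invisible(x)
}

#' Construct a bicluster set
#'
#' An ordered collection of biclusters from one run; exact duplicates
#' (identical row and column sets) are removed, keeping the first occurrence.
#'
#' @param biclusters list of [bicluster()] objects.
#' @param provenance optional list describing how the set was produced
#'   (e.g. the parameters of the run).
#' @return an object of class `BiclusterSet`.
#' @export
bicluster_set <- function(biclusters = list(), provenance = NULL) {
  stopifnot(is.list(biclusters))
  for (b in biclusters) {
    if (!inherits(b, "Bicluster")) {
      stop("all members must be Bicluster objects", call. = FALSE)
    }
  }
  keys <- vapply(biclusters, .bicluster_key, character(1))
  keep <- !duplicated(keys)
  structure(list(biclusters = biclusters[keep], provenance = provenance),
            class = "BiclusterSet")
}

.bicluster_key <- function(b) {
  paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","),
        sep = "|")
}

#' @export
length.BiclusterSet <- function(x) length(x$biclusters)

#' @export
print.BiclusterSet <- function(x, ...) {
  cat(sprintf("bicluster set: %d bicluster(s)\n", length(x)))
  for (i in seq_len(min(length(x), 10L))) {
    b <- x$biclusters[[i]]
    cat(sprintf("  [%d] %dx%d\n", i, length(b$rows), length(b$cols)))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

# TRUE iff the submatrix referenced by b is all ones
.is_all_ones <- function(values, b) {
  all(values[b$rows, b$cols] == 1L)
}
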