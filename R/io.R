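#' Read a gene-by-condition matrix from delimited text
#'
#' Expects a rectangular table with a header row of condition labels and a
#' first column of gene labels. The delimiter is inferred from the file
#' extension (`.csv` uses a comma, anything else a tab) unless given.
#'
#' @param path file to read.
#' @param kind `"expression"` for real-valued data or `"binary"` for a 0/1
#'   matrix; binary input is validated and a violating cell reported.
#' @param sep field delimiter; `NULL` (default) infers from the extension.
#' @return an [expression_matrix()] or [binary_matrix()].
#' @export
read_matrix <- function(path, kind = c("expression", "binary"), sep = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric values in ", path, call. = FALSE)
  }
  if (kind == "binary") binary_matrix(m) else expression_matrix(m)
}

#' Write a matrix as delimited text
#'
#' Inverse of [read_matrix()]: header row of condition labels, first column
#' of gene labels.
#'
#' @param x an `ExpressionMatrix` or `BinaryMatrix`.
#' @param path output file.
#' @param sep field delimiter; inferred from the extension when `NULL`.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "ambb_matrix"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bicluster set to text plus a JSON sidecar
#'
#' The text file lists, per bicluster, its shape and the gene and condition
#' labels; the sidecar `<path>.json` stores 0-based row/column indices and
#' the run provenance, and is what [read_biclusters()] parses back.
#'
#' @param bs a [bicluster_set()].
#' @param path output text file; the sidecar is written to `paste0(path, ".json")`.
#' @param matrix optional host matrix supplying labels for the text output;
#'   without it indices are printed instead of labels.
#' @export
write_biclusters <- function(bs, path, matrix = NULL) {
  stopifnot(inherits(bs, "BiclusterSet"))
  lines <- character(0)
  for (i in seq_len(length(bs))) {
    b <- bs$biclusters[[i]]
    if (!is.null(matrix)) {
      g <- matrix$gene_labels[b$rows]
      cc <- matrix$condition_labels[b$cols]
    } else {
      g <- as.character(b$rows)
      cc <- as.character(b$cols)
    }
    lines <- c(lines,
               sprintf("bicluster %d\tshape %dx%d", i,
                       length(b$rows), length(b$cols)),
               paste0("genes\t", paste(g, collapse = "\t")),
               paste0("conditions\t", paste(cc, collapse = "\t")),
               "")
  }
  writeLines(lines, path)
  sidecar <- list(
    n_biclusters = length(bs),
    provenance = bs$provenance,
    biclusters = lapply(bs$biclusters, function(b) {
      list(rows = b$rows - 1L, cols = b$cols - 1L)
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a bicluster set from a JSON sidecar
#'
#' @param path a sidecar file produced by [write_biclusters()] (0-based
#'   indices).
#' @return a [bicluster_set()].
#' @export
read_biclusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bcs <- obj$biclusters
  if (is.data.frame(bcs)) {
    bcs <- lapply(seq_len(nrow(bcs)), function(i) {
      list(rows = bcs$rows[[i]], cols = bcs$cols[[i]])
    })
  }
  bicluster_set(
    lapply(bcs, function(b) {
      bicluster(unlist(b$rows) + 1L, unlist(b$cols) + 1L)
    }),
    provenance = obj$provenance
  )
}
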