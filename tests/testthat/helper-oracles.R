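# Independent oracles used across the suite. Deliberately naive: double
# loops and exhaustive enumeration, never the package's own code paths.

rand_binary <- function(n, m, p = 0.5) {
  binary_matrix(matrix(rbinom(n * m, 1L, p), n, m))
}

# pairwise Hamming distances by explicit double loop
naive_row_distances <- function(v) {
  n <- nrow(v)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(v[i, ] != v[j, ])
    }
  }
  d
}

# rows within strict delta of the seed, by explicit scan
naive_expand_rows <- function(v, seed, delta) {
  keep <- seed
  for (i in seq_len(nrow(v))) {
    if (sum(v[i, ] != v[seed, ]) < delta) keep <- c(keep, i)
  }
  sort(unique(keep))
}

# All maximal all-ones submatrices (closed biclusters) of a small 0/1
# matrix, by enumerating every column subset and closing it.
enumerate_maximal_ones <- function(v) {
  m <- ncol(v)
  seen <- character(0)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    rows <- which(apply(v[, cols, drop = FALSE] == 1L, 1L, all))
    if (!length(rows)) next
    cols2 <- which(apply(v[rows, , drop = FALSE] == 1L, 2L, all))
    key <- paste(paste(rows, collapse = ","), paste(cols2, collapse = ","),
                 sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- c(out, list(list(rows = rows, cols = cols2)))
  }
  # drop closures contained in another closure
  maximal <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i != j && maximal[i] &&
          all(out[[i]]$rows %in% out[[j]]$rows) &&
          all(out[[i]]$cols %in% out[[j]]$cols) &&
          (length(out[[j]]$rows) > length(out[[i]]$rows) ||
           length(out[[j]]$cols) > length(out[[i]]$cols))) {
        maximal[i] <- FALSE
      }
    }
  }
  out[maximal]
}

contained_in_some_maximal <- function(b, maximals) {
  for (mx in maximals) {
    if (all(b$rows %in% mx$rows) && all(b$cols %in% mx$cols)) return(TRUE)
  }
  FALSE
}

# match score by explicit double loop over bicluster pairs (gene sets)
naive_match_score <- function(E1, E2) {
  best <- numeric(length(E1$biclusters))
  for (i in seq_along(E1$biclusters)) {
    g1 <- E1$biclusters[[i]]$rows
    js <- vapply(E2$biclusters, function(b2) {
      length(intersect(g1, b2$rows)) / length(union(g1, b2$rows))
    }, numeric(1))
    best[i] <- max(js)
  }
  mean(best)
}

worked_example_matrix <- function() {
  binary_matrix(rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L)))
}
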