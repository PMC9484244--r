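#' Parameters for an AMBB run
#'
#' @param delta non-negative integer row threshold: a row joins the seed's
#'   cluster when its difference value to the seed is strictly below `delta`.
#' @param lambda column-threshold policy: `"auto"` schedules lambda upward
#'   from 0 until `ceiling(r / 2)` (r = current row-cluster size) or a
#'   bicluster is obtained; a non-negative integer fixes it.
#' @param method `"a"` uses every row once as a seed; `"b"` takes seeds in
#'   descending 1-count order.
#' @param min_rows,min_cols minimum bicluster dimensions (default 2x2).
#' @param binarization mode passed to [binarize()] when the input is an
#'   expression matrix.
#' @param seed_masking if `TRUE`, rows already inside an accepted bicluster
#'   are skipped as seeds (greedy cover variant); default `FALSE` keeps every
#'   seed, maximizing pattern discovery, and relies on deduplication.
#' @param refine_lambda fixed column threshold used inside recursive
#'   refinement (default 1, the value normally used for bicluster
#'   acquisition); set to `"auto"` to schedule there too.
#' @return an object of class `AMBBParams`.
#' @export
ambb_params <- function(delta, lambda = "auto", method = c("b", "a"),
                        min_rows = 2L, min_cols = 2L,
                        binarization = "per_gene_midpoint",
                        seed_masking = FALSE, refine_lambda = 1L) {
  method <- match.arg(method)
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 0L) {
    stop("delta must be a non-negative integer", call. = FALSE)
  }
  .check_lambda <- function(l, what) {
    if (identical(l, "auto")) return(l)
    l <- as.integer(l)
    if (is.na(l) || l < 0L) {
      stop(what, " must be \"auto\" or a non-negative integer", call. = FALSE)
    }
    l
  }
  structure(list(
    delta = delta,
    lambda = .check_lambda(lambda, "lambda"),
    method = method,
    min_rows = as.integer(min_rows),
    min_cols = as.integer(min_cols),
    binarization = binarization,
    seed_masking = isTRUE(seed_masking),
    refine_lambda = .check_lambda(refine_lambda, "refine_lambda")
  ), class = "AMBBParams")
}

#' Select the seed row
#'
#' The seed is the non-excluded row with the highest number of 1s; ties are
#' broken by the lowest index. Returns `NULL` when every row is excluded or
#' the best available row contains no 1s.
#'
#' @param E a [binary_matrix()].
#' @param excluded row indices to skip.
#' @return integer row index, or `NULL`.
#' @export
select_seed <- function(E, excluded = integer(0)) {
  stopifnot(inherits(E, "BinaryMatrix"))
  counts <- rowSums(E$values)
  if (length(excluded)) counts[excluded] <- -1L
  if (all(counts <= 0L)) return(NULL)
  unname(which.max(counts))
}

#' Expand a seed into a row cluster
#'
#' Returns the seed together with every row whose difference value to the
#' seed is strictly below `delta`.
#'
#' @param E a [binary_matrix()].
#' @param seed row index of the seed.
#' @param delta non-negative integer row threshold.
#' @return sorted integer vector of row indices (always contains the seed).
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' expand_rows(E, seed = 2, delta = 2) # rows 1 and 2
expand_rows <- function(E, seed, delta) {
  stopifnot(inherits(E, "BinaryMatrix"))
  seed <- as.integer(seed)
  if (seed < 1L || seed > nrow(E$values)) {
    stop("seed out of bounds", call. = FALSE)
  }
  dv <- .dv_to_seed(E$values, seed)
  sort(unique(c(seed, which(dv < delta))))
}

# difference values from one row to all rows (one row of the row
# adjacency difference matrix, computed lazily)
.dv_to_seed <- function(v, seed) {
  as.integer(rowSums(v != matrix(v[seed, ], nrow(v), ncol(v), byrow = TRUE)))
}

#' Expand a row cluster into a column cluster
#'
#' The column with the largest column value over the row cluster becomes the
#' column seed (ties: lowest index). Under the `"auto"` policy the column
#' threshold lambda starts at 0 and increments until `ceiling(r / 2)` or a
#' candidate set of at least `min_cols` columns is obtained; a fixed lambda
#' is tried once. A column joins when its difference value to the column
#' seed, restricted to the row cluster, is strictly below lambda (the seed
#' itself is always a member).
#'
#' @param E a [binary_matrix()].
#' @param rows non-empty row cluster.
#' @param lambda `"auto"` or a fixed non-negative integer.
#' @param min_cols minimum number of columns for success.
#' @return `list(cols = <sorted indices>, lambda_used = <integer>)`, or
#'   `NULL` when no lambda in the schedule yields `min_cols` columns (e.g.
#'   the column seed has no matching column).
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' expand_columns(E, rows = c(1, 2)) # columns 1 and 2 at lambda = 1
expand_columns <- function(E, rows, lambda = "auto", min_cols = 2L) {
  stopifnot(inherits(E, "BinaryMatrix"))
  rows <- .check_rows(E, rows)
  .expand_columns_sub(E$values, rows, seq_len(ncol(E$values)), lambda,
                      min_cols)
}

# column expansion restricted to a candidate column set (used verbatim by
# the top-level pass, with cols = all columns, and by refinement)
.expand_columns_sub <- function(v, rows, cols, lambda, min_cols) {
  sub <- v[rows, cols, drop = FALSE]
  cv <- colSums(sub)
  if (max(cv) == 0L) return(NULL)
  seed_local <- which.max(cv)
  d <- colSums(sub != sub[, seed_local])
  r <- length(rows)
  lambdas <- if (identical(lambda, "auto")) 0:ceiling(r / 2) else as.integer(lambda)
  for (lam in lambdas) {
    sel <- sort(unique(c(seed_local, which(d < lam))))
    if (length(sel) >= min_cols) {
      return(list(cols = cols[sel], lambda_used = lam))
    }
  }
  NULL
}

#' Refine a candidate bicluster to an all-ones submatrix
#'
#' When the candidate's submatrix still contains 0s, the seed selection /
#' row expansion / column expansion steps are repeated inside the submatrix
#' until every element is 1. Termination is guaranteed by requiring the
#' submatrix to strictly shrink at each level; when a pass fails to shrink
#' it (or produces no candidate), the row or column containing the most 0s
#' is dropped instead (row first on ties) and refinement recurses.
#'
#' @param E a [binary_matrix()].
#' @param b a [bicluster()] valid for `E`.
#' @param params an [ambb_params()]; `delta` and `refine_lambda` drive the
#'   inner passes.
#' @param depth recursion depth (internal).
#' @return an all-ones [bicluster()] meeting `min_rows` x `min_cols`, or
#'   `NULL` when refinement falls below the minimum sizes.
#' @export
refine_bicluster <- function(E, b, params, depth = 0L) {
  stopifnot(inherits(E, "BinaryMatrix"), inherits(b, "Bicluster"),
            inherits(params, "AMBBParams"))
  v <- E$values
  if (depth > nrow(v) + ncol(v)) {
    stop("refinement failed to terminate (internal error)", call. = FALSE)
  }
  if (length(b$rows) < params$min_rows || length(b$cols) < params$min_cols) {
    return(NULL)
  }
  if (.is_all_ones(v, b)) {
    attr(b, "refine_depth") <- depth
    return(b)
  }

  nxt <- .refine_pass(v, b, params)
  shrank <- !is.null(nxt) &&
    (length(nxt$rows) < length(b$rows) || length(nxt$cols) < length(b$cols)) &&
    all(nxt$rows %in% b$rows) && all(nxt$cols %in% b$cols)
  if (!shrank) nxt <- .drop_max_zeros(v, b)
  if (is.null(nxt)) return(NULL)
  refine_bicluster(E, nxt, params, depth + 1L)
}

# one seed/expand pass restricted to b's submatrix; returns a Bicluster in
# global indices or NULL
.refine_pass <- function(v, b, params) {
  sub <- v[b$rows, b$cols, drop = FALSE]
  counts <- rowSums(sub)
  if (max(counts) == 0L) return(NULL)
  seed_local <- which.max(counts)
  dv <- as.integer(rowSums(sub != matrix(sub[seed_local, ], nrow(sub),
                                         ncol(sub), byrow = TRUE)))
  rows_local <- sort(unique(c(seed_local, which(dv < params$delta))))
  rows <- b$rows[rows_local]
  if (length(rows) < params$min_rows) return(NULL)
  cexp <- .expand_columns_sub(v, rows, b$cols, params$refine_lambda,
                              params$min_cols)
  if (is.null(cexp)) return(NULL)
  bicluster(rows, cexp$cols)
}

# termination fallback: drop the row or column with the most zeros
# (row first on ties); NULL when that would violate the minimum sizes
.drop_max_zeros <- function(v, b) {
  sub <- v[b$rows, b$cols, drop = FALSE]
  rz <- rowSums(sub == 0L)
  cz <- colSums(sub == 0L)
  drop_row <- max(rz) >= max(cz)
  if (drop_row) {
    if (length(b$rows) <= 1L) return(NULL)
    bicluster(b$rows[-which.max(rz)], b$cols)
  } else {
    if (length(b$cols) <= 1L) return(NULL)
    bicluster(b$rows, b$cols[-which.max(cz)])
  }
}

#' Run the AMBB biclustering algorithm
#'
#' For each seed the algorithm expands a row cluster under the row threshold
#' `delta`, expands a column cluster under the lambda policy, and refines the
#' candidate until its submatrix is all 1s. Method `"a"` uses every row once
#' as a seed in index order; method `"b"` takes rows in descending 1-count
#' order. Results below `min_rows` x `min_cols` are discarded and exact
#' duplicates removed, preserving first occurrence.
#'
#' @param E a [binary_matrix()], or an [expression_matrix()] (binarized
#'   first with `params$binarization`).
#' @param params an [ambb_params()].
#' @return a `RunReport`: list with `params`, `seeds_tried`, `biclusters`
#'   (a [bicluster_set()]), `refinement_depth_max` and `n_ops` (count of
#'   top-level difference-value / column-pass evaluations, for complexity
#'   diagnostics).
#' @export
#' @examples
#' E <- binary_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' run_ambb(E, ambb_params(delta = 2))$biclusters
run_ambb <- function(E, params) {
  stopifnot(inherits(params, "AMBBParams"))
  if (inherits(E, "ExpressionMatrix")) E <- binarize(E, params$binarization)
  stopifnot(inherits(E, "BinaryMatrix"))
  v <- E$values
  n <- nrow(v); m <- ncol(v)
  counts <- rowSums(v)
  seeds <- switch(params$method,
                  a = seq_len(n),
                  b = order(-counts, seq_len(n)))
  found <- list()
  keys <- character(0)
  covered <- logical(n)
  seeds_tried <- 0L
  depth_max <- 0L
  n_ops <- 0L

  for (s in seeds) {
    if (counts[s] == 0L) next
    if (params$seed_masking && covered[s]) next
    seeds_tried <- seeds_tried + 1L
    rows <- expand_rows(E, s, params$delta)
    n_ops <- n_ops + n                       # one DV per row against the seed
    if (length(rows) < params$min_rows) next
    cexp <- expand_columns(E, rows, params$lambda, params$min_cols)
    lam_tries <- if (is.null(cexp)) ceiling(length(rows) / 2) + 1L
                 else if (identical(params$lambda, "auto")) cexp$lambda_used + 1L
                 else 1L
    n_ops <- n_ops + m * lam_tries           # one column pass per lambda tried
    if (is.null(cexp)) next
    b <- refine_bicluster(E, bicluster(rows, cexp$cols), params)
    if (is.null(b)) next
    depth_max <- max(depth_max, attr(b, "refine_depth") %||% 0L)
    key <- .bicluster_key(b)
    if (key %in% keys) next
    keys <- c(keys, key)
    found <- c(found, list(b))
    if (params$seed_masking) covered[b$rows] <- TRUE
  }

  structure(list(
    params = params,
    seeds_tried = seeds_tried,
    biclusters = bicluster_set(found, provenance = unclass(params)),
    refinement_depth_max = depth_max,
    n_ops = n_ops
  ), class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf(
    "AMBB run: method %s, delta %d, %d seed(s) tried, %d bicluster(s)\n",
    x$params$method, x$params$delta, x$seeds_tried, length(x$biclusters)))
  invisible(x)
}

#' Semi-automatic row-threshold selection
#'
#' Runs the algorithm across a range of row thresholds and keeps the one
#' that yields the largest number of (unique) biclusters, with ties broken
#' toward the smallest threshold. The `"scan"` strategy evaluates every
#' value in the range; `"bisect"` probes the midpoint plus/minus a 1-percent
#' of-n half-width and recurses into the half whose probe yields more
#' biclusters, until the interval collapses.
#'
#' @param E a [binary_matrix()].
#' @param delta_range integer vector giving the candidate thresholds (scan)
#'   or its range (bisect).
#' @param params an [ambb_params()]; its `delta` is overridden.
#' @param strategy `"scan"` (default) or `"bisect"`.
#' @return list with `best_delta` and `diagnostics`, a data.frame of
#'   `(delta, n_biclusters)` for every threshold probed.
#' @export
search_row_threshold <- function(E, delta_range, params,
                                 strategy = c("scan", "bisect")) {
  stopifnot(inherits(E, "BinaryMatrix"), inherits(params, "AMBBParams"))
  strategy <- match.arg(strategy)
  delta_range <- sort(unique(as.integer(delta_range)))
  if (!length(delta_range)) stop("empty delta range", call. = FALSE)
  if (any(delta_range < 0L) || any(delta_range > ncol(E$values))) {
    stop("delta range must lie within [0, m]", call. = FALSE)
  }

  count_at <- local({
    cache <- new.env(parent = emptyenv())
    function(d) {
      key <- as.character(d)
      if (!is.null(cache[[key]])) return(cache[[key]])
      p <- params; p$delta <- as.integer(d)
      cache[[key]] <- length(run_ambb(E, p)$biclusters)
      cache[[key]]
    }
  })
  probed <- integer(0)

  if (strategy == "scan") {
    counts <- vapply(delta_range, count_at, integer(1))
    probed <- delta_range
    best <- delta_range[which.max(counts)]
  } else {
    lo <- min(delta_range); hi <- max(delta_range)
    w <- max(1L, floor(0.01 * nrow(E$values) + 0.5))
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      p_lo <- max(lo, mid - w); p_hi <- min(hi, mid + w)
      probed <- c(probed, p_lo, p_hi)
      if (count_at(p_lo) >= count_at(p_hi)) hi <- mid else lo <- mid
    }
    probed <- c(probed, lo, hi)
    best <- if (count_at(lo) >= count_at(hi)) lo else hi
  }

  probed <- sort(unique(probed))
  diagnostics <- data.frame(
    delta = probed,
    n_biclusters = vapply(probed, count_at, integer(1))
  )
  list(best_delta = best, diagnostics = diagnostics)
}

#' Recommended row-threshold scan window for an implant design
#'
#' For a background of 1-density `p` with implanted all-1 blocks of `w`
#' columns in an `m`-column matrix, pairwise row difference values split
#' into two populations: rows sharing a block differ only through
#' background noise, with mean `2 p (1 - p) (m - w)`, while rows of
#' different blocks additionally differ on the `2 w` block columns, with
#' mean `2 w (1 - p) + 2 p (1 - p) (m - 2 w)`. A useful row threshold sits
#' between the two, so the scan window runs from three binomial standard
#' deviations above the within-block mean to three below the between-block
#' mean. When density is so high that the two populations merge, the window
#' collapses to its lower end.
#'
#' @param n_cols number of columns m.
#' @param implant_cols implant width w in columns.
#' @param density background 1-density p.
#' @return integer vector of candidate thresholds for
#'   [search_row_threshold()], clipped to `[1, n_cols]`.
#' @export
#' @examples
#' recommended_delta_range(50, 10, 0.05)
recommended_delta_range <- function(n_cols, implant_cols, density) {
  m <- as.integer(n_cols); w <- as.integer(implant_cols)
  p <- density
  if (p < 0 || p > 1) stop("density must lie in [0, 1]", call. = FALSE)
  if (w > m) stop("implant_cols must not exceed n_cols", call. = FALSE)
  q <- 2 * p * (1 - p)                      # mismatch prob on a noise column
  mu_w <- q * (m - w)
  sd_w <- sqrt((m - w) * q * (1 - q))
  mu_b <- 2 * w * (1 - p) + q * max(m - 2 * w, 0)
  sd_b <- sqrt(2 * w * p * (1 - p) + max(m - 2 * w, 0) * q * (1 - q))
  lo <- max(1L, as.integer(ceiling(mu_w + 3 * sd_w)))
  hi <- as.integer(floor(mu_b - 3 * sd_b))
  lo <- min(lo, m)
  hi <- min(max(hi, lo), m)
  lo:hi
}
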