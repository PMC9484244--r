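#' Specification of a synthetic benchmark instance
#'
#' Describes the benchmark designs used to evaluate binary biclustering:
#' a Bernoulli 0/1 background (its 1-density plays the role of the noise
#' level) with implanted biclusters. Implants occupy a sampled,
#' not-necessarily-contiguous row subset and a contiguous column window.
#' Patterns: `constant_binary` writes all-1 blocks directly into the binary
#' background; `shift` (`a_ij = pi_i + beta_j`), `scale`
#' (`a_ij = pi_i * beta_j`) and `shift_scale` (`a_ij = pi_i * beta_j +
#' gamma_j`) produce expression-scale matrices over a standard-normal
#' background, with optional Gaussian noise on the implant cells.
#'
#' Defaults encode the 50x50 design with 5 disjoint 10x10 implants; larger
#' designs (100x100, 200x200) conventionally implant 10 blocks. Background
#' density is swept over 5--50% in benchmarks; the default here is the
#' lowest rung, 5%.
#'
#' @param n_rows,n_cols matrix size.
#' @param background_density fraction of 1s in the background, in \[0, 1\].
#' @param n_biclusters number of implanted blocks.
#' @param bicluster_shape integer pair `(rows, cols)` per implant.
#' @param pattern one of `"constant_binary"`, `"shift"`, `"scale"`,
#'   `"shift_scale"`.
#' @param noise_sd standard deviation of Gaussian noise added to implant
#'   cells of expression-scale patterns (ignored for `constant_binary`).
#' @param overlap `NULL` for pairwise-disjoint implants, or an integer pair
#'   `(rows, cols)`: consecutive implants share exactly that block.
#' @param rng_seed integer seed; identical spec and seed give a bit-identical
#'   instance.
#' @param row_effect_range,col_effect_range,shift_effect_range uniform
#'   ranges for the row effects `pi`, column effects `beta` and additive
#'   column effects `gamma`. The defaults keep implant values well above the
#'   background so midpoint binarization preserves implants at zero noise.
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_rows = 50L, n_cols = 50L,
                           background_density = 0.05,
                           n_biclusters = 5L,
                           bicluster_shape = c(10L, 10L),
                           pattern = c("constant_binary", "shift", "scale",
                                       "shift_scale"),
                           noise_sd = 0,
                           overlap = NULL,
                           rng_seed = 1L,
                           row_effect_range = c(4, 6),
                           col_effect_range = c(1, 2),
                           shift_effect_range = c(0, 1)) {
  pattern <- match.arg(pattern)
  if (background_density < 0 || background_density > 1) {
    stop("background_density must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  bicluster_shape <- as.integer(bicluster_shape)
  if (any(bicluster_shape < 1L) || bicluster_shape[1] > n_rows ||
      bicluster_shape[2] > n_cols) {
    stop("implants must fit inside the matrix", call. = FALSE)
  }
  if (!is.null(overlap)) {
    overlap <- as.integer(overlap)
    if (length(overlap) != 2L || any(overlap < 1L) ||
        any(overlap >= bicluster_shape)) {
      stop("overlap must be a (rows, cols) pair strictly smaller than ",
           "bicluster_shape", call. = FALSE)
    }
  }
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) stop("rng_seed must be an integer", call. = FALSE)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    background_density = background_density,
    n_biclusters = as.integer(n_biclusters),
    bicluster_shape = bicluster_shape,
    pattern = pattern, noise_sd = noise_sd, overlap = overlap,
    rng_seed = rng_seed,
    row_effect_range = row_effect_range,
    col_effect_range = col_effect_range,
    shift_effect_range = shift_effect_range
  ), class = "SyntheticSpec")
}

#' Generate a random binary background
#'
#' I.i.d. Bernoulli(`background_density`) entries from the generator seeded
#' with `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [binary_matrix()] of size `n_rows` x `n_cols`.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$rng_seed)
  v <- matrix(stats::rbinom(spec$n_rows * spec$n_cols, 1L,
                            spec$background_density),
              spec$n_rows, spec$n_cols)
  binary_matrix(v)
}

.sample_from <- function(x, size) x[sample.int(length(x), size)]

# Sample implant positions: each implant gets a row subset (non-contiguous
# allowed) and a contiguous column window. Disjoint designs make both row
# sets and column windows pairwise disjoint; overlap designs chain implants
# so consecutive pairs share exactly overlap[1] rows and overlap[2] columns
# and non-consecutive pairs share nothing. Consumes the current RNG stream.
.place_implants <- function(spec) {
  n <- spec$n_rows; m <- spec$n_cols; k <- spec$n_biclusters
  wr <- spec$bicluster_shape[1]; wc <- spec$bicluster_shape[2]
  if (is.null(spec$overlap)) {
    if (k * wr > n || k * wc > m) {
      stop("cannot place ", k, " disjoint ", wr, "x", wc, " implants in a ",
           n, "x", m, " matrix; use fewer or smaller implants",
           call. = FALSE)
    }
    perm <- sample.int(n)
    rows <- lapply(seq_len(k), function(i) {
      sort(perm[((i - 1L) * wr + 1L):(i * wr)])
    })
    extra <- m - k * wc
    offs <- sort(sample.int(extra + 1L, k, replace = TRUE) - 1L)
    cols <- lapply(seq_len(k), function(i) {
      start <- offs[i] + (i - 1L) * wc + 1L
      start:(start + wc - 1L)
    })
  } else {
    or <- spec$overlap[1]; oc <- spec$overlap[2]
    span <- wc + (k - 1L) * (wc - oc)
    need_rows <- wr + (k - 1L) * (wr - or)
    if (span > m || need_rows > n) {
      stop("overlapping implant chain does not fit; use fewer or smaller ",
           "implants", call. = FALSE)
    }
    if (k >= 3L && (or > wr - or || oc > wc - oc)) {
      stop("overlap block must be at most half the implant shape so that ",
           "only consecutive implants share cells", call. = FALSE)
    }
    start1 <- sample.int(m - span + 1L, 1L)
    cols <- lapply(seq_len(k), function(i) {
      start <- start1 + (i - 1L) * (wc - oc)
      start:(start + wc - 1L)
    })
    rows <- vector("list", k)
    used <- integer(0)
    prev2 <- integer(0)  # rows of implant i-2, excluded from the shared pick
    for (i in seq_len(k)) {
      if (i == 1L) {
        r <- .sample_from(seq_len(n), wr)
      } else {
        pool_shared <- setdiff(rows[[i - 1L]], prev2)
        shared <- .sample_from(pool_shared, or)
        fresh <- .sample_from(setdiff(seq_len(n), used), wr - or)
        r <- c(shared, fresh)
      }
      rows[[i]] <- sort(r)
      prev2 <- if (i >= 2L) rows[[i - 1L]] else integer(0)
      used <- union(used, rows[[i]])
    }
  }
  Map(function(r, c) list(rows = r, cols = c), rows, cols)
}

#' Implant all-1 biclusters into a binary background
#'
#' Writes 1s over each implant's cells and records the ground truth. The
#' placement RNG is seeded with `rng_seed + 1` so background and placement
#' are independently reproducible.
#'
#' @param background a [binary_matrix()], typically from
#'   [generate_background()].
#' @param spec a [synthetic_spec()] with `pattern = "constant_binary"`.
#' @return a `SyntheticInstance`: list with `matrix` (the [binary_matrix()]),
#'   `truth` (a [bicluster_set()] of the implants, in placement order) and
#'   `spec`.
#' @export
implant_biclusters <- function(background, spec) {
  stopifnot(inherits(background, "BinaryMatrix"),
            inherits(spec, "SyntheticSpec"))
  if (spec$pattern != "constant_binary") {
    stop("implant_biclusters handles constant_binary implants; use ",
         "generate_pattern_matrix() for expression-scale patterns",
         call. = FALSE)
  }
  if (nrow(background$values) != spec$n_rows ||
      ncol(background$values) != spec$n_cols) {
    stop("background size does not match the spec", call. = FALSE)
  }
  set.seed(spec$rng_seed + 1L)
  places <- .place_implants(spec)
  v <- background$values
  for (p in places) v[p$rows, p$cols] <- 1L
  dimnames(v) <- dimnames(background$values)
  structure(list(
    matrix = binary_matrix(v),
    truth = bicluster_set(lapply(places, function(p) {
      bicluster(p$rows, p$cols)
    }), provenance = list(generator = unclass(spec))),
    spec = spec
  ), class = "SyntheticInstance")
}

#' Generate an expression-scale pattern instance
#'
#' Standard-normal background with implanted shift / scale / shift-scale
#' blocks. Per implant, row effects `pi ~ U(row_effect_range)` and column
#' effects `beta ~ U(col_effect_range)`, `gamma ~ U(shift_effect_range)`
#' are drawn; implant cells follow the pattern algebra, plus
#' `N(0, noise_sd)` noise when `noise_sd > 0`.
#'
#' @param spec a [synthetic_spec()] with `pattern` in
#'   `"shift"`, `"scale"`, `"shift_scale"`.
#' @return a `SyntheticInstance` whose `matrix` is an
#'   [expression_matrix()].
#' @export
generate_pattern_matrix <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (!spec$pattern %in% c("shift", "scale", "shift_scale")) {
    stop("unknown pattern for generate_pattern_matrix: ", spec$pattern,
         call. = FALSE)
  }
  set.seed(spec$rng_seed)
  v <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
              spec$n_rows, spec$n_cols)
  places <- .place_implants(spec)
  for (p in places) {
    wr <- length(p$rows); wc <- length(p$cols)
    pi_ <- stats::runif(wr, spec$row_effect_range[1], spec$row_effect_range[2])
    beta <- stats::runif(wc, spec$col_effect_range[1], spec$col_effect_range[2])
    gamma <- stats::runif(wc, spec$shift_effect_range[1],
                          spec$shift_effect_range[2])
    block <- switch(spec$pattern,
      shift = outer(pi_, beta, "+"),
      scale = outer(pi_, beta, "*"),
      shift_scale = outer(pi_, beta, "*") +
        matrix(gamma, wr, wc, byrow = TRUE)
    )
    if (spec$noise_sd > 0) {
      block <- block + stats::rnorm(wr * wc, 0, spec$noise_sd)
    }
    v[p$rows, p$cols] <- block
  }
  structure(list(
    matrix = expression_matrix(v),
    truth = bicluster_set(lapply(places, function(p) {
      bicluster(p$rows, p$cols)
    }), provenance = list(generator = unclass(spec))),
    spec = spec
  ), class = "SyntheticInstance")
}

#' Generate a complete synthetic instance from a spec
#'
#' Dispatches on the spec's pattern: constant binary implants over a
#' Bernoulli background, or an expression-scale pattern matrix.
#'
#' @param spec a [synthetic_spec()].
#' @return a `SyntheticInstance`.
#' @export
simulate_instance <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$pattern == "constant_binary") {
    implant_biclusters(generate_background(spec), spec)
  } else {
    generate_pattern_matrix(spec)
  }
}

#' @export
print.SyntheticInstance <- function(x, ...) {
  cat(sprintf(
    "synthetic instance: %dx%d %s, density %.2f, %d implant(s) of %dx%d\n",
    x$spec$n_rows, x$spec$n_cols, x$spec$pattern,
    x$spec$background_density, x$spec$n_biclusters,
    x$spec$bicluster_shape[1], x$spec$bicluster_shape[2]))
  invisible(x)
}
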