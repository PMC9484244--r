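test_that("seed selection picks the row with most 1s, lowest index on ties", {
  E <- worked_example_matrix()
  expect_equal(select_seed(E), 2L)
  expect_null(select_seed(binary_matrix(matrix(0L, 3, 3))))
  tied <- binary_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 0, 1)))
  expect_equal(select_seed(tied), 1L)
  expect_equal(select_seed(tied, excluded = 1L), 2L)
  expect_null(select_seed(tied, excluded = 1:3))
})

test_that("row expansion keeps rows strictly under delta, plus the seed", {
  E <- worked_example_matrix()
  expect_equal(expand_rows(E, seed = 2, delta = 2), c(1L, 2L))
  expect_equal(expand_rows(E, seed = 2, delta = 1), 2L)
  # delta = 0: only rows identical to the seed would qualify (none strictly
  # below 0), so the seed alone survives
  expect_equal(expand_rows(E, seed = 1, delta = 0), 1L)

  withr::local_seed(31)
  for (rep in 1:10) {
    E2 <- rand_binary(12, 8)
    seed <- sample(12, 1); delta <- sample(0:8, 1)
    expect_equal(expand_rows(E2, seed, delta),
                 naive_expand_rows(E2$values, seed, delta))
  }
})

test_that("row expansion is monotone in delta", {
  withr::local_seed(17)
  for (rep in 1:10) {
    E <- rand_binary(10, 9)
    seed <- sample(10, 1)
    prev <- integer(0)
    for (delta in 0:9) {
      cur <- expand_rows(E, seed, delta)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("column expansion reproduces the worked example and its failure case", {
  E <- worked_example_matrix()
  got <- expand_columns(E, rows = 1:2, lambda = 1)
  expect_equal(got$cols, c(1L, 2L))

  # a column seed with no matching column within the threshold yields nothing
  lone <- binary_matrix(rbind(c(0, 1, 0, 0), c(0, 1, 1, 0), c(1, 0, 0, 1)))
  expect_null(expand_columns(lone, rows = 1:2, lambda = 1, min_cols = 3))

  # one all-ones row: every column is identical, all join at lambda = 1
  ones <- binary_matrix(rbind(c(1, 1, 1, 1), c(1, 0, 0, 0)))
  got2 <- expand_columns(ones, rows = 1L, lambda = "auto")
  expect_equal(got2$cols, 1:4)
  expect_equal(got2$lambda_used, 1L)
})

test_that("auto lambda schedule stops at ceiling(r/2)", {
  # two rows, columns all far from the seed column: schedule 0..1 fails
  E <- binary_matrix(rbind(c(1, 0, 0), c(1, 0, 0)))
  # col 1 is the seed (CV=2); cols 2,3 at distance 2; lambda max = 1
  expect_null(expand_columns(E, rows = 1:2, lambda = "auto", min_cols = 2))
  # with four rows the schedule reaches lambda = 2 and admits distance-1 cols
  E2 <- binary_matrix(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  got <- expand_columns(E2, rows = 1:4, lambda = "auto", min_cols = 2)
  expect_equal(got$cols, c(1L, 2L))
  expect_equal(got$lambda_used, 2L)
})

test_that("refinement is a fixed point on all-ones input and shrinks otherwise", {
  E <- worked_example_matrix()
  p <- ambb_params(delta = 2)
  b <- bicluster(1:2, 1:2)
  got <- refine_bicluster(E, b, p)
  expect_equal(got$rows, b$rows)
  expect_equal(got$cols, b$cols)

  # 3x3 with one 0: result must be an all-ones 2x3 or 3x2 contained in a
  # maximal all-ones submatrix of the instance
  v <- matrix(1L, 3, 3); v[1, 1] <- 0L
  E3 <- binary_matrix(v)
  maximals <- enumerate_maximal_ones(v)
  got3 <- refine_bicluster(E3, bicluster(1:3, 1:3), ambb_params(delta = 2))
  expect_true(all(E3$values[got3$rows, got3$cols] == 1L))
  expect_equal(sort(c(length(got3$rows), length(got3$cols))), c(2L, 3L))
  expect_true(contained_in_some_maximal(got3, maximals))

  # refinement falling below the minimum sizes returns NULL
  tiny <- binary_matrix(rbind(c(1, 0), c(0, 1)))
  expect_null(refine_bicluster(tiny, bicluster(1:2, 1:2),
                               ambb_params(delta = 1)))
})

test_that("run_ambb recovers the worked example bicluster and handles empty input", {
  E <- worked_example_matrix()
  rep_ <- run_ambb(E, ambb_params(delta = 2, method = "b"))
  expect_equal(length(rep_$biclusters), 1L)
  b <- rep_$biclusters$biclusters[[1]]
  expect_equal(b$rows, 1:2)
  expect_equal(b$cols, 1:2)
  expect_true(all(E$values[b$rows, b$cols] == 1L))

  z <- binary_matrix(matrix(0L, 4, 4))
  expect_equal(length(run_ambb(z, ambb_params(delta = 2))$biclusters), 0L)
})

test_that("an implanted all-ones block is recovered exactly on a clean background", {
  withr::local_seed(77)
  v <- matrix(0L, 30, 30)
  rows <- sort(sample(30, 10)); cols <- 11:20
  v[rows, cols] <- 1L
  E <- binary_matrix(v)
  truth <- bicluster_set(list(bicluster(rows, cols)))
  found <- run_ambb(E, ambb_params(delta = 3))$biclusters
  expect_equal(length(found), 1L)
  expect_equal(recovery(truth, found), 1)
  expect_equal(relevance(truth, found), 1)
})

test_that("every emitted bicluster is all-ones and within a maximal all-ones submatrix", {
  withr::local_seed(101)
  for (rep in 1:40) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    E <- rand_binary(n, m, p = runif(1, 0.3, 0.8))
    maximals <- enumerate_maximal_ones(E$values)
    for (method in c("a", "b")) {
      delta <- sample(1:m, 1)
      found <- run_ambb(E, ambb_params(delta = delta, method = method))
      for (b in found$biclusters$biclusters) {
        expect_true(all(E$values[b$rows, b$cols] == 1L))
        expect_true(contained_in_some_maximal(b, maximals))
      }
    }
  }
})

test_that("methods a and b agree on the deduplicated bicluster set without masking", {
  withr::local_seed(55)
  for (rep in 1:10) {
    E <- rand_binary(15, 10, p = 0.5)
    delta <- sample(2:6, 1)
    keys <- function(bs) sort(vapply(bs$biclusters, function(b) {
      paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","))
    }, character(1)))
    a <- run_ambb(E, ambb_params(delta = delta, method = "a"))$biclusters
    b <- run_ambb(E, ambb_params(delta = delta, method = "b"))$biclusters
    expect_true(all(keys(b) %in% keys(a)))
  }
})

test_that("operation counts respect the advertised complexity bound", {
  withr::local_seed(61)
  for (rep in 1:5) {
    n <- sample(10:25, 1); m <- sample(8:20, 1)
    E <- rand_binary(n, m, 0.4)
    r <- run_ambb(E, ambb_params(delta = sample(1:5, 1)))
    bound <- max(n^2, n * m * (ceiling(n / 2) + 1))
    expect_lte(r$n_ops, 2 * bound)
  }
})

test_that("threshold search finds the only productive delta and keeps diagnostics", {
  # the two block rows differ in 2 positions, so only delta >= 3 joins them;
  # the spoiler row never joins anything at these deltas
  E <- binary_matrix(rbind(
    c(1, 1, 1, 0, 0, 0),
    c(1, 1, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0)
  ))
  # exhaustive scan oracle: count biclusters for each delta the slow way
  oracle_counts <- vapply(0:4, function(d) {
    length(run_ambb(E, ambb_params(delta = d))$biclusters)
  }, integer(1))
  best_oracle <- (0:4)[which.max(oracle_counts)]
  got <- search_row_threshold(E, 0:4, ambb_params(delta = 0))
  expect_equal(got$best_delta, best_oracle)
  expect_equal(nrow(got$diagnostics), 5L)
  expect_equal(got$diagnostics$n_biclusters, oracle_counts)

  one <- search_row_threshold(E, 3, ambb_params(delta = 0))
  expect_equal(one$best_delta, 3L)
})

test_that("bisect strategy lands on a count-maximizing plateau", {
  withr::local_seed(19)
  inst <- simulate_instance(synthetic_spec(background_density = 0.05,
                                           rng_seed = 3))
  scan <- search_row_threshold(inst$matrix, 10:16, ambb_params(delta = 1))
  bis <- search_row_threshold(inst$matrix, 10:16, ambb_params(delta = 1),
                              strategy = "bisect")
  best_count <- max(scan$diagnostics$n_biclusters)
  bis_count <- scan$diagnostics$n_biclusters[
    scan$diagnostics$delta == bis$best_delta]
  # bisect probes a subset of the range; it must return a probed delta whose
  # count is within the observed spread
  expect_true(bis$best_delta %in% 10:16)
  expect_lte(bis_count, best_count)
})
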