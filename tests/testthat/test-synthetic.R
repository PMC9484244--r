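test_that("background density behaves at the extremes and in expectation", {
  z <- generate_background(synthetic_spec(background_density = 0,
                                          n_biclusters = 1))
  expect_true(all(z$values == 0L))
  o <- generate_background(synthetic_spec(background_density = 1,
                                          n_biclusters = 1))
  expect_true(all(o$values == 1L))
  big <- generate_background(synthetic_spec(n_rows = 200, n_cols = 200,
                                            background_density = 0.3,
                                            n_biclusters = 1, rng_seed = 8))
  d <- mean(big$values)
  sd3 <- 3 * sqrt(0.3 * 0.7 / (200 * 200))
  expect_lt(abs(d - 0.3), sd3)
})

test_that("disjoint implants write exactly k all-ones blocks on a clean background", {
  spec <- synthetic_spec(background_density = 0, rng_seed = 4)
  inst <- implant_biclusters(generate_background(spec), spec)
  expect_equal(sum(inst$matrix$values), 500L)
  expect_equal(length(inst$truth), 5L)
  rowsets <- lapply(inst$truth$biclusters, `[[`, "rows")
  colsets <- lapply(inst$truth$biclusters, `[[`, "cols")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(length(intersect(rowsets[[i]], rowsets[[j]])), 0L)
    expect_equal(length(intersect(colsets[[i]], colsets[[j]])), 0L)
  }
  for (b in inst$truth$biclusters) {
    expect_true(all(inst$matrix$values[b$rows, b$cols] == 1L))
    expect_equal(diff(range(b$cols)), 9L)  # contiguous column window
  }
})

test_that("overlap layouts share exactly the requested block between consecutive implants", {
  for (ov in list(c(2L, 5L), c(5L, 5L))) {
    spec <- synthetic_spec(n_rows = 60, n_cols = 60,
                           background_density = 0.05, n_biclusters = 5,
                           overlap = ov, rng_seed = 12)
    inst <- simulate_instance(spec)
    tb <- inst$truth$biclusters
    for (i in seq_len(4)) {
      expect_equal(length(intersect(tb[[i]]$rows, tb[[i + 1]]$rows)), ov[1])
      expect_equal(length(intersect(tb[[i]]$cols, tb[[i + 1]]$cols)), ov[2])
    }
    for (i in 1:3) for (j in (i + 2):5) {
      shared_cells <- length(intersect(tb[[i]]$rows, tb[[j]]$rows)) *
        length(intersect(tb[[i]]$cols, tb[[j]]$cols))
      expect_equal(shared_cells, 0L)
    }
    for (b in tb) expect_true(all(inst$matrix$values[b$rows, b$cols] == 1L))
  }
})

test_that("identical spec and seed give bit-identical instances", {
  spec <- synthetic_spec(background_density = 0.2, rng_seed = 99)
  a <- simulate_instance(spec)
  b <- simulate_instance(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$biclusters, b$truth$biclusters)
  p <- synthetic_spec(pattern = "shift", rng_seed = 7)
  expect_identical(simulate_instance(p)$matrix$values,
                   simulate_instance(p)$matrix$values)
})

test_that("shift implants have constant column offsets, scale implants proportional columns", {
  shift <- simulate_instance(synthetic_spec(pattern = "shift", rng_seed = 5))
  b <- shift$truth$biclusters[[1]]
  block <- shift$matrix$values[b$rows, b$cols]
  offs <- block[, -1, drop = FALSE] - block[, 1]
  expect_true(all(abs(sweep(offs, 2, offs[1, ])) < 1e-10))

  scale_ <- simulate_instance(synthetic_spec(pattern = "scale", rng_seed = 5))
  b2 <- scale_$truth$biclusters[[1]]
  block2 <- scale_$matrix$values[b2$rows, b2$cols]
  ratios <- block2[, -1, drop = FALSE] / block2[, 1]
  expect_true(all(abs(sweep(ratios, 2, ratios[1, ])) < 1e-10))

  ss <- simulate_instance(synthetic_spec(pattern = "shift_scale",
                                         rng_seed = 5))
  b3 <- ss$truth$biclusters[[1]]
  block3 <- ss$matrix$values[b3$rows, b3$cols]
  # shift-scale columns are affine images of each other: a_ij = pi_i b_j + g_j
  for (j in 2:ncol(block3)) {
    fit <- stats::lm(block3[, j] ~ block3[, 1])
    expect_lt(max(abs(stats::residuals(fit))), 1e-8)
  }
})

test_that("binarized strong-signal pattern implants are recovered end to end", {
  inst <- simulate_instance(synthetic_spec(pattern = "shift", noise_sd = 0,
                                           rng_seed = 21))
  E <- binarize(inst$matrix)
  p <- ambb_params(delta = 1)
  p$delta <- search_row_threshold(E, recommended_delta_range(50, 10, 0.05),
                                  p)$best_delta
  found <- run_ambb(E, p)$biclusters
  expect_gt(recovery(inst$truth, found), 0.9)
})

test_that("infeasible placements fail with guidance", {
  expect_error(synthetic_spec(n_rows = 15, bicluster_shape = c(20, 10)),
               "fit")
  spec <- synthetic_spec(n_rows = 30, n_cols = 30, n_biclusters = 5,
                         background_density = 0)
  expect_error(implant_biclusters(generate_background(spec), spec),
               "fewer or smaller")
})
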