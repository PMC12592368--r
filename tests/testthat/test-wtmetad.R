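test_that("coordination number switching function", {
  expect_equal(coordination_number(0, 0.275), 1)
  expect_equal(coordination_number(0.275, 0.275), 0.5)       # removable singularity
  expect_equal(coordination_number(0.55, 0.275), 63 / 4095)  # = (1-64)/(1-4096)
  # sums over the provided distances, each term monotone decreasing
  d <- seq(0.1, 0.6, by = 0.05)
  terms <- purrr::map_dbl(d, coordination_number, r0 = 0.275)
  expect_true(all(diff(terms) < 0))
  expect_equal(coordination_number(d, 0.275), sum(terms))
  expect_error(coordination_number(0.2, 0), "r0")
  expect_error(coordination_number(-0.1, 0.275), "distances")
})

test_that("flat-bottom restraint energy", {
  r <- restraint_spec("flat_bottom_cylinder", axis = c(0, 1, 0),
                      R_cyl = 0.7, K_res = 1e5)
  expect_equal(flat_bottom_energy(c(0.35, 0.2, 0), r), 0)
  expect_equal(flat_bottom_energy(c(0.71, 0.5, 0), r), 0.5 * 1e5 * 1e-4,
               tolerance = 1e-9)
  # cylindrical symmetry
  th <- seq(0, 2 * pi, length.out = 9)
  pts <- cbind(0.9 * cos(th), 0.3, 0.9 * sin(th))
  expect_lt(diff(range(flat_bottom_energy(pts, r))), 1e-9)
  # continuity of value and first derivative at the boundary
  eps <- 1e-7
  e_in <- flat_bottom_energy(c(0.7 - eps, 0, 0), r)
  e_out <- flat_bottom_energy(c(0.7 + eps, 0, 0), r)
  expect_lt(abs(e_out - e_in), 1e-6)
})

test_that("well-tempered height rule", {
  RT <- 2.577
  expect_equal(well_tempered_height(0.773, 0, 5, RT), 0.773)
  expect_equal(well_tempered_height(1, (5 - 1) * RT, 5, RT), exp(-1))
  expect_equal(well_tempered_height(1, 50, 1e9, RT), 1, tolerance = 1e-6)
  expect_error(well_tempered_height(1, 0, 1, RT), "gamma")
})

test_that("unbiased sampler satisfies equipartition on a harmonic well", {
  k <- 50
  pot <- model_potential("double_well_1d", anchor_positions = 0,
                         well_depths = 0,
                         restraint = restraint_spec("harmonic_point",
                                                    K_res = k, origin = 0))
  p <- sampler_params(n_steps = 1e6, seed = 7, h0 = 0, dt = 2e-4,
                      record_stride = 5)
  out <- run_wtmetad(pot, dw_cv(), p, n_walkers = 1,
                     bias_grid = grid_spec("x", -2, 2, 100),
                     init = matrix(0))
  v <- var(out$trajectories[[1]]$x1)
  expect_lt(abs(v - 2.577 / k) / (2.577 / k), 0.05)
})

test_that("runs are reproducible and walker count matters", {
  pot <- dw_potential()
  p <- sampler_params(n_steps = 2e4, seed = 99)
  a <- run_wtmetad(pot, dw_cv(), p, n_walkers = 2)
  b <- run_wtmetad(pot, dw_cv(), p, n_walkers = 2)
  expect_identical(a$trajectories[[1]]$x1, b$trajectories[[1]]$x1)
  expect_identical(a$bias$height, b$bias$height)
  c3 <- run_wtmetad(pot, dw_cv(), p, n_walkers = 3)
  expect_false(identical(a$trajectories[[1]]$x1, c3$trajectories[[1]]$x1))
})

test_that("zero-bias stationary histogram matches the Boltzmann density", {
  pot <- dw_potential(depths = c(6, 5), widths = 0.25)
  p <- sampler_params(n_steps = 2e6, seed = 13, h0 = 0, record_stride = 20)
  out <- run_wtmetad(pot, dw_cv(), p, n_walkers = 1,
                     init = matrix(1.25))
  x <- out$trajectories[[1]]$x1
  # analytic CDF on a fine grid (restraint included)
  xs <- seq(-0.5, 3.0, by = 1e-3)
  w <- exp(-eval_potential(pot, matrix(xs, ncol = 1)) / 2.577)
  cdf <- cumsum(w) / sum(w)
  ks <- max(abs(purrr::map_dbl(seq(0, 2.5, by = 0.05), function(q) {
    mean(x <= q) - cdf[findInterval(q, xs)]
  })))
  expect_lt(ks, 0.05)
})

test_that("deposited heights follow the well-tempered rule exactly (exact bias)", {
  pot <- dw_potential()
  p <- sampler_params(n_steps = 3e4, seed = 3, deposit_stride = 1000)
  out <- run_wtmetad(pot, dw_cv(), p, n_walkers = 2, exact_bias = TRUE)
  hills <- out$bias
  RT <- 2.577
  for (i in seq_len(nrow(hills))) {
    prev <- bias_state(hills[seq_len(i - 1), , drop = FALSE],
                       gamma = 5, cv_names = "x")
    v <- unname(ionbindr:::bias_at(prev, matrix(hills$x[i], 1, 1), exact = TRUE))
    # C++ truncates hill tails at 5 sigma; the R oracle sums them fully,
    # hence the 1e-6 relative tolerance
    expect_equal(hills$height[i],
                 well_tempered_height(p$h0, v, 5, RT), tolerance = 1e-6)
  }
  # heights bounded by h0 and decaying at a repeatedly visited basin
  expect_true(all(hills$height <= p$h0 + 1e-12))
  left <- hills[hills$x < 1.25, ]
  expect_lt(mean(tail(left$height, 5)), mean(head(left$height, 5)))
})

test_that("total bias is non-negative and non-decreasing in time", {
  pot <- dw_potential()
  p <- sampler_params(n_steps = 2e4, seed = 4, deposit_stride = 1000)
  out <- run_wtmetad(pot, dw_cv(), p, n_walkers = 1)
  pts <- matrix(seq(0, 2.5, by = 0.25), ncol = 1)
  prev <- numeric(nrow(pts))
  for (i in seq_len(nrow(out$bias))) {
    cur <- ionbindr:::bias_at(
      bias_state(out$bias[seq_len(i), , drop = FALSE], gamma = 5, cv_names = "x"),
      pts, exact = TRUE)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("grid bias cache agrees with exact hill summation", {
  pot <- dw_potential()
  p <- sampler_params(n_steps = 1e5, seed = 21, deposit_stride = 2000)
  cache <- run_wtmetad(pot, dw_cv(), p, n_walkers = 2)
  pts <- matrix(seq(0.1, 2.4, by = 0.1), ncol = 1)
  v_exact <- ionbindr:::bias_at(cache$bias, pts, exact = TRUE)
  v_trunc <- ionbindr:::bias_at(cache$bias, pts, exact = FALSE)
  expect_equal(v_trunc, v_exact, tolerance = 1e-6)
})

test_that("COLVAR and HILLS files round-trip", {
  hills <- tibble::tibble(time = c(100, 200, 300),
                          x = c(0.2, 0.4, 0.6), sigma_x = 0.05,
                          height = c(0.77, 0.71, 0.68), biasf = 5)
  b <- bias_state(hills, gamma = 5)
  f <- withr::local_tempfile()
  write_hills(b, f)
  b2 <- read_hills(f)
  expect_equal(b2$x, hills$x)
  expect_equal(b2$height, hills$height)
  expect_equal(attr(b2, "gamma"), 5)

  # COLVAR fixture with three CVs
  fc <- withr::local_tempfile()
  writeLines(c("#! FIELDS time L1 L2 CNW",
               "0 1.0 1.2 5.5", "10 0.9 1.1 5.4", "20 0.8 1.0 5.2"), fc)
  tr <- read_colvar(fc)
  expect_equal(attr(tr, "cv_names"), c("L1", "L2", "CNW"))
  expect_equal(nrow(tr), 3)
  expect_equal(tr$CNW[3], 5.2)

  # trajectory round trip at declared precision
  ft <- withr::local_tempfile()
  write_colvar(tr, ft)
  tr2 <- read_colvar(ft)
  expect_equal(tr2$L1, tr$L1)

  # unknown columns preserved
  fx <- withr::local_tempfile()
  writeLines(c("#! FIELDS time L1 extra.bias", "0 1.0 2.5"), fx)
  trx <- read_colvar(fx)
  expect_true("extra.bias" %in% names(trx))
})

test_that("PLUMED-dialect format errors are reported", {
  f <- withr::local_tempfile()
  writeLines(c("0 1.0", "10 0.9"), f)
  expect_error(read_colvar(f), "FIELDS")
  f2 <- withr::local_tempfile()
  writeLines(c("#! FIELDS time x", "0 1.0", "10"), f2)
  expect_error(read_colvar(f2), "line 3")
  f3 <- withr::local_tempfile()
  writeLines(c("#! FIELDS time x sigma_x height", "0 1 0.05 0.7"), f3)
  expect_silent(read_hills(f3))
})
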