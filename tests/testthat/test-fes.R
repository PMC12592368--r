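empty_bias <- function(cv = "x") {
  cols <- setNames(list(numeric(0), numeric(0), numeric(0), numeric(0)),
                   c("time", cv, paste0("sigma_", cv), "height"))
  bias_state(tibble::as_tibble(cols), gamma = 5, cv_names = cv)
}

fake_traj <- function(x, cv = "x") {
  tr <- tibble::tibble(step = seq_along(x))
  tr[[cv]] <- x
  attr(tr, "cv_names") <- cv
  tr
}

test_that("zero-bias reweighting equals the plain histogram exactly", {
  set.seed(5)
  x <- rnorm(5000, 1, 0.3)
  g <- grid_spec("x", 0, 2, 40)
  fes <- reweight_to_fes(fake_traj(x), empty_bias(), g, discard = 0, RT = 2.577)
  # plain histogram on the same half-open bins
  h <- table(factor(findInterval(x, seq(0, 2, length.out = 41),
                                 rightmost.closed = TRUE),
                    levels = 1:40))
  plain <- -2.577 * log(as.numeric(h))
  plain[!is.finite(plain)] <- NA
  plain <- plain - min(plain, na.rm = TRUE)
  expect_equal(as.vector(fes$free_energy), plain, tolerance = 1e-12)
})

test_that("reweighting inverts a known analytic bias (direct sampling oracle)", {
  # sample exactly from exp(-(U + Vb)/RT) by inverse CDF, then reweight by
  # exp(+Vb/RT): the estimate must match -RT ln exp(-U/RT)
  RT <- 2.577
  xs <- seq(0, 2, by = 1e-4)
  U <- 8 * (xs - 1)^2
  Vb_of <- function(x) 6 * exp(-(x - 1)^2 / (2 * 0.2^2))
  dens <- exp(-(U + Vb_of(xs)) / RT)
  cdf <- cumsum(dens) / sum(dens)
  set.seed(11)
  x <- xs[findInterval(runif(2e5), cdf) + 1]
  # represent the analytic bias as one Gaussian hill
  b <- bias_state(tibble::tibble(time = 1, x = 1, sigma_x = 0.2, height = 6),
                  gamma = 5, cv_names = "x")
  g <- grid_spec("x", 0.3, 1.7, 56)
  fes <- reweight_to_fes(fake_traj(x), b, g, discard = 0, RT = RT)
  tb <- tibble::as_tibble(fes)
  target <- 8 * (tb$x - 1)^2
  target <- target - min(target)
  ok <- is.finite(tb$fes_kj_mol) & target < 12
  expect_lt(max(abs(tb$fes_kj_mol[ok] - target[ok])), 0.35)
})

test_that("reweighting is gauge invariant and min-zero", {
  set.seed(6)
  x <- runif(4000, 0, 2)
  g <- grid_spec("x", 0, 2, 20)
  base <- reweight_to_fes(fake_traj(x), empty_bias(), g, discard = 0)
  # a near-constant bias (huge width) shifts every weight equally
  b <- bias_state(tibble::tibble(time = 1, x = 1, sigma_x = 1e6, height = 7),
                  gamma = 5, cv_names = "x")
  shifted <- reweight_to_fes(fake_traj(x), b, g, discard = 0)
  expect_equal(as.vector(shifted$free_energy), as.vector(base$free_energy),
               tolerance = 1e-8)
  expect_equal(min(base$free_energy, na.rm = TRUE), 0)
})

test_that("reweighting input errors", {
  g <- grid_spec("x", 0, 2, 20)
  expect_error(reweight_to_fes(fake_traj(c(0.5, 1)), empty_bias(), g,
                               discard = 10), "discarded")
  expect_error(reweight_to_fes(fake_traj(c(5, 6)), empty_bias(), g,
                               discard = 0), "inside the grid")
})

test_that("projection marginalises separable surfaces correctly", {
  g <- grid_spec(c("x", "y"), c(-1, -1), c(1, 1), c(40, 40))
  ctr <- ionbindr:::grid_centers_tbl(g)
  RT <- 2.577
  f2 <- array(2 * ctr$x^2 + 5 * ctr$y^2, dim = c(40, 40))
  fes <- fes_grid(g, f2, RT = RT)
  px <- project_fes(fes, "x")
  tbx <- tibble::as_tibble(px)
  target <- 2 * tbx$x^2
  expect_lt(max(abs(tbx$fes_kj_mol - (target - min(target)))), 1e-9)
  # idempotent composition
  again <- project_fes(px, "x")
  expect_equal(as.vector(again$free_energy), as.vector(px$free_energy))
  expect_error(project_fes(fes, character(0)), "empty")
})

test_that("2D Gaussian-basin projection agrees with 1D quadrature", {
  RT <- 2.577
  g <- grid_spec(c("x", "y"), c(-1.5, -1.5), c(1.5, 1.5), c(120, 120))
  ctr <- ionbindr:::grid_centers_tbl(g)
  U <- -10 * exp(-(ctr$x^2 + ctr$y^2) / (2 * 0.3^2)) + 3 * ctr$x^2 + 3 * ctr$y^2
  fes <- fes_grid(g, array(U, c(120, 120)), RT = RT)
  proj <- tibble::as_tibble(project_fes(fes, "x"))
  # independent 1D quadrature over a fine y grid
  ys <- seq(-1.5, 1.5, by = 1e-3)
  orc <- purrr::map_dbl(proj$x, function(xx) {
    u <- -10 * exp(-(xx^2 + ys^2) / (2 * 0.3^2)) + 3 * xx^2 + 3 * ys^2
    -RT * log(sum(exp(-u / RT)) * 1e-3)
  })
  orc <- orc - min(orc)
  expect_lt(max(abs(proj$fes_kj_mol - orc)), 0.05)
})

test_that("PMF extraction applies the unbound-zero convention", {
  g <- grid_spec("L", 0, 2.5, 100)
  flat <- fes_grid(g, rep(1, 100), RT = 2.577)  # constant surface
  pmf <- pmf_along_cv(flat, "L", c(2, 2.5))
  expect_true(all(abs(pmf$pmf_kj_mol) < 1e-12))

  # square well: -10 for L < 0.4, 0 on the unbound window
  ctr <- g$centers[[1]]
  f <- ifelse(ctr < 0.4, 0, 10)  # fes_grid re-zeroes; depth difference is 10
  sw <- fes_grid(g, f, RT = 2.577)
  pmf2 <- pmf_along_cv(sw, "L", c(2, 2.5))
  expect_equal(unique(pmf2$pmf_kj_mol[ctr < 0.4]), -10)
  expect_equal(unique(pmf2$pmf_kj_mol[ctr >= 2 & ctr < 2.5]), 0)

  expect_error(pmf_along_cv(fes_grid(g, ifelse(ctr < 1, 0, NA), RT = 2.577),
                            "L", c(2, 2.5)), "unbound window")
})

test_that("PMF extraction commutes with re-zeroing and projection", {
  g <- grid_spec(c("L", "y"), c(0, -1), c(2.5, 1), c(50, 20))
  ctr <- ionbindr:::grid_centers_tbl(g)
  f <- array(-8 * exp(-(ctr$L - 0.2)^2 / 0.02) + 2 * ctr$y^2, c(50, 20))
  fes <- fes_grid(g, f, RT = 2.577)
  p1 <- pmf_along_cv(fes, "L", c(2, 2.5))
  p2 <- pmf_along_cv(project_fes(fes, "L"), "L", c(2, 2.5))
  expect_equal(p1$pmf_kj_mol, p2$pmf_kj_mol, tolerance = 1e-9)
})

test_that("sampled + reweighted double well matches the quadrature oracle", {
  pot <- dw_potential()
  ref <- reference_fes_by_quadrature(pot, dw_grid(), dw_cv(), resolution = 0.002)
  p <- sampler_params(n_steps = 3e6, seed = 11, deposit_stride = 2000,
                      record_stride = 50)
  out <- run_wtmetad(pot, dw_cv(), p, n_walkers = 4, bias_grid = dw_grid())
  fes <- reweight_to_fes(out$trajectories, out$bias, dw_grid(), discard = 1/3)
  expect_lt(abs(basin_delta_f(fes) - basin_delta_f(ref)), 0.5)
  # PMF-level agreement inside the flat-bottom region, below the barrier top
  # (outside it the restraint wall is barely sampled and only noise remains)
  pmf_s <- pmf_along_cv(fes, "x", c(1.4, 1.8))
  pmf_r <- pmf_along_cv(ref, "x", c(1.4, 1.8))
  ok <- is.finite(pmf_s$pmf_kj_mol) & pmf_r$pmf_kj_mol < 10 &
    pmf_s$cv > -0.1 & pmf_s$cv < 2.6
  expect_lt(max(abs(pmf_s$pmf_kj_mol[ok] - pmf_r$pmf_kj_mol[ok])), 1.0)
})

test_that("block analysis: constants, iid noise, and AR(1) correlation", {
  ba0 <- block_analysis(rep(3.3, 1000), block_counts = c(3, 10, 50))
  expect_true(all(ba0$sem == 0))

  set.seed(42)
  ba <- block_analysis(rnorm(1e4), block_counts = c(3, 10, 50, 100))
  sem10 <- ba$sem[ba$block_count == 10]
  expect_lt(abs(sem10 - 0.01) / 0.01, 0.3)

  # AR(1), phi = 0.9 (integrated autocorrelation time ~19 samples): the SEM
  # is underestimated while blocks are shorter than the correlation time and
  # grows toward a plateau once they are much longer
  set.seed(7)
  n <- 2e4
  e <- rnorm(n)
  ar <- as.numeric(stats::filter(e, 0.9, method = "recursive"))
  bar <- tidy(block_analysis(ar, block_counts = c(40, 160, 640, 2560)))
  bar <- bar[order(bar$block_size), ]  # block sizes 7 ... 500
  expect_gt(tail(bar$sem, 1), 1.5 * bar$sem[1])
  expect_gt(stats::cor(log(bar$block_size), bar$sem, method = "spearman"), 0.7)
})

test_that("block analysis handles degenerate counts", {
  expect_warning(ba <- block_analysis(rnorm(50), block_counts = c(5, 100)),
                 "skipping")
  expect_equal(ba$block_count, 5)
  expect_error(suppressWarnings(block_analysis(rnorm(5), block_counts = 100)),
               "no usable")
})

test_that("FES CSV round trip", {
  g <- grid_spec(c("x", "y"), 0, 2, 25)
  ctr <- ionbindr:::grid_centers_tbl(g)
  fes <- fes_grid(g, array(ctr$x + 2 * ctr$y, c(25, 25)), RT = 2.577)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fes(fes, f)
  back <- read_fes(f)
  expect_equal(as.vector(back$free_energy), as.vector(fes$free_energy),
               tolerance = 1e-9)
  expect_equal(back$grid$cv_names, c("x", "y"))
})
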