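#' Reweight biased trajectories to a free-energy surface
#'
#' Final-bias reweighting: after discarding an initial burn-in, each retained
#' sample is weighted by `w ~ exp(+V_final(s_t)/RT)` where `V_final` is the
#' total deposited bias at the end of the run, and the FES is
#' `-RT ln` of the weighted CV histogram, minimum shifted to zero. With an
#' identically zero bias the weights are equal and the result is exactly the
#' plain histogram estimate. Per-cell effective sample sizes
#' `(sum w)^2 / sum w^2` are attached as `counts`.
#'
#' @param trajectories A trajectory tibble or list of them (see
#'   [run_wtmetad()] / [read_colvar()]).
#' @param bias A [bias_state()] (may have zero hills).
#' @param grid A [grid_spec()] whose names match trajectory CV columns.
#' @param discard Initial fraction (< 1) of each walker's samples, or an
#'   absolute number of steps, to drop as burn-in. Default 0.25.
#' @param RT Thermal energy, kJ/mol.
#' @param exact Exact hill summation (no 5-sigma truncation).
#'
#' @return A [fes_grid()].
#' @export
reweight_to_fes <- function(trajectories, bias, grid, discard = 0.25,
                            RT = 2.577, exact = FALSE) {
  if (!is.list(trajectories) || is.data.frame(trajectories)) {
    trajectories <- list(trajectories)
  }
  cvn <- grid$cv_names
  bias_cvn <- attr(bias, "cv_names") %||% cvn
  retained <- purrr::map(trajectories, function(tr) {
    stopifnot(all(cvn %in% names(tr)))
    steps <- if ("step" %in% names(tr)) tr$step else tr$time
    cut <- if (discard < 1) discard * max(steps) else discard
    tr[steps > cut, union(cvn, intersect(bias_cvn, names(tr))), drop = FALSE]
  })
  pooled <- dplyr::bind_rows(retained)
  samples <- as.matrix(pooled[, cvn, drop = FALSE])
  if (nrow(samples) == 0) abort("reweight_to_fes: all samples discarded")
  # the bias is evaluated at the sample's full biased-CV coordinates, even
  # when the histogram grid keeps only a subset of them
  V <- if (nrow(bias) > 0 && all(bias_cvn %in% names(pooled))) {
    bias_at(bias, as.matrix(pooled[, bias_cvn, drop = FALSE]), exact = exact)
  } else {
    bias_at(bias, samples, exact = exact)
  }
  if (any(!is.finite(V))) abort("reweight_to_fes: bias not finite on all samples")
  w <- exp((V - max(V)) / RT)
  idx <- grid_linear_index(grid, grid_bin_index(grid, samples))
  ok <- !is.na(idx)
  if (!any(ok)) abort("reweight_to_fes: no samples fall inside the grid")
  wsum <- numeric(prod(grid$n_bins))
  w2sum <- numeric(prod(grid$n_bins))
  s1 <- rowsum(w[ok], idx[ok]); i1 <- as.integer(rownames(s1))
  wsum[i1] <- s1[, 1]
  s2 <- rowsum(w[ok]^2, idx[ok])
  w2sum[i1] <- s2[, 1]
  f <- -RT * log(wsum)
  f[wsum == 0] <- NA_real_
  neff <- ifelse(w2sum > 0, wsum^2 / w2sum, 0)
  fes_grid(grid, f, RT = RT,
           provenance = list(method = "final-bias reweighting",
                             discard = discard, n_samples = sum(ok),
                             n_hills = nrow(bias)),
           counts = array(neff, dim = grid$n_bins))
}

#' Project a free-energy surface onto a subset of its CVs
#'
#' Boltzmann-weighted marginalisation:
#' `F_proj(s) = -RT ln sum_marginalised exp(-F/RT)`, re-zeroed; missing cells
#' are excluded from the sum (never imputed).
#'
#' @param fes A [fes_grid()].
#' @param keep_dims CV names (or indices) to keep, in order.
#' @return A [fes_grid()] over the kept CVs.
#' @export
project_fes <- function(fes, keep_dims) {
  if (length(keep_dims) == 0) abort("project_fes: keep_dims must not be empty")
  g <- fes$grid
  keep <- if (is.character(keep_dims)) match(keep_dims, g$cv_names) else as.integer(keep_dims)
  if (anyNA(keep)) abort("project_fes: keep_dims not found in the grid")
  RT <- fes$RT
  wts <- exp(-fes$free_energy / RT)
  wts[is.na(wts)] <- 0
  proj <- apply(wts, keep, sum)
  f <- -RT * log(proj)
  f[proj == 0] <- NA_real_
  newg <- grid_spec(g$cv_names[keep], g$min[keep], g$max[keep], g$n_bins[keep])
  fes_grid(newg, f, RT = RT,
           provenance = c(fes$provenance,
                          list(projected_from = g$cv_names)))
}

#' Extract a 1D potential of mean force
#'
#' Projects a FES to one CV and shifts it so the mean over the unbound window
#' is zero (the bulk-reference convention used for binding free energies).
#'
#' @param fes A [fes_grid()] (any dimensionality containing `cv_name`).
#' @param cv_name The CV to keep.
#' @param unbound_window Length-2 numeric, the bulk window (nm), e.g.
#'   `c(2, 2.5)`.
#' @return A `pmf_profile` tibble with columns `cv` (bin centers) and
#'   `pmf_kj_mol`; attributes `cv_name`, `RT`, `zero_convention`.
#' @export
pmf_along_cv <- function(fes, cv_name, unbound_window) {
  p <- if (length(fes$grid$cv_names) > 1) project_fes(fes, cv_name) else fes
  centers <- p$grid$centers[[1]]
  vals <- as.vector(p$free_energy)
  inw <- centers >= unbound_window[1] & centers < unbound_window[2]
  if (!any(inw & is.finite(vals))) {
    abort("pmf_along_cv: unbound window has no visited cells")
  }
  vals <- vals - mean(vals[inw & is.finite(vals)])
  out <- tibble::tibble(cv = centers, pmf_kj_mol = vals)
  attr(out, "cv_name") <- cv_name
  attr(out, "RT") <- p$RT
  attr(out, "zero_convention") <- "mean over unbound window = 0"
  attr(out, "unbound_window") <- unbound_window
  class(out) <- c("pmf_profile", class(out))
  out
}

#' Block analysis of a time series
#'
#' Splits a series into `k` contiguous equal blocks (remainder truncated) for
#' each requested `k`, applies a statistic per block, and reports the mean
#' and standard error of the mean (SEM) across blocks. For correlated series
#' the SEM rises with block size toward a plateau; the plateau (largest-block
#' end, i.e. smallest `k`) is the reported uncertainty.
#'
#' @param x Numeric vector, or a data frame of per-sample rows.
#' @param block_counts Integer vector of block counts (default `3:100`,
#'   mirroring standard practice; counts exceeding the series length are
#'   skipped with a warning).
#' @param statistic Function applied per block (default `mean`; for data
#'   frames it receives the block's rows).
#' @param plateau_tol Relative SEM change below which successive
#'   largest-block SEMs count as stabilised (default 0.2).
#'
#' @return A `block_analysis_result` tibble (`block_count`, `block_size`,
#'   `mean`, `sem`) with attributes `plateau_value`, `plateau_sem`,
#'   `plateau_reached`.
#' @export
#' @examples
#' set.seed(1)
#' block_analysis(rnorm(1e4), block_counts = c(3, 10, 50))
block_analysis <- function(x, block_counts = 3:100, statistic = mean,
                           plateau_tol = 0.2) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  block_counts <- sort(unique(as.integer(block_counts)))
  if (any(block_counts > n)) {
    warn(sprintf("block_analysis: skipping block counts > series length (%d)", n))
    block_counts <- block_counts[block_counts <= n]
  }
  if (length(block_counts) == 0) abort("block_analysis: no usable block counts")
  rows <- purrr::map(block_counts, function(k) {
    bs <- n %/% k
    vals <- purrr::map_dbl(seq_len(k), function(b) {
      i <- ((b - 1) * bs + 1):(b * bs)
      if (is.data.frame(x)) statistic(x[i, , drop = FALSE]) else statistic(x[i])
    })
    vals <- vals[is.finite(vals)]
    tibble::tibble(block_count = k, block_size = bs,
                   mean = mean(vals),
                   sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0)
  })
  out <- dplyr::bind_rows(rows)
  big <- dplyr::arrange(out, dplyr::desc(.data$block_size))
  reached <- if (nrow(big) >= 2 && big$sem[2] > 0) {
    abs(big$sem[1] - big$sem[2]) / big$sem[2] < plateau_tol
  } else TRUE
  attr(out, "plateau_value") <- big$mean[1]
  attr(out, "plateau_sem") <- big$sem[1]
  attr(out, "plateau_reached") <- reached
  class(out) <- c("block_analysis_result", class(out))
  out
}
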