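#' Bound/unbound region definition for binding free energies
#'
#' @param bound Length-2 CV interval (nm) of the bound region; default
#'   `c(0, 0.4)` (cation in the site, L < 0.4 nm).
#' @param unbound Length-2 CV interval (nm) of the bulk reference window;
#'   default `c(2, 2.5)`.
#' @return A list of class `region_spec` with `bound`, `unbound` and `l_u`
#'   (the unbound-window length, default 0.5 nm).
#' @export
region_spec <- function(bound = c(0, 0.4), unbound = c(2, 2.5)) {
  stopifnot(length(bound) == 2, length(unbound) == 2,
            bound[2] > bound[1], unbound[2] > unbound[1])
  if (bound[2] > unbound[1] && unbound[2] > bound[1]) {
    abort("region_spec: bound and unbound intervals must be disjoint")
  }
  structure(list(bound = bound, unbound = unbound, l_u = diff(unbound)),
            class = "region_spec")
}

#' Ionic charges and ionic strength for the Debye-Hueckel correction
#'
#' @param z_cation,z_site Integer charges of the free cation and the free
#'   site.
#' @param z_complex Charge of the cation-site complex; defaults to
#'   `z_cation + z_site`.
#' @param I Ionic strength in mol/L (>= 0).
#' @return A list of class `charge_set`.
#' @export
#' @examples
#' charge_set(2, -2, I = 0.15)
charge_set <- function(z_cation, z_site, z_complex = NULL, I = 0) {
  if (I < 0) abort("charge_set: ionic strength must be >= 0")
  structure(list(z_cation = z_cation, z_site = z_site,
                 z_complex = z_complex %||% (z_cation + z_site), I = I),
            class = "charge_set")
}

# trapezoid of exp(-PMF/RT) over an interval, with interpolated edge values
# so region widths are honoured exactly; the grid is bin centers, so edges
# may extend half a bin beyond the outermost center (flat extrapolation)
boltzmann_integral <- function(centers, pmf, interval, RT) {
  half <- stats::median(diff(sort(centers))) / 2
  lo <- max(interval[1], min(centers) - half)
  hi <- min(interval[2], max(centers) + half)
  fin <- is.finite(pmf)
  inside <- fin & centers >= lo & centers < hi
  if (!any(inside)) abort("region with no PMF support")
  xs <- centers[inside]; ys <- pmf[inside]
  if (lo < xs[1]) {
    v <- approx(centers[fin], pmf[fin], xout = lo, rule = 2)$y
    xs <- c(lo, xs); ys <- c(v, ys)
  }
  if (hi > xs[length(xs)]) {
    v <- approx(centers[fin], pmf[fin], xout = hi, rule = 2)$y
    xs <- c(xs, hi); ys <- c(ys, v)
  }
  f <- exp(-ys / RT)
  sum(diff(xs) * (head(f, -1) + tail(f, -1)) / 2)
}

#' PMF contribution to the standard binding free energy
#'
#' `dG_PMF = RT ln( I_unbound / I_bound )` where each `I` is the trapezoidal
#' integral of `exp(-PMF/RT)` over the region. The PMF is expected on the
#' unbound-zero convention (see [pmf_along_cv()]); the result is invariant
#' under adding a constant to the PMF.
#'
#' @param pmf A `pmf_profile` (or tibble with `cv` and `pmf_kj_mol`).
#' @param regions A [region_spec()].
#' @param RT Thermal energy, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
delta_g_pmf <- function(pmf, regions = region_spec(), RT = 2.577) {
  iu <- boltzmann_integral(pmf$cv, pmf$pmf_kj_mol, regions$unbound, RT)
  ib <- boltzmann_integral(pmf$cv, pmf$pmf_kj_mol, regions$bound, RT)
  RT * log(iu / ib)
}

#' Effective cross-section of a flat-bottom cylindrical restraint
#'
#' The radial integral `S_u = int_0^inf 2 pi r exp(-U_res(r)/RT) dr` of a
#' flat-bottom cylinder evaluates in closed form to
#' `pi R_cyl^2 + 2 pi ( sqrt(pi RT / (2 K_res)) R_cyl + RT / K_res )`; it
#' tends to the hard-wall `pi R_cyl^2` as `K_res -> Inf` and to
#' `2 pi RT / K_res` at `R_cyl = 0`.
#'
#' @param R_cyl Cylinder radius, nm (>= 0).
#' @param K_res Force constant, kJ mol^-1 nm^-2 (> 0).
#' @param RT Thermal energy, kJ/mol.
#' @return Area in nm^2.
#' @export
#' @examples
#' s_u_cross_section(0.7, 1e5, 2.577)  # ~ 1.5675 nm^2
s_u_cross_section <- function(R_cyl, K_res, RT = 2.577) {
  if (R_cyl < 0) abort("s_u_cross_section: R_cyl must be >= 0")
  if (K_res <= 0) abort("s_u_cross_section: K_res must be > 0")
  pi * R_cyl^2 + 2 * pi * (sqrt(pi * RT / (2 * K_res)) * R_cyl + RT / K_res)
}

#' Standard-state volume correction
#'
#' `dG_V = -RT ln( l_u S_u / V0 )`: converts the sampled unbound volume (the
#' unbound window length times the restraint cross-section) to the 1 M
#' standard-state volume `V0`.
#'
#' @param l_u Unbound-window length, nm.
#' @param S_u Restraint cross-section, nm^2 (see [s_u_cross_section()]).
#' @param V0 Standard-state volume, nm^3 (default 1.661).
#' @param RT Thermal energy, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
delta_g_volume <- function(l_u, S_u, V0 = 1.661, RT = 2.577) {
  stopifnot(l_u > 0, S_u > 0, V0 > 0, RT > 0)
  -RT * log(l_u * S_u / V0)
}

#' Ionic-strength correction by the limiting Debye-Hueckel law
#'
#' Converts the binding free energy to zero ionic strength using limiting-law
#' activity coefficients `log10 gamma_i = -A z_i^2 sqrt(I)`:
#' `dG_I = RT ln10 (-A sqrt(I)) (z_cation^2 + z_site^2 - z_complex^2)`.
#' Zero at `I = 0` or all-zero charges. `mode = "literal_ratio"` evaluates
#' `RT ln(gamma_cat gamma_site / gamma_complex)` with `gamma_i` read literally
#' as `-A z_i^2 sqrt(I)`; that reading is dimensionally unsound (the
#' "coefficients" are negative) and errors — it exists for audit only.
#'
#' @param charges A [charge_set()].
#' @param A Debye-Hueckel coefficient, M^-1/2 (default 0.519, water, 310 K).
#' @param RT Thermal energy, kJ/mol.
#' @param mode `"debye_huckel_log10"` (default) or `"literal_ratio"`.
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' delta_g_ionic(charge_set(2, -2, I = 0.01))  # ~ -2.464 kJ/mol
delta_g_ionic <- function(charges, A = 0.519, RT = 2.577,
                          mode = c("debye_huckel_log10", "literal_ratio")) {
  mode <- match.arg(mode)
  z2 <- charges$z_cation^2 + charges$z_site^2 - charges$z_complex^2
  if (charges$I == 0 || z2 == 0) {
    if (mode == "debye_huckel_log10" || charges$I == 0) return(0)
  }
  if (mode == "literal_ratio") {
    g <- function(z) -A * z^2 * sqrt(charges$I)
    ratio <- g(charges$z_cation) * g(charges$z_site) / g(charges$z_complex)
    if (!is.finite(ratio) || ratio <= 0) {
      abort(paste("delta_g_ionic: the literal activity-coefficient reading",
                  "yields a non-positive ratio; use the default",
                  "debye_huckel_log10 interpretation"))
    }
    return(RT * log(ratio))
  }
  RT * log(10) * (-A * sqrt(charges$I)) * z2
}

#' Standard binding free energy at zero ionic strength
#'
#' Assembles `dG0 = dG_PMF + dG_V + dG_I` (an exact identity of the returned
#' components) from a 1D PMF, the restraint geometry and the charge set. When
#' `samples` is supplied (reweighted trajectory samples), the statistical
#' error is estimated by block analysis: each walker's retained series is
#' split into `k` contiguous blocks, a per-block dG0 is computed from the
#' block's reweighted PMF, and the SEM at the largest block size is reported.
#'
#' @param pmf A `pmf_profile` from [pmf_along_cv()].
#' @param regions A [region_spec()].
#' @param restraint A [restraint_spec()] (flat-bottom cylinder) used for the
#'   volume correction.
#' @param charges A [charge_set()]; default zero ionic strength.
#' @param constants A [binding_constants()].
#' @param samples Optional list for the SEM: `trajectories` (list of
#'   trajectory tibbles), `bias` (a [bias_state()]), `grid` (1D
#'   [grid_spec()] along the PMF CV), `discard` (burn-in, as in
#'   [reweight_to_fes()]), `block_counts` (default `3:25`).
#'
#' @return A `binding_free_energy` object: list with `dG_pmf`, `dG_V`,
#'   `dG_I`, `dG0`, `sem`, `blocks` (a [block_analysis()] result or `NULL`)
#'   and `settings`.
#' @export
standard_binding_free_energy <- function(pmf, regions = region_spec(),
                                         restraint = NULL,
                                         charges = charge_set(2, -2, I = 0),
                                         constants = binding_constants(),
                                         samples = NULL) {
  RT <- constants$RT
  dg_pmf <- delta_g_pmf(pmf, regions, RT)
  S_u <- s_u_cross_section(restraint$R_cyl %||% 0.7,
                           restraint$K_res %||% 1e5, RT)
  dg_v <- delta_g_volume(regions$l_u, S_u, constants$V0, RT)
  dg_i <- delta_g_ionic(charges, constants$A, RT)
  blocks <- NULL
  sem <- NA_real_
  if (!is.null(samples)) {
    cvn <- attr(pmf, "cv_name")
    grid <- samples$grid
    block_counts <- samples$block_counts %||% 3:25
    trs <- samples$trajectories
    if (is.data.frame(trs)) trs <- list(trs)
    discard <- samples$discard %||% 0.25
    retained <- purrr::map(trs, function(tr) {
      steps <- if ("step" %in% names(tr)) tr$step else tr$time
      cut <- if (discard < 1) discard * max(steps) else discard
      tr[steps > cut, , drop = FALSE]
    })
    n <- min(purrr::map_int(retained, nrow))
    # final-bias weights computed once (at the full biased-CV coordinates);
    # blocks only re-histogram
    bias_cvn <- attr(samples$bias, "cv_names") %||% cvn
    if (!all(bias_cvn %in% names(retained[[1]]))) bias_cvn <- cvn
    cv_mat <- purrr::map(retained, ~ as.matrix(.x[seq_len(n), cvn, drop = FALSE]))
    bias_mat <- purrr::map(retained,
                           ~ as.matrix(.x[seq_len(n), bias_cvn, drop = FALSE]))
    Vb <- bias_at(samples$bias, do.call(rbind, bias_mat))
    w_all <- exp((Vb - max(Vb)) / RT)
    w_mat <- matrix(w_all, nrow = n)  # one column per walker
    centers <- grid$centers[[1]]
    binw <- grid_bin_width(grid)
    dg0_of_block <- function(b, k) {
      bs <- n %/% k
      idx <- ((b - 1) * bs + 1):(b * bs)
      s <- unlist(purrr::map(cv_mat, ~ .x[idx, 1]))
      w <- as.vector(w_mat[idx, ])
      bi <- grid_bin_index(grid, matrix(s, ncol = 1))[, 1]
      ok <- !is.na(bi)
      if (!any(ok)) return(NA_real_)
      hist <- numeric(length(centers))
      gs <- rowsum(w[ok], bi[ok])
      hist[as.integer(rownames(gs))] <- gs[, 1]
      f <- -RT * log(hist)
      f[hist == 0] <- NA_real_
      inw <- centers >= regions$unbound[1] & centers < regions$unbound[2]
      if (!any(inw & is.finite(f))) return(NA_real_)
      p <- tibble::tibble(cv = centers,
                          pmf_kj_mol = f - mean(f[inw & is.finite(f)]))
      out <- try(delta_g_pmf(p, regions, RT) + dg_v + dg_i, silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out
    }
    rows <- purrr::map(block_counts[block_counts <= n], function(k) {
      vals <- purrr::map_dbl(seq_len(k), dg0_of_block, k = k)
      vals <- vals[is.finite(vals)]
      tibble::tibble(block_count = k, block_size = n %/% k,
                     mean = mean(vals),
                     sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else NA_real_)
    })
    blocks <- dplyr::bind_rows(rows)
    big <- dplyr::arrange(blocks, dplyr::desc(.data$block_size))
    attr(blocks, "plateau_value") <- big$mean[1]
    attr(blocks, "plateau_sem") <- big$sem[1]
    class(blocks) <- c("block_analysis_result", class(blocks))
    sem <- big$sem[1]
  }
  structure(
    list(dG_pmf = dg_pmf, dG_V = dg_v, dG_I = dg_i,
         dG0 = dg_pmf + dg_v + dg_i, sem = sem, blocks = blocks,
         settings = list(regions = regions, restraint = restraint,
                         charges = charges, constants = constants)),
    class = "binding_free_energy"
  )
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat("<binding_free_energy>\n")
  cat(sprintf("  dG_PMF = %8.3f kJ/mol\n", x$dG_pmf))
  cat(sprintf("  dG_V   = %8.3f kJ/mol\n", x$dG_V))
  cat(sprintf("  dG_I   = %8.3f kJ/mol\n", x$dG_I))
  cat(sprintf("  dG0    = %8.3f %s kJ/mol\n", x$dG0,
              if (is.na(x$sem)) "" else sprintf("+/- %.3f", x$sem)))
  invisible(x)
}

#' Binding free-energy differences and fold preferences
#'
#' `delta_delta_g(a, b)` returns `dG0_a - dG0_b` (the "a versus b"
#' convention) with the SEMs combined in quadrature when available.
#' `fold_preference(dG0_a, dG0_b, RT)` returns `exp((dG0_b - dG0_a)/RT)`,
#' the binding preference of `a` over `b` (> 1 when `a` binds more
#' strongly); its uncertainty is propagated from the SEMs by quadrature.
#'
#' @param a,b `binding_free_energy` objects or plain dG0 values (kJ/mol).
#' @return `delta_delta_g`: a named vector `c(ddG = , sem = )`;
#'   `fold_preference`: a named vector `c(fold = , sem = )`.
#' @export
#' @examples
#' delta_delta_g(-9.4, -12.9)            # +3.5
#' fold_preference(-12.9, -3.7)$fold     # ~ 35
delta_delta_g <- function(a, b) {
  dg <- function(x) if (inherits(x, "binding_free_energy")) x$dG0 else x
  se <- function(x) if (inherits(x, "binding_free_energy")) x$sem else NA_real_
  list(ddG = dg(a) - dg(b),
       sem = sqrt(se(a)^2 + se(b)^2))
}

#' @rdname delta_delta_g
#' @param dG0_a,dG0_b Standard binding free energies (kJ/mol) or
#'   `binding_free_energy` objects.
#' @param RT Thermal energy, kJ/mol.
#' @param sem_a,sem_b Optional SEMs of the two inputs (kJ/mol).
#' @export
fold_preference <- function(dG0_a, dG0_b, RT = 2.577,
                            sem_a = NULL, sem_b = NULL) {
  dg <- function(x) if (inherits(x, "binding_free_energy")) x$dG0 else x
  se <- function(x, s) {
    if (!is.null(s)) s
    else if (inherits(x, "binding_free_energy")) x$sem
    else NA_real_
  }
  fold <- exp((dg(dG0_b) - dg(dG0_a)) / RT)
  s <- sqrt(se(dG0_a, sem_a)^2 + se(dG0_b, sem_b)^2)
  list(fold = fold, sem = fold * s / RT)
}
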