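#' Brute-force reference free-energy surface by dense-grid quadrature
#'
#' Computes `F(s) = -RT ln integral( delta(CV(x) - s) exp(-U(x)/RT) dx )` for
#' a model landscape by direct numerical integration on a dense Cartesian
#' grid covering the restrained region, binned onto the requested CV grid and
#' shifted so the minimum is zero. This is the ground-truth oracle against
#' which sampled and reweighted estimates are validated: it involves no
#' sampling at all.
#'
#' For hydration-aware landscapes the auxiliary coordinate is integrated on
#' its own sub-grid when a CV reads it, and integrates out to a constant
#' (dropped) otherwise.
#'
#' @param spec A [model_potential()].
#' @param grid A [grid_spec()] over the CVs.
#' @param cvs List of [cv_spec()]s (one per grid dimension).
#' @param resolution Integration-grid spacing in nm (> 0). Default 0.02.
#' @param h_resolution Spacing for the hydration coordinate. Default 0.1.
#'
#' @return A [fes_grid()] with `provenance$method = "quadrature"`. A warning
#'   is recorded in the provenance (and signalled) when the CV grid is too
#'   coarse to resolve the well widths (bin width > width/2).
#' @export
#' @examples
#' pot <- model_potential("double_well_1d", anchor_positions = c(0.25, 2.25),
#'                        well_depths = c(10, 10), well_widths = 0.1)
#' g <- grid_spec("x", 0, 2.5, 100)
#' cv <- list(cv_spec("raw_coordinate", index = 1, name = "x"))
#' ref <- reference_fes_by_quadrature(pot, g, cv, resolution = 0.005)
reference_fes_by_quadrature <- function(spec, grid, cvs,
                                        resolution = 0.02,
                                        h_resolution = 0.1) {
  stopifnot(inherits(spec, "model_potential"), inherits(grid, "grid_spec"))
  if (resolution <= 0) abort("resolution must be > 0")
  if (length(cvs) != grid_dim(grid)) {
    abort("reference_fes_by_quadrature: one cv_spec per grid dimension required")
  }
  prov <- list(method = "quadrature", resolution = resolution,
               normalization = "minimum set to zero", warnings = character())
  if (any(grid_bin_width(grid) > min(spec$well_widths) / 2)) {
    msg <- "CV grid spacing exceeds half the narrowest well width; basins may be under-resolved"
    warn(msg)
    prov$warnings <- c(prov$warnings, msg)
  }

  RT <- spec$RT
  res <- spec$restraint
  margin <- sqrt(2 * 20 * RT / res$K_res)  # restraint wall at 20 RT
  acc <- numeric(prod(grid$n_bins))

  accumulate <- function(coords, w) {
    s <- cv_values(cvs, coords)
    idx <- grid_linear_index(grid, grid_bin_index(grid, s))
    ok <- !is.na(idx) & is.finite(w) & w > 0
    if (!any(ok)) return(invisible())
    gs <- rowsum(w[ok], group = idx[ok])
    i <- as.integer(rownames(gs))
    acc[i] <<- acc[i] + gs[, 1]
    invisible()
  }

  needs_h <- spec$kind == "two_anchor_3d_hydration" &&
    any(purrr::map_chr(cvs, "kind") == "coordination_number")

  if (spec$kind == "double_well_1d") {
    lo <- res$axial_range[1] - margin
    hi <- res$axial_range[2] + margin
    x <- seq(lo, hi, by = resolution)
    u <- eval_potential(spec, matrix(x, ncol = 1))
    accumulate(matrix(x, ncol = 1), exp(-u / RT) * resolution)
  } else {
    # integrate in the restraint's axis frame
    u1 <- res$axis
    ref <- if (abs(u1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * u1) * u1
    v <- v / sqrt(sum(v^2))
    w3 <- c(u1[2] * v[3] - u1[3] * v[2],
            u1[3] * v[1] - u1[1] * v[3],
            u1[1] * v[2] - u1[2] * v[1])
    rmax <- res$R_cyl + margin
    ab <- seq(-rmax, rmax, by = resolution)
    t_rng <- if (!is.null(res$axial_range)) res$axial_range + c(-margin, margin)
      else range(spec$anchors %*% u1) + c(-1, 1)
    ts <- seq(t_rng[1], t_rng[2], by = resolution)
    plane <- as.matrix(expand.grid(a = ab, b = ab))
    keep <- rowSums(plane^2) <= rmax^2
    plane <- plane[keep, , drop = FALSE]
    base_xyz <- plane[, 1] %o% v + plane[, 2] %o% w3
    dV <- resolution^3
    if (needs_h) {
      sig_h <- sqrt(RT / spec$k_h)
      hs <- seq(spec$h_bulk - spec$hydration_coupling - 4 * sig_h,
                spec$h_bulk + 4 * sig_h, by = h_resolution)
    }
    for (t in ts) {
      xyz <- sweep(base_xyz, 2, res$origin + t * u1, "+")
      if (spec$kind == "two_anchor_3d") {
        u <- eval_potential(spec, xyz)
        accumulate(xyz, exp(-u / RT) * dV)
      } else if (!needs_h) {
        # h integrates to a CV-independent constant; evaluate at the rest value
        coords <- cbind(xyz, hydration_rest_value(spec, xyz))
        u <- eval_potential(spec, coords)
        accumulate(coords, exp(-u / RT) * dV)
      } else {
        for (h in hs) {
          coords <- cbind(xyz, h)
          u <- eval_potential(spec, coords)
          accumulate(coords, exp(-u / RT) * dV * h_resolution)
        }
      }
    }
  }

  f <- -RT * log(acc)
  f[!is.finite(f)] <- NA_real_
  fes_grid(grid, f, RT = RT, provenance = prov)
}
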