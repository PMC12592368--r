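#' Default van der Waals radii (nm)
#'
#' Radii used by [pore_profile()]; C 0.17, N 0.155, O 0.152, S 0.18 nm, with
#' 0.15 nm for anything else.
#' @return Named numeric vector of radii in nm.
#' @export
default_vdw_radii <- function() {
  c(C = 0.17, N = 0.155, O = 0.152, S = 0.18, H = 0.12, default = 0.15)
}

#' Pore radius profile along a channel axis
#'
#' A simple plane-wise largest-empty-sphere profiler: for each axial slice,
#' the pore radius is the maximum over in-plane centre positions of
#' `min_i(|centre - atom_i| - vdw_i)`, found by multi-start Nelder-Mead local
#' optimisation seeded at the axis and at four lateral offsets. Radii are
#' clipped at zero. Slices with no atom within `cutoff` of the axis point
#' report the sentinel `max_radius`.
#'
#' @param structure An `ionbind_structure`.
#' @param axis Pore axis (default z), normalised internally; it must pass
#'   through the structure bounding box.
#' @param z_min,z_max Axial range to profile (nm, along `axis` through
#'   `origin`).
#' @param step Slice spacing in nm (> 0).
#' @param radii Named vdW radii table in nm (see [default_vdw_radii()]).
#' @param origin Point the axis passes through (default: centroid of all
#'   atoms projected to the axis' normal plane).
#' @param max_offset Maximum lateral displacement of the sphere centre from
#'   the axis, nm (default 1).
#' @param cutoff Neighbourhood radius for the empty-slice sentinel, nm.
#' @param max_radius Sentinel radius reported for empty slices, nm.
#'
#' @return A `pore_profile` tibble: `z_nm`, `radius_nm`, `center_x/y/z`.
#' @export
#' @examples
#' ring <- make_ring_structure(8, ring_radius = 0.5, z = 0)
#' pore_profile(ring, z_min = 0, z_max = 0, step = 0.05)
pore_profile <- function(structure, axis = c(0, 0, 1), z_min = NULL,
                         z_max = NULL, step = 0.05,
                         radii = default_vdw_radii(), origin = NULL,
                         max_offset = 1, cutoff = 1.5, max_radius = 2) {
  if (step <= 0) abort("pore_profile: step must be > 0")
  u <- axis / sqrt(sum(axis^2))
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  heavy <- structure$element != "H"
  xyz <- xyz[heavy, , drop = FALSE]
  rv <- radii[structure$element[heavy]]
  rv[is.na(rv)] <- radii[["default"]]
  t_ax <- as.vector(xyz %*% u)
  if (is.null(origin)) {
    cen <- colMeans(xyz)
    origin <- cen - sum(cen * u) * u
  }
  rng <- range(t_ax)
  z_min <- z_min %||% rng[1]
  z_max <- z_max %||% rng[2]
  if (z_min > rng[2] || z_max < rng[1]) {
    abort("pore_profile: axial range lies outside the structure bounding box")
  }
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  zs <- seq(z_min, z_max, by = step)
  out <- purrr::map(zs, function(zz) {
    p0 <- origin + zz * u
    d_ax <- sqrt(rowSums(sweep(xyz, 2, p0)^2))
    near <- d_ax <= cutoff + max_radius
    if (!any(near)) {
      return(tibble::tibble(z_nm = zz, radius_nm = max_radius,
                            center_x = p0[1], center_y = p0[2], center_z = p0[3]))
    }
    a_xyz <- xyz[near, , drop = FALSE]
    a_r <- rv[near]
    objective <- function(ab) {
      if (sum(ab^2) > max_offset^2) return(1e6)  # keep the centre near the axis
      p <- p0 + ab[1] * v + ab[2] * w
      -(min(sqrt(rowSums(sweep(a_xyz, 2, p)^2)) - a_r))
    }
    starts <- list(c(0, 0), c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1))
    best <- purrr::map(starts, ~ optim(.x, objective, method = "Nelder-Mead",
                                       control = list(reltol = 1e-8)))
    b <- best[[which.min(purrr::map_dbl(best, "value"))]]
    p <- p0 + b$par[1] * v + b$par[2] * w
    tibble::tibble(z_nm = zz, radius_nm = max(0, -b$value),
                   center_x = p[1], center_y = p[2], center_z = p[3])
  }) |> dplyr::bind_rows()
  class(out) <- c("pore_profile", class(out))
  out
}

#' Ring-of-atoms fixture for pore profiling
#'
#' A single ring of `n` carbon atoms at `ring_radius` from the z axis in the
#' plane `z`, useful as an analytically solvable pore fixture (pore radius =
#' ring_radius - vdW radius at the ring plane).
#'
#' @param n Number of atoms.
#' @param ring_radius Ring radius, nm.
#' @param z Plane height, nm.
#' @param chain_id Chain label.
#' @param first_residue_number Residue number of the first atom.
#' @return An `ionbind_structure`.
#' @export
make_ring_structure <- function(n = 8, ring_radius = 0.5, z = 0,
                                chain_id = "A", first_residue_number = 1L) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  new_structure(tibble::tibble(
    atom = "C", element = "C", residue_name = "ALA",
    residue_number = first_residue_number + seq_len(n) - 1L,
    chain_id = chain_id, altloc = " ", occupancy = 1,
    x = ring_radius * cos(th), y = ring_radius * sin(th), z = z,
    model_id = 1L
  ))
}
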