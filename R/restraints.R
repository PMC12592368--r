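#' Specify a sampling restraint
#'
#' Restraints confine the diffusing cation during enhanced sampling and enter
#' the standard-state volume correction. Three kinds are supported:
#'
#' * `flat_bottom_cylinder` — zero inside a cylinder of radius `R_cyl` about
#'   `axis` (through `origin`), harmonic with force constant `K_res` outside.
#'   An optional `axial_range` adds the same flat-bottom/harmonic treatment
#'   along the axis, closing the sampling volume at both ends.
#' * `flat_bottom_interval` — the 1D analogue: zero on `axial_range`,
#'   harmonic outside (used by 1D double-well systems, which are otherwise
#'   unconfined).
#' * `harmonic_point` — harmonic tether of stiffness `K_res` to `origin`.
#'
#' @param kind One of `"flat_bottom_cylinder"`, `"flat_bottom_interval"`,
#'   `"harmonic_point"`.
#' @param axis Unit 3-vector of the cylinder axis (normalised internally).
#' @param R_cyl Cylinder radius in nm (>= 0).
#' @param K_res Force constant in kJ mol^-1 nm^-2 (> 0). Default 1e5.
#' @param origin Point on the axis / tether centre, nm.
#' @param axial_range Length-2 numeric: flat-bottom range along the axis (or
#'   the 1D coordinate), nm. `NULL` leaves the cylinder open-ended.
#'
#' @return An object of class `restraint_spec`.
#' @export
#' @examples
#' restraint_spec("flat_bottom_cylinder", R_cyl = 0.7, K_res = 1e5,
#'                axial_range = c(-0.5, 2.6))
restraint_spec <- function(kind = c("flat_bottom_cylinder",
                                    "flat_bottom_interval",
                                    "harmonic_point"),
                           axis = c(0, 1, 0), R_cyl = 0.7, K_res = 1e5,
                           origin = c(0, 0, 0), axial_range = NULL) {
  kind <- match.arg(kind)
  if (R_cyl < 0) abort("R_cyl must be >= 0")
  if (K_res <= 0) abort("K_res must be > 0")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) abort("axis must be a nonzero vector")
  axis <- axis / nrm
  if (!is.null(axial_range)) {
    stopifnot(length(axial_range) == 2, axial_range[2] > axial_range[1])
  }
  structure(
    list(kind = kind, axis = axis, R_cyl = R_cyl, K_res = K_res,
         origin = origin, axial_range = axial_range),
    class = "restraint_spec"
  )
}

#' Flat-bottom restraint energy
#'
#' Energy of a position under a [restraint_spec()]: zero inside the
#' flat-bottom region, `0.5 * K_res * excess^2` outside, continuous with a
#' continuous first derivative at the boundary.
#'
#' @param position Numeric vector (a single point: length 3, or length 1 for
#'   `flat_bottom_interval`) or a matrix with one point per row.
#' @param restraint A [restraint_spec()].
#'
#' @return Energy in kJ/mol (vector, one value per point).
#' @export
#' @examples
#' r <- restraint_spec("flat_bottom_cylinder", R_cyl = 0.7, K_res = 1e5)
#' flat_bottom_energy(c(0.71, 0, 0), r)  # 0.5 * 1e5 * 0.01^2 = 5
flat_bottom_energy <- function(position, restraint) {
  stopifnot(inherits(restraint, "restraint_spec"))
  x <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  K <- restraint$K_res
  if (restraint$kind == "flat_bottom_interval") {
    v <- x[, 1]
    lo <- restraint$axial_range[1]; hi <- restraint$axial_range[2]
    excess <- pmax(lo - v, 0) + pmax(v - hi, 0)
    return(0.5 * K * excess^2)
  }
  if (restraint$kind == "harmonic_point") {
    d <- min(ncol(x), 3)
    rel <- sweep(x[, seq_len(d), drop = FALSE], 2, restraint$origin[seq_len(d)])
    return(0.5 * K * rowSums(rel^2))
  }
  stopifnot(ncol(x) >= 3)
  rel <- sweep(x[, 1:3, drop = FALSE], 2, restraint$origin)
  t_ax <- as.vector(rel %*% restraint$axis)
  perp2 <- pmax(rowSums(rel^2) - t_ax^2, 0)
  excess_r <- pmax(sqrt(perp2) - restraint$R_cyl, 0)
  e <- 0.5 * K * excess_r^2
  if (!is.null(restraint$axial_range)) {
    lo <- restraint$axial_range[1]; hi <- restraint$axial_range[2]
    excess_z <- pmax(lo - t_ax, 0) + pmax(t_ax - hi, 0)
    e <- e + 0.5 * K * excess_z^2
  }
  e
}
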