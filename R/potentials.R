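#' Define a model binding landscape
#'
#' Analytically tractable stand-ins for cation-binding systems: a particle
#' diffusing inside a restraining cylinder toward one or two attractive
#' "carboxyl" anchors. Each anchor contributes an isotropic Gaussian well
#' `-depth * exp(-r^2 / (2 width^2))`; an `r^-12` soft-core repulsion
#' `RT * (repulsion_radius / r)^12` per anchor keeps the particle off the
#' anchor core (disabled when `repulsion_radius = 0`). The potential is zero
#' far from all anchors.
#'
#' Kinds:
#' * `double_well_1d` — 1D coordinate, two Gaussian wells, interval restraint.
#' * `two_anchor_3d` — 3D particle, two anchors, cylindrical flat-bottom
#'   restraint; CVs are typically the two anchor distances L1/L2.
#' * `two_anchor_3d_hydration` — as above plus a 4th auxiliary "hydration"
#'   coordinate `h`, harmonically tethered (stiffness `k_h`) to a rest value
#'   `h_bulk - hydration_coupling * sum_i exp(-r_i^2 / (2 width_i^2))` that
#'   decreases as the particle approaches an anchor — a solvent-free mimic of
#'   partial dehydration on binding (waters displaced from the first shell).
#'
#' @param kind Landscape kind, see above.
#' @param anchor_positions For 3D kinds a list of 3-vectors (nm); for
#'   `double_well_1d` a numeric vector of well positions.
#' @param well_depths Well depths in kJ/mol, one per anchor (>= 0).
#' @param well_widths Gaussian widths in nm, one per anchor (> 0).
#' @param repulsion_radius Soft-core radius in nm (>= 0; 0 disables).
#' @param hydration_coupling Waters displaced at full binding (dimensionless;
#'   default 2, monodentate binding to both anchors).
#' @param h_bulk Rest value of the hydration coordinate in bulk (default 6,
#'   the octahedral first shell of Mg2+).
#' @param k_h Tether stiffness for `h`, kJ/mol per unit^2 (default 10).
#' @param restraint A [restraint_spec()]; defaults to the protein-site
#'   cylinder (R_cyl 0.9 nm, K_res 1e5) for 3D kinds and an interval for 1D.
#' @param RT Thermal energy, kJ/mol (default 2.577, 310 K).
#'
#' @return An object of class `model_potential`.
#' @export
#' @examples
#' pot <- model_potential("two_anchor_3d")
#' eval_potential(pot, c(-0.15, 0, 0.2))
model_potential <- function(kind = c("double_well_1d", "two_anchor_3d",
                                     "two_anchor_3d_hydration"),
                            anchor_positions = NULL,
                            well_depths = NULL,
                            well_widths = 0.1,
                            repulsion_radius = 0,
                            hydration_coupling = 2,
                            h_bulk = 6, k_h = 10,
                            restraint = NULL,
                            RT = 2.577) {
  kind <- match.arg(kind)
  if (is.null(anchor_positions)) {
    anchor_positions <- if (kind == "double_well_1d") c(0.25, 2.25)
      else list(c(-0.15, 0, 0), c(0.15, 0, 0))
  }
  if (kind == "double_well_1d") {
    anchors <- matrix(as.numeric(anchor_positions), ncol = 1)
  } else {
    if (!is.list(anchor_positions)) anchor_positions <- list(anchor_positions)
    stopifnot(all(lengths(anchor_positions) == 3))
    anchors <- do.call(rbind, anchor_positions)
  }
  n_a <- nrow(anchors)
  well_depths <- rep_len(as.numeric(well_depths %||% 12), n_a)
  well_widths <- rep_len(as.numeric(well_widths), n_a)
  if (any(well_depths < 0)) abort("well_depths must be >= 0")
  if (any(well_widths <= 0)) abort("well_widths must be > 0")
  if (repulsion_radius < 0) abort("repulsion_radius must be >= 0")
  if (is.null(restraint)) {
    restraint <- if (kind == "double_well_1d") {
      restraint_spec("flat_bottom_interval",
                     axial_range = range(anchors) + c(-0.5, 0.5))
    } else {
      restraint_spec("flat_bottom_cylinder", axis = c(0, 1, 0),
                     R_cyl = 0.9, K_res = 1e5, axial_range = c(-0.45, 2.7))
    }
  }
  structure(
    list(kind = kind, anchors = anchors, well_depths = well_depths,
         well_widths = well_widths, repulsion_radius = repulsion_radius,
         hydration_coupling = hydration_coupling, h_bulk = h_bulk, k_h = k_h,
         restraint = restraint, RT = RT,
         n_dim = switch(kind, double_well_1d = 1L, two_anchor_3d = 3L,
                        two_anchor_3d_hydration = 4L)),
    class = "model_potential"
  )
}

# rest value of the hydration coordinate as a function of spatial position
hydration_rest_value <- function(spec, xyz) {
  g <- 0
  for (i in seq_len(nrow(spec$anchors))) {
    rel <- sweep(xyz, 2, spec$anchors[i, ])
    g <- g + exp(-rowSums(rel^2) / (2 * spec$well_widths[i]^2))
  }
  spec$h_bulk - spec$hydration_coupling * g
}

#' Evaluate a model landscape
#'
#' Total potential energy (wells + soft-core repulsion + hydration tether +
#' restraint) at one or more points of the sampler space.
#'
#' @param spec A [model_potential()].
#' @param coords A point (numeric vector of length `spec$n_dim`: 1 for
#'   `double_well_1d`, 3 for `two_anchor_3d`, 4 with hydration) or a matrix
#'   of points, one per row.
#' @param include_restraint Include the restraint energy (default `TRUE`).
#'
#' @return Energy in kJ/mol, one value per point.
#' @export
#' @examples
#' pot <- model_potential("double_well_1d", anchor_positions = c(0.25, 2.25),
#'                        well_depths = c(10, 8), well_widths = 0.1)
#' eval_potential(pot, 0.25)  # ~ -10 (depth at the left minimum)
eval_potential <- function(spec, coords, include_restraint = TRUE) {
  stopifnot(inherits(spec, "model_potential"))
  x <- if (is.matrix(coords)) coords else matrix(coords, nrow = 1)
  if (ncol(x) != spec$n_dim) {
    abort(sprintf("eval_potential: expected %d coordinate(s) for kind '%s', got %d",
                  spec$n_dim, spec$kind, ncol(x)))
  }
  n_sp <- ncol(spec$anchors)  # spatial dimensionality (1 or 3)
  xyz <- x[, seq_len(n_sp), drop = FALSE]
  u <- numeric(nrow(x))
  for (i in seq_len(nrow(spec$anchors))) {
    rel <- sweep(xyz, 2, spec$anchors[i, ])
    r2 <- rowSums(rel^2)
    u <- u - spec$well_depths[i] * exp(-r2 / (2 * spec$well_widths[i]^2))
    if (spec$repulsion_radius > 0) {
      u <- u + spec$RT * (spec$repulsion_radius^2 / r2)^6
    }
  }
  if (spec$kind == "two_anchor_3d_hydration") {
    h <- x[, 4]
    u <- u + 0.5 * spec$k_h * (h - hydration_rest_value(spec, xyz))^2
  }
  if (include_restraint) {
    u <- u + flat_bottom_energy(xyz, spec$restraint)
  }
  u
}
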