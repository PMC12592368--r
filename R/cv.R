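#' Specify a collective variable
#'
#' Collective variables (CVs) are the low-dimensional coordinates along which
#' bias is deposited and free energy estimated. Three kinds are supported:
#'
#' * `distance_to_anchor` — Euclidean distance (nm) from the particle to a
#'   fixed 3D point, the analogue of the cation-to-carboxyl-carbon distances
#'   L1/L2.
#' * `raw_coordinate` — a Cartesian component of the sampler state, by index.
#' * `coordination_number` — reads the auxiliary hydration coordinate of a
#'   hydration-aware landscape (by `index`), standing in for the smooth count
#'   of first-shell waters CN_W. `r0` records the switching-function radius
#'   used when computing coordination numbers from real distances with
#'   [coordination_number()].
#'
#' @param kind CV kind, see above.
#' @param anchor 3-vector (nm), for `distance_to_anchor`.
#' @param index 1-based coordinate index, for `raw_coordinate` and
#'   `coordination_number`.
#' @param r0 Switching radius in nm (metadata for `coordination_number`).
#' @param name CV name used in COLVAR/HILLS headers and grids.
#'
#' @return An object of class `cv_spec`.
#' @export
#' @examples
#' cv_spec("distance_to_anchor", anchor = c(-0.15, 0, 0), name = "L1")
cv_spec <- function(kind = c("distance_to_anchor", "coordination_number",
                             "raw_coordinate"),
                    anchor = NULL, index = NULL, r0 = NULL, name = "cv") {
  kind <- match.arg(kind)
  if (kind == "distance_to_anchor") {
    stopifnot(length(anchor) == 3)
  } else {
    if (is.null(index)) abort("cv_spec: `index` is required for this kind")
    if (kind == "coordination_number" && !is.null(r0) && r0 <= 0)
      abort("cv_spec: r0 must be > 0")
  }
  structure(list(kind = kind, anchor = anchor, index = as.integer(index %||% NA),
                 r0 = r0, name = name),
            class = "cv_spec")
}

# Evaluate a list of cv_specs on an n x d coordinate matrix -> n x n_cv matrix.
cv_values <- function(cvs, coords) {
  coords <- if (is.matrix(coords)) coords else matrix(coords, nrow = 1)
  out <- matrix(NA_real_, nrow(coords), length(cvs))
  for (k in seq_along(cvs)) {
    cv <- cvs[[k]]
    out[, k] <- switch(cv$kind,
      distance_to_anchor = {
        rel <- sweep(coords[, 1:3, drop = FALSE], 2, cv$anchor)
        sqrt(rowSums(rel^2))
      },
      raw_coordinate = coords[, cv$index],
      coordination_number = coords[, cv$index]
    )
  }
  colnames(out) <- purrr::map_chr(cvs, "name")
  out
}

#' Smooth coordination number from a rational switching function
#'
#' Counts contacts smoothly as `sum_i (1 - (r_i/r0)^6) / (1 - (r_i/r0)^12)`.
#' Each term equals `1 / (1 + (r_i/r0)^6)` identically, which is how it is
#' evaluated; the removable singularity at `r_i = r0` therefore takes its
#' limit value 1/2 exactly. Terms decrease smoothly and monotonically from 1
#' (contact) to 0 (far).
#'
#' @param distances Non-negative distances in nm.
#' @param r0 Switching radius in nm (> 0); e.g. 0.275 nm for the first
#'   hydration shell of Mg2+ and 0.310 nm for Ca2+.
#'
#' @return The coordination number (a single non-negative number).
#' @export
#' @examples
#' coordination_number(0.275, r0 = 0.275)  # exactly 0.5
#' coordination_number(c(0.2, 0.2, 0.2, 0.2, 0.21, 0.55), r0 = 0.275)
coordination_number <- function(distances, r0) {
  if (r0 <= 0) abort("coordination_number: r0 must be > 0")
  if (any(distances < 0)) abort("coordination_number: distances must be >= 0")
  sum(1 / (1 + (distances / r0)^6))
}
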