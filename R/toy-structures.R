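# local atom templates (nm, relative to CA) with roughly tetrahedral geometry;
# side chains built along +z so a Calpha-Calpha offset along z sets the pair
# geometry without side-chain clashes
residue_template <- function(residue_type) {
  ca_cb <- c(0.051, -0.051, 0.134)
  step <- 0.152 * c(0.33, -0.33, 0.883) / sqrt(0.33^2 + 0.33^2 + 0.883^2)
  base <- list(
    N  = c(-0.146, 0, 0),
    CA = c(0, 0, 0),
    C  = c(0.052, 0.143, 0),
    O  = c(0.095, 0.258, 0)
  )
  if (residue_type == "other") {
    return(c(base, list(CB = ca_cb)))
  }
  cg <- ca_cb + step
  sc <- switch(residue_type,
    ASP = list(CB = ca_cb, CG = cg,
               OD1 = cg + c(0.110, 0, 0.055), OD2 = cg + c(-0.110, 0, 0.055)),
    GLU = list(CB = ca_cb, CG = cg, CD = cg + step,
               OE1 = cg + step + c(0.110, 0, 0.055),
               OE2 = cg + step + c(-0.110, 0, 0.055)),
    LYS = list(CB = ca_cb, CG = cg),
    abort(paste("unsupported residue type:", residue_type))
  )
  c(base, sc)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Build a toy tetramer structure with prescribed acidic-pair geometry
#'
#' Generates a minimal all-atom structure (backbone plus side-chain stubs)
#' with `n_chains`-fold rotational symmetry about the z axis, mimicking the
#' arrangement of acidic residues around the intracellular entrance of a
#' tetrameric channel pore. Each chain carries the requested residue pairs
#' with exactly the requested Calpha-Calpha distances (realised along z, so
#' the tolerance is machine precision).
#'
#' @param n_chains Number of chains (>= 1); chains are named A, B, C, ...
#' @param pair_geometry A list of pairs, each a list/vector
#'   `(residue_type_a, residue_type_b, ca_distance_nm)` with residue types in
#'   ASP/GLU/LYS/other.
#' @param ring_radius Distance of the Calpha atoms from the symmetry axis,
#'   nm (default 1.5; adjacent chains then sit > 2 nm apart, so no
#'   inter-chain pairs arise at the default scan thresholds).
#'
#' @return An `ionbind_structure` tibble.
#' @export
#' @examples
#' s <- make_toy_tetramer(4, list(list("ASP", "ASP", 1.05)))
#' scan_sites(s)
make_toy_tetramer <- function(n_chains, pair_geometry, ring_radius = 1.5) {
  stopifnot(n_chains >= 1)
  if (!is.list(pair_geometry[[1]])) pair_geometry <- list(pair_geometry)
  atoms <- list()
  resnum <- 0L
  for (ch in seq_len(n_chains)) {
    chain <- LETTERS[ch]
    R <- rot_z(2 * pi * (ch - 1) / n_chains)
    resnum <- 0L
    for (j in seq_along(pair_geometry)) {
      pg <- pair_geometry[[j]]
      d <- as.numeric(pg[[3]])
      if (!is.finite(d) || d <= 0) {
        abort("make_toy_tetramer: ca_distance must be a positive length (nm)")
      }
      # pair j: residue a at z = 3*(j-1), residue b directly above at +d;
      # the 3 nm spacing keeps distinct pairs beyond every scan cutoff
      ca_a <- c(ring_radius, 0, 3 * (j - 1))
      ca_b <- ca_a + c(0, 0, d)
      for (side in 1:2) {
        rtype <- as.character(pg[[side]])
        ca <- if (side == 1) ca_a else ca_b
        tpl <- residue_template(rtype)
        resnum <- resnum + 1L
        resname <- if (rtype == "other") "ALA" else rtype
        for (an in names(tpl)) {
          pos <- as.vector(R %*% (ca + tpl[[an]]))
          atoms[[length(atoms) + 1L]] <- tibble::tibble(
            atom = an, element = substr(an, 1, 1), residue_name = resname,
            residue_number = 100L + resnum, chain_id = chain,
            altloc = " ", occupancy = 1,
            x = pos[1], y = pos[2], z = pos[3], model_id = 1L
          )
        }
      }
    }
  }
  new_structure(dplyr::bind_rows(atoms))
}
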