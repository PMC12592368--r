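# shared fixtures, built in code

# 1D double well with soft interval walls (K = 2000 keeps the auto timestep
# at 2.5e-4, so desk-scale runs stay fast)
dw_potential <- function(depths = c(14, 11), widths = 0.12,
                         minima = c(0.25, 2.25), K = 2000) {
  model_potential("double_well_1d", anchor_positions = minima,
                  well_depths = depths, well_widths = widths,
                  restraint = restraint_spec("flat_bottom_interval",
                                             K_res = K,
                                             axial_range = range(minima) + c(-0.5, 0.5)))
}

dw_cv <- function() list(cv_spec("raw_coordinate", index = 1, name = "x"))

dw_grid <- function() grid_spec("x", -0.3, 2.8, 124)

# basin free-energy difference (left of split minus right) of a 1D FES
basin_delta_f <- function(fes, split = 1.25) {
  tb <- tibble::as_tibble(fes)
  RT <- fes$RT
  bf <- function(sel) {
    v <- tb$fes_kj_mol[sel & is.finite(tb$fes_kj_mol)]
    -RT * log(sum(exp(-v / RT)))
  }
  bf(tb$x < split) - bf(tb$x >= split)
}

# independent 1D quadrature oracle: hand-written potential and trapezoid,
# no package internals
oracle_dw_basin_delta_f <- function(depths, widths, minima, K, RT = 2.577,
                                    split = 1.25) {
  widths <- rep_len(widths, 2)
  lo <- min(minima) - 0.5; hi <- max(minima) + 0.5
  x <- seq(lo - 0.2, hi + 0.2, by = 5e-4)
  U <- -depths[1] * exp(-(x - minima[1])^2 / (2 * widths[1]^2)) -
    depths[2] * exp(-(x - minima[2])^2 / (2 * widths[2]^2)) +
    0.5 * K * (pmax(lo - x, 0) + pmax(x - hi, 0))^2
  w <- exp(-U / RT)
  trap <- function(sel) {
    xs <- x[sel]; ys <- w[sel]
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  }
  -RT * (log(trap(x < split)) - log(trap(x >= split)))
}

# CA-only structure from a table of (chain, resnum, resname, x, y, z in nm)
make_ca_structure <- function(df) {
  new_structure(tibble::tibble(
    atom = "CA", element = "C", residue_name = df$resname,
    residue_number = as.integer(df$resnum), chain_id = df$chain,
    altloc = " ", occupancy = 1, x = df$x, y = df$y, z = df$z, model_id = 1L
  ))
}

# ASP residue with explicit side-chain geometry: CA at origin, CB on +z,
# N in the xz plane, CG placed by rotating the anti position (chi1 = 180)
# by `rot_deg` about the CA->CB axis (right-handed); OD1 continues anti
# along the chain so chi2 is well defined
asp_dihedral_fixture <- function(rot_deg = 0) {
  rot <- rot_deg * pi / 180
  Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1), 3, 3)
  n <- c(0.14, 0, -0.05)
  ca <- c(0, 0, 0)
  cb <- c(0, 0, 0.15)
  cg_anti <- c(-0.13, 0, 0.22)           # anti to N: chi1 = 180
  cg <- as.vector(Rz %*% cg_anti) + c(0, 0, 0) # rotation about z = CA->CB axis
  od1_anti_local <- c(0.11, 0, 0.08)     # from CG, roughly anti continuation
  od1 <- cg + as.vector(Rz %*% od1_anti_local)
  atoms <- tibble::tibble(
    atom = c("N", "CA", "CB", "CG", "OD1"),
    element = c("N", "C", "C", "C", "O"),
    residue_name = "ASP", residue_number = 10L, chain_id = "A",
    altloc = " ", occupancy = 1,
    x = c(n[1], ca[1], cb[1], cg[1], od1[1]),
    y = c(n[2], ca[2], cb[2], cg[2], od1[2]),
    z = c(n[3], ca[3], cb[3], cg[3], od1[3]),
    model_id = 1L
  )
  new_structure(atoms)
}

mirror_structure <- function(s) {
  s$y <- -s$y
  s
}

demo_test_config <- function(seed, n_steps = 2e6) {
  demo_config(seed = seed, n_steps = n_steps)
}
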