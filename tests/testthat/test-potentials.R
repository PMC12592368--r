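test_that("eval_potential reproduces stated depths and limits", {
  pot <- model_potential("double_well_1d", anchor_positions = c(0.25, 2.25),
                         well_depths = c(10, 8), well_widths = 0.1)
  # at either minimum the other well's contribution is ~exp(-200), negligible
  expect_equal(eval_potential(pot, 0.25, include_restraint = FALSE), -10,
               tolerance = 1e-9)
  expect_equal(eval_potential(pot, 2.25, include_restraint = FALSE), -8,
               tolerance = 1e-9)

  pot3 <- model_potential("two_anchor_3d", repulsion_radius = 0)
  # far from the anchors but on the cylinder axis: potential -> 0
  expect_equal(eval_potential(pot3, c(0, 2.5, 0)), 0, tolerance = 1e-6)

  # midpoint between anchors 0.3 nm apart, depths (10, 10), widths 0.1:
  # hand evaluation of the two Gaussian wells
  pot_mid <- model_potential("two_anchor_3d",
                             anchor_positions = list(c(-0.15, 0, 0), c(0.15, 0, 0)),
                             well_depths = c(10, 10), well_widths = 0.1,
                             repulsion_radius = 0)
  expected <- -2 * 10 * exp(-0.15^2 / (2 * 0.1^2))
  expect_equal(eval_potential(pot_mid, c(0, 0, 0), include_restraint = FALSE),
               expected)
})

test_that("eval_potential validates dimensionality and is symmetric", {
  pot <- model_potential("two_anchor_3d", well_depths = c(10, 10),
                         repulsion_radius = 0.05)
  expect_error(eval_potential(pot, c(0, 0)), "expected 3")
  # swap of equal anchors: mirror through the yz plane
  p <- c(0.05, 0.3, 0.1)
  expect_equal(eval_potential(pot, p),
               eval_potential(pot, c(-p[1], p[2], p[3])))
  # rotation about the cylinder axis (y)
  th <- 1.1
  rotp <- c(cos(th) * p[1] + sin(th) * p[3], p[2],
            -sin(th) * p[1] + cos(th) * p[3])
  pot_sym <- model_potential("two_anchor_3d",
                             anchor_positions = list(c(0, 0, 0), c(0, 0.3, 0)),
                             well_depths = c(10, 8), repulsion_radius = 0.05)
  expect_equal(eval_potential(pot_sym, p), eval_potential(pot_sym, rotp),
               tolerance = 1e-12)
})

test_that("hydration coordinate adds a tether that vanishes at its rest value", {
  pot <- model_potential("two_anchor_3d_hydration", well_depths = c(10, 10),
                         repulsion_radius = 0, hydration_coupling = 2)
  xyz <- c(0.4, 0.5, 0)
  u3 <- eval_potential(model_potential("two_anchor_3d", well_depths = c(10, 10),
                                       repulsion_radius = 0,
                                       restraint = pot$restraint), xyz)
  h_rest <- ionbindr:::hydration_rest_value(pot, matrix(xyz, 1))
  expect_equal(eval_potential(pot, c(xyz, h_rest)), u3)
  expect_gt(eval_potential(pot, c(xyz, h_rest + 1)), u3)
})

test_that("quadrature FES of an ideal gas matches the entropic closed form", {
  # zero well depths inside a cylinder; CV = distance to a point on the axis:
  # while the L-sphere fits inside the cylinder, FES = -2 RT ln(L) + const
  pot <- model_potential("two_anchor_3d",
                         anchor_positions = list(c(0, 1, 0), c(0, 1, 0)),
                         well_depths = 0, repulsion_radius = 0,
                         restraint = restraint_spec("flat_bottom_cylinder",
                                                    axis = c(0, 1, 0),
                                                    R_cyl = 0.7, K_res = 1e5,
                                                    axial_range = c(0, 2)))
  cv <- list(cv_spec("distance_to_anchor", anchor = c(0, 1, 0), name = "L"))
  g <- grid_spec("L", 0.1, 0.65, 55)
  fes <- reference_fes_by_quadrature(pot, g, cv, resolution = 0.005)
  tb <- tibble::as_tibble(fes)
  expected <- -2 * pot$RT * log(tb$L)
  expected <- expected - min(expected)
  expect_lt(max(abs(tb$fes_kj_mol - expected)), 0.05)
})

test_that("quadrature FES: symmetric double well has equal basins", {
  pot <- dw_potential(depths = c(12, 12), widths = 0.1)
  fes <- reference_fes_by_quadrature(pot, dw_grid(), dw_cv(),
                                     resolution = 0.002)
  expect_lt(abs(basin_delta_f(fes)), 0.02)
})

test_that("quadrature recovers an engineered 5.0 kJ/mol basin difference", {
  # the left well's width is calibrated with the independent trapezoid oracle
  # so the basin free-energy difference is exactly 5.0 kJ/mol
  depths <- c(15, 10); minima <- c(0.25, 2.25); K <- 2000
  w1 <- stats::uniroot(function(w) {
    oracle_dw_basin_delta_f(depths, c(w, 0.08), minima, K) + 5
  }, c(0.06, 0.2), tol = 1e-10)$root
  widths <- c(w1, 0.08)
  pot <- model_potential("double_well_1d", anchor_positions = minima,
                         well_depths = depths, well_widths = widths,
                         restraint = restraint_spec("flat_bottom_interval",
                                                    K_res = K,
                                                    axial_range = range(minima) + c(-0.5, 0.5)))
  fes <- reference_fes_by_quadrature(pot, dw_grid(), dw_cv(),
                                     resolution = 0.002)
  oracle <- oracle_dw_basin_delta_f(depths, widths, minima, K)
  got <- basin_delta_f(fes)
  expect_equal(got, oracle, tolerance = 0.01)
  expect_lt(abs(got - (-5.0)), 0.1)
})

test_that("quadrature converges under grid refinement", {
  pot <- dw_potential()
  f1 <- reference_fes_by_quadrature(pot, dw_grid(), dw_cv(), resolution = 0.004)
  f2 <- reference_fes_by_quadrature(pot, dw_grid(), dw_cv(), resolution = 0.002)
  expect_lt(abs(basin_delta_f(f1) - basin_delta_f(f2)), 0.05)
})

test_that("quadrature warns when the CV grid cannot resolve the wells", {
  pot <- dw_potential(widths = 0.03)
  coarse <- grid_spec("x", -0.3, 2.8, 30)  # bin width ~0.1 > width/2
  expect_warning(
    fes <- reference_fes_by_quadrature(pot, coarse, dw_cv(), resolution = 0.002),
    "under-resolved")
  expect_true(length(fes$provenance$warnings) > 0)
  expect_error(reference_fes_by_quadrature(pot, coarse, dw_cv(), resolution = -1),
               "resolution")
})

test_that("model_potential validates its invariants", {
  expect_error(model_potential("double_well_1d", well_depths = -1), "well_depths")
  expect_error(model_potential("double_well_1d", well_widths = 0), "well_widths")
  expect_error(model_potential("double_well_1d", repulsion_radius = -0.1),
               "repulsion_radius")
})

test_that("toy tetramer realises requested geometry and round-trips", {
  s <- make_toy_tetramer(4, list(list("ASP", "ASP", 1.05)))
  acidic <- unique(s[s$residue_name == "ASP", c("chain_id", "residue_number")])
  expect_equal(nrow(acidic), 8)
  for (ch in c("A", "B", "C", "D")) {
    expect_equal(ca_distance(s, paste0(ch, ":101"), paste0(ch, ":102")), 1.05,
                 tolerance = 1e-9)
  }
  s2 <- make_toy_tetramer(1, list(list("ASP", "GLU", 1.15)))
  expect_equal(ca_distance(s2, "A:101", "A:102"), 1.15, tolerance = 1e-9)
  expect_error(make_toy_tetramer(2, list(list("ASP", "ASP", -1))), "positive")

  # writer/reader round trip preserves coordinates to 1e-3 Angstrom
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s_back <- read_structure(f)
  expect_equal(nrow(s_back), nrow(s))
  expect_lt(max(abs(s_back$x - s$x)), 1e-4)  # nm
  expect_lt(max(abs(s_back$z - s$z)), 1e-4)
})
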