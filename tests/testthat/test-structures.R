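test_that("shipped PDB fixture reads with correct residues and elements", {
  f <- system.file("extdata", "asp_glu_pair.pdb", package = "ionbindr")
  s <- read_structure(f)
  res <- unique(s[, c("residue_name", "residue_number")])
  expect_equal(nrow(res), 2)
  expect_setequal(res$residue_name, c("ASP", "GLU"))
  expect_true(all(s$element[s$atom == "CA"] == "C"))
  expect_true(all(s$element[s$atom == "OD1"] == "O"))
})

test_that("mmCIF dialect yields the same structure as PDB", {
  fp <- system.file("extdata", "asp_glu_pair.pdb", package = "ionbindr")
  fc <- system.file("extdata", "asp_glu_pair.cif", package = "ionbindr")
  sp <- read_structure(fp)
  sc <- read_structure(fc)
  expect_equal(nrow(sp), nrow(sc))
  expect_equal(sp$atom, sc$atom)
  expect_lt(max(abs(sp$x - sc$x), abs(sp$y - sc$y), abs(sp$z - sc$z)), 1e-4)
})

test_that("altloc duplicates resolve to highest occupancy, ties to first", {
  pdb <- c(
    "ATOM      1  CA AASP A  10       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BASP A  10       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AASP A  10       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BASP A  10       4.000   0.000   0.000  0.50  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- read_structure(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$atom == "CA"], 0.2)  # occupancy 0.60 wins
  expect_equal(s$x[s$atom == "CB"], 0.3)  # tie: first in file
})

test_that("structure reader errors are informative", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_structure(f), "empty model")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.id", "_atom_site.Cartn_x",
               "1 2 3"), fc)
  expect_error(read_structure(fc), "ragged")
})

test_that("pair thresholds follow the component-distance arithmetic", {
  expect_equal(pair_threshold("ASP", "ASP"), 1.1)
  expect_equal(pair_threshold("ASP", "GLU"), 1.2)
  expect_equal(pair_threshold("GLU", "ASP"), 1.2)  # symmetric
  expect_equal(pair_threshold("GLU", "GLU"), 1.3)
  expect_error(pair_threshold("LYS", "ASP"), "non-acidic")
})

test_that("scan_sites applies strict class-specific cutoffs", {
  # DD at 1.05 < 1.1: one site per chain
  s <- make_toy_tetramer(4, list(list("ASP", "ASP", 1.05)))
  sites <- scan_sites(s)
  expect_equal(nrow(sites), 4)
  expect_true(all(sites$n_residues == 2))
  # DD at 1.25 > 1.1: nothing
  expect_equal(nrow(scan_sites(make_toy_tetramer(4, list(list("ASP", "ASP", 1.25))))), 0)
  # DD at 1.15 fails, DE at 1.15 passes (cutoff 1.2)
  expect_equal(nrow(scan_sites(make_toy_tetramer(1, list(list("ASP", "ASP", 1.15))))), 0)
  expect_equal(nrow(scan_sites(make_toy_tetramer(1, list(list("ASP", "GLU", 1.15))))), 1)
  # exactly at the threshold: excluded (strict inequality)
  at_thr <- make_ca_structure(tibble::tibble(
    chain = "A", resnum = c(1, 2), resname = "ASP",
    x = 0, y = 0, z = c(0, 1.1)))
  expect_equal(nrow(scan_sites(at_thr)), 0)
})

test_that("single-linkage merging unions chained pairs into one site", {
  chain <- make_ca_structure(tibble::tibble(
    chain = "A", resnum = 1:4, resname = "ASP",
    x = 0, y = 0, z = c(0, 1.0, 2.0, 3.0)))
  merged <- scan_sites(chain, merge = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_residues, 4)
  unmerged <- scan_sites(chain, merge = FALSE)
  expect_equal(nrow(unmerged), 3)
})

test_that("scan_sites is invariant under atom order and rigid motion", {
  s <- make_toy_tetramer(4, list(list("ASP", "GLU", 1.1), list("ASP", "ASP", 1.02)))
  base <- scan_sites(s)
  # shuffle atoms
  set.seed(1)
  shuffled <- new_structure(s[sample(nrow(s)), ])
  expect_equal(scan_sites(shuffled)$residues, base$residues)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  moved <- s
  moved$x <- xyz[, 1] + 3; moved$y <- xyz[, 2] - 2; moved$z <- xyz[, 3] + 1
  ms <- scan_sites(new_structure(moved))
  expect_equal(ms$residues, base$residues)
  expect_equal(purrr::map_dbl(ms$pairs, ~ .x$ca_distance_nm[1]),
               purrr::map_dbl(base$pairs, ~ .x$ca_distance_nm[1]),
               tolerance = 1e-9)
})

test_that("C4-symmetric tetramer yields four geometrically identical sites", {
  s <- make_toy_tetramer(4, list(list("ASP", "ASP", 1.05)))
  sites <- scan_sites(s)
  d <- purrr::map_dbl(sites$pairs, ~ .x$ca_distance_nm[1])
  expect_lt(diff(range(d)), 1e-6)
  r <- sqrt(sites$centroid_x^2 + sites$centroid_y^2)
  expect_lt(diff(range(r)), 1e-6)
})

test_that("axial slab filter restricts the scan", {
  s <- make_toy_tetramer(1, list(list("ASP", "ASP", 1.05), list("ASP", "ASP", 1.05)))
  # pairs sit at z ~ [0, 1.05] and [3, 4.05]
  all_sites <- scan_sites(s)
  expect_equal(nrow(all_sites), 2)
  slab <- scan_sites(s, z_range = c(-0.1, 1.2))
  expect_equal(nrow(slab), 1)
})

test_that("ca_distance basics and errors", {
  s <- make_ca_structure(tibble::tibble(
    chain = "A", resnum = c(1, 2), resname = "ASP",
    x = 0, y = 0, z = c(0, 1.1)))
  expect_equal(ca_distance(s, "A:1", "A:2"), 1.1)
  expect_equal(ca_distance(s, "A:1", "A:1"), 0)
  expect_error(ca_distance(s, "A:1", "A:9"), "not found")
})

test_that("side-chain dihedrals follow the IUPAC sign convention", {
  anti <- asp_dihedral_fixture(0)
  expect_equal(sidechain_dihedrals(anti, "A:10")[["chi1"]], 180)
  # +60 degree rotation about CA->CB from anti: chi1 = -120 by the
  # independent rotation-matrix construction in the fixture
  rot <- asp_dihedral_fixture(60)
  expect_equal(sidechain_dihedrals(rot, "A:10")[["chi1"]], -120,
               tolerance = 1e-9)
  # mirror image negates the angles (chi1 = 180 maps to itself)
  m <- mirror_structure(rot)
  expect_equal(sidechain_dihedrals(m, "A:10")[["chi1"]], 120, tolerance = 1e-9)
  # mirror negates chi2 (compare on the circle: 180 and -180 coincide)
  circ_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  expect_lt(circ_diff(sidechain_dihedrals(m, "A:10")[["chi2"]],
                      -sidechain_dihedrals(rot, "A:10")[["chi2"]]), 1e-9)
  # missing atom is named
  broken <- new_structure(anti[anti$atom != "CG", ])
  expect_error(sidechain_dihedrals(broken, "A:10"), "CG")
  # non-acidic residues rejected
  lys <- make_toy_tetramer(1, list(list("LYS", "ASP", 1.0)))
  expect_error(sidechain_dihedrals(lys, "A:101"), "ASP or GLU")
})

test_that("pore radius of an atom ring equals ring radius minus vdW", {
  ring <- make_ring_structure(8, ring_radius = 0.5, z = 0)
  p <- pore_profile(ring, z_min = 0, z_max = 0, step = 0.05)
  expect_equal(p$radius_nm, 0.5 - 0.17, tolerance = 1e-4)
})

test_that("pore profile minimum sits at the narrower ring", {
  two <- new_structure(dplyr::bind_rows(
    make_ring_structure(8, 0.5, z = 0),
    make_ring_structure(8, 0.4, z = 0.5, first_residue_number = 101L)))
  p <- pore_profile(two, z_min = -0.1, z_max = 0.6, step = 0.05)
  expect_equal(p$z_nm[which.min(p$radius_nm)], 0.5, tolerance = 0.051)
})

test_that("cylinder profile is constant and matches an exhaustive search", {
  rings <- purrr::map(seq(0, 1, by = 0.1), function(zz)
    make_ring_structure(12, 0.5, z = zz))
  cyl <- new_structure(dplyr::bind_rows(rings))
  p <- pore_profile(cyl, z_min = 0.2, z_max = 0.8, step = 0.05)
  expect_lt(diff(range(p$radius_nm)), 0.05 / 2)

  # exhaustive fine-grid oracle at one plane
  xyz <- as.matrix(cyl[, c("x", "y", "z")])
  grid <- expand.grid(x = seq(-0.3, 0.3, by = 0.005),
                      y = seq(-0.3, 0.3, by = 0.005))
  z0 <- 0.5
  rad <- apply(grid, 1, function(g) {
    min(sqrt((xyz[, 1] - g[1])^2 + (xyz[, 2] - g[2])^2 + (xyz[, 3] - z0)^2)) - 0.17
  })
  oracle <- max(rad)
  got <- p$radius_nm[abs(p$z_nm - z0) < 1e-9]
  expect_equal(got, oracle, tolerance = 0.05 / 2)
})

test_that("empty slices report the sentinel radius", {
  ring <- make_ring_structure(8, 0.5, z = 0)
  p <- pore_profile(ring, z_min = 0, z_max = 8, step = 4, max_radius = 2)
  expect_equal(p$radius_nm[p$z_nm == 8], 2)
})
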