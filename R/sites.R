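# one row per residue with its CA position; warns about acidic residues
# lacking a CA (they are skipped by the scanner)
residue_table <- function(structure, warn_missing_ca = TRUE) {
  res <- structure |>
    dplyr::distinct(.data$chain_id, .data$residue_number, .data$residue_name)
  ca <- structure |>
    dplyr::filter(.data$atom == "CA") |>
    dplyr::distinct(.data$chain_id, .data$residue_number, .keep_all = TRUE) |>
    dplyr::select("chain_id", "residue_number",
                  ca_x = "x", ca_y = "y", ca_z = "z")
  out <- dplyr::left_join(res, ca, by = c("chain_id", "residue_number"))
  miss <- is.na(out$ca_x) & out$residue_name %in% c("ASP", "GLU")
  if (warn_missing_ca && any(miss)) {
    warn(sprintf("skipping %d acidic residue(s) without a CA atom", sum(miss)))
  }
  out
}

get_atom_xyz <- function(structure, chain, resnum, atom_name) {
  row <- structure[structure$chain_id == chain &
                     structure$residue_number == resnum &
                     structure$atom == atom_name, ]
  if (nrow(row) == 0) {
    abort(sprintf("atom %s not found in residue %s:%d", atom_name, chain, resnum))
  }
  c(row$x[1], row$y[1], row$z[1])
}

parse_residue_ref <- function(ref) {
  if (is.character(ref)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort("residue ref must be 'chain:resnum'")
    list(chain = parts[1], resnum = as.integer(parts[2]))
  } else {
    list(chain = ref$chain_id %||% ref$chain, resnum = ref$residue_number %||% ref$resnum)
  }
}

#' Calpha-distance cutoff for an acidic residue pair
#'
#' The geometric criterion for a divalent-cation site assumes simultaneous
#' direct (not water-mediated) coordination by the carboxyl groups of two
#' acidic residues. The Calpha-Calpha cutoff is the sum of the Calpha-to-
#' carboxyl-carbon distance of each residue (0.25 nm for ASP, 0.35 nm for
#' GLU) plus twice the carboxyl-carbon-to-cation distance (2 x 0.3 nm):
#' 1.1 nm for DD, 1.2 nm for DE, 1.3 nm for EE pairs.
#'
#' @param type_a,type_b `"ASP"` or `"GLU"`.
#' @return The cutoff in nm (symmetric in its arguments).
#' @export
#' @examples
#' pair_threshold("ASP", "GLU")  # 1.2
pair_threshold <- function(type_a, type_b) {
  arm <- function(t) switch(t, ASP = 0.25, GLU = 0.35,
                            abort(paste("pair_threshold: non-acidic type", t)))
  arm(type_a) + arm(type_b) + 2 * 0.3
}

#' Scan a structure for candidate divalent-cation binding pairs
#'
#' Enumerates all ASP/GLU residue pairs (intra- and inter-chain) whose
#' Calpha-Calpha distance is strictly below the class-specific cutoff of
#' [pair_threshold()], optionally restricted to an axial slab (the
#' user-supplied stand-in for "the intracellular side of the TMD").
#'
#' @param structure An `ionbind_structure`.
#' @param z_range Optional length-2 numeric: keep residues whose CA axial
#'   coordinate (projection on `axis`) lies inside this range (nm).
#' @param axis Axis for the slab filter (default z).
#'
#' @return A tibble of candidate pairs, ordered by (chain, residue number):
#'   `chain_a`, `resnum_a`, `resname_a`, `chain_b`, `resnum_b`, `resname_b`,
#'   `pair_class` (DD/DE/EE), `ca_distance_nm`, `threshold_nm`.
#' @export
scan_pairs <- function(structure, z_range = NULL, axis = c(0, 0, 1)) {
  rt <- residue_table(structure)
  rt <- rt[rt$residue_name %in% c("ASP", "GLU") & !is.na(rt$ca_x), , drop = FALSE]
  if (!is.null(z_range)) {
    t_ax <- as.matrix(rt[, c("ca_x", "ca_y", "ca_z")]) %*% (axis / sqrt(sum(axis^2)))
    rt <- rt[t_ax >= z_range[1] & t_ax <= z_range[2], , drop = FALSE]
  }
  rt <- dplyr::arrange(rt, .data$chain_id, .data$residue_number)
  empty <- tibble::tibble(
    chain_a = character(), resnum_a = integer(), resname_a = character(),
    chain_b = character(), resnum_b = integer(), resname_b = character(),
    pair_class = character(), ca_distance_nm = numeric(),
    threshold_nm = numeric()
  )
  n <- nrow(rt)
  if (n < 2) return(empty)
  xyz <- as.matrix(rt[, c("ca_x", "ca_y", "ca_z")])
  dmat <- as.matrix(stats::dist(xyz))
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      thr <- pair_threshold(rt$residue_name[i], rt$residue_name[j])
      if (dmat[i, j] < thr) {
        cls <- paste0(substr(rt$residue_name[i], 1, 1) |>
                        (\(a) ifelse(a == "A", "D", "E"))(),
                      ifelse(substr(rt$residue_name[j], 1, 1) == "A", "D", "E"))
        cls <- paste(sort(strsplit(cls, "")[[1]]), collapse = "")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chain_a = rt$chain_id[i], resnum_a = rt$residue_number[i],
          resname_a = rt$residue_name[i],
          chain_b = rt$chain_id[j], resnum_b = rt$residue_number[j],
          resname_b = rt$residue_name[j],
          pair_class = cls, ca_distance_nm = dmat[i, j], threshold_nm = thr
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Identify candidate divalent-cation binding sites
#'
#' Runs [scan_pairs()] and, when `merge = TRUE`, unions pairs that share a
#' residue (single-linkage over the shared-residue relation) into composite
#' sites, reproducing multi-residue clusters as one site. Sites are numbered
#' deterministically by (chain, lowest residue number).
#'
#' @inheritParams scan_pairs
#' @param merge Merge pairs sharing a residue into one site (default `TRUE`).
#'
#' @return A tibble with one row per site: `site_id`, `n_residues`,
#'   `residues` (label string), `centroid_x/y/z` (nm, Calpha centroid), and
#'   a `pairs` list-column of member [scan_pairs()] rows. Zero rows when no
#'   acidic pairs qualify (not an error).
#' @export
#' @examples
#' s <- make_toy_tetramer(4, list(list("ASP", "ASP", 1.05)))
#' scan_sites(s)
scan_sites <- function(structure, z_range = NULL, axis = c(0, 0, 1),
                       merge = TRUE) {
  pairs <- scan_pairs(structure, z_range = z_range, axis = axis)
  empty <- tibble::tibble(site_id = integer(), n_residues = integer(),
                          residues = character(), centroid_x = numeric(),
                          centroid_y = numeric(), centroid_z = numeric(),
                          pairs = list())
  if (nrow(pairs) == 0) return(empty)
  key_a <- paste0(pairs$chain_a, ":", pairs$resnum_a)
  key_b <- paste0(pairs$chain_b, ":", pairs$resnum_b)
  if (merge) {
    keys <- unique(c(key_a, key_b))
    comp <- seq_along(keys)  # union-find over shared residues
    names(comp) <- keys
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (p in seq_len(nrow(pairs))) {
      ra <- find(match(key_a[p], keys)); rb <- find(match(key_b[p], keys))
      if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
    }
    group <- vapply(seq_along(keys), find, integer(1))
    pair_group <- group[match(key_a, keys)]
  } else {
    pair_group <- seq_len(nrow(pairs))
  }
  rt <- residue_table(structure, warn_missing_ca = FALSE)
  rt_key <- paste0(rt$chain_id, ":", rt$residue_number)
  sites <- unique(pair_group) |>
    purrr::map(function(g) {
      pp <- pairs[pair_group == g, , drop = FALSE]
      keys <- sort(unique(c(paste0(pp$chain_a, ":", pp$resnum_a),
                            paste0(pp$chain_b, ":", pp$resnum_b))))
      ri <- match(keys, rt_key)
      ord <- order(rt$chain_id[ri], rt$residue_number[ri])
      ri <- ri[ord]
      tibble::tibble(
        n_residues = length(ri),
        residues = paste0(rt$chain_id[ri], ":", rt$residue_name[ri],
                          rt$residue_number[ri], collapse = ","),
        centroid_x = mean(rt$ca_x[ri]), centroid_y = mean(rt$ca_y[ri]),
        centroid_z = mean(rt$ca_z[ri]),
        first_chain = rt$chain_id[ri][1],
        first_resnum = rt$residue_number[ri][1],
        pairs = list(pp)
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$first_chain, .data$first_resnum)
  sites$site_id <- seq_len(nrow(sites))
  sites |>
    dplyr::select("site_id", "n_residues", "residues",
                  "centroid_x", "centroid_y", "centroid_z", "pairs")
}

#' Calpha-Calpha distance between two residues
#'
#' @param structure An `ionbind_structure`.
#' @param ref_a,ref_b Residue references, `"chain:resnum"` strings.
#' @return Euclidean distance in nm.
#' @export
#' @examples
#' s <- make_toy_tetramer(1, list(list("ASP", "ASP", 1.05)))
#' ca_distance(s, "A:101", "A:102")
ca_distance <- function(structure, ref_a, ref_b) {
  a <- parse_residue_ref(ref_a); b <- parse_residue_ref(ref_b)
  pa <- get_atom_xyz(structure, a$chain, a$resnum, "CA")
  pb <- get_atom_xyz(structure, b$chain, b$resnum, "CA")
  sqrt(sum((pa - pb)^2))
}

signed_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  # IUPAC sign: sin(phi) proportional to (n1 x n2) . b2_hat
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(n1xn2 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Side-chain dihedral angles of an acidic residue
#'
#' Signed chi1 (N-CA-CB-CG) and chi2 (CA-CB-CG-OD1 for ASP, CA-CB-CG-CD for
#' GLU) dihedrals in degrees, IUPAC sign convention, range (-180, 180].
#'
#' @param structure An `ionbind_structure`.
#' @param ref Residue reference, `"chain:resnum"`.
#' @return A named numeric vector `c(chi1 = , chi2 = )`.
#' @export
sidechain_dihedrals <- function(structure, ref) {
  r <- parse_residue_ref(ref)
  rn <- structure$residue_name[structure$chain_id == r$chain &
                                 structure$residue_number == r$resnum][1]
  if (is.na(rn) || !rn %in% c("ASP", "GLU")) {
    abort("sidechain_dihedrals: residue must be ASP or GLU")
  }
  chi2_last <- if (rn == "ASP") "OD1" else "CD"
  at <- function(nm) get_atom_xyz(structure, r$chain, r$resnum, nm)
  c(chi1 = signed_dihedral(at("N"), at("CA"), at("CB"), at("CG")),
    chi2 = signed_dihedral(at("CA"), at("CB"), at("CG"), at(chi2_last)))
}
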