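#' @rdname read_structure
#' @param atoms A tibble of atom records (see Details of [read_structure()]).
#' @export
new_structure <- function(atoms) {
  req <- c("atom", "element", "residue_name", "residue_number", "chain_id",
           "altloc", "occupancy", "x", "y", "z", "model_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste("structure atoms missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("empty model: structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("structure coordinates must be finite")
  }
  out <- tibble::as_tibble(atoms[req])
  class(out) <- c("ionbind_structure", class(out))
  out
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "MG", "ZN", "CA", "NA", "CL", "MN", "BR") &
           nchar(atom_name) >= 4,  # 2-char elements occupy the full name field
         two, toupper(substr(nm, 1, 1)))
}

# keep the highest-occupancy altloc per (model, chain, residue, atom);
# ties resolved by file order
resolve_altlocs <- function(atoms) {
  atoms$`..ord` <- seq_len(nrow(atoms))
  out <- atoms |>
    dplyr::group_by(.data$model_id, .data$chain_id, .data$residue_number,
                    .data$residue_name, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$`..ord`,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$`..ord`)
  out$`..ord` <- NULL
  out
}

#' Read a protein structure
#'
#' Minimal PDB and mmCIF (`_atom_site` loop) readers sufficient for the
#' geometric operations of this package. Author residue numbering is used;
#' for duplicated altlocs the highest-occupancy copy is kept (ties: first in
#' file); hydrogens are retained but ignored by geometry operations.
#' Coordinates are Angstrom in the files and nm in the returned object; only
#' the first model is used unless `model` is given.
#'
#' @param path File path.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension by default.
#' @param model Model id to keep (default: the first in the file).
#'
#' @details The returned structure is a tibble of atom records with columns
#'   `atom` (name), `element`, `residue_name`, `residue_number` (author),
#'   `chain_id`, `altloc`, `occupancy`, `x`, `y`, `z` (nm) and `model_id`.
#'
#' @return An `ionbind_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- switch(format, pdb = parse_pdb(path), mmcif = parse_mmcif(path))
  if (nrow(atoms) == 0) abort(paste("empty model: no atom records in", path))
  keep_model <- model %||% atoms$model_id[1]
  atoms <- atoms[atoms$model_id == keep_model, , drop = FALSE]
  if (nrow(atoms) == 0) abort(paste("model", keep_model, "not present in", path))
  new_structure(resolve_altlocs(atoms))
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_id <- 1L
  model_of <- integer(length(lines))
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  cur <- 1L
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "MODEL")) {
      cur <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(cur)) cur <- model_id + 1L
      model_id <- cur
    }
    model_of[i] <- cur
  }
  al <- lines[is_atom]
  if (length(al) == 0) return(tibble::tibble())
  num <- function(s) suppressWarnings(as.numeric(s))
  xyz <- cbind(num(substr(al, 31, 38)), num(substr(al, 39, 46)),
               num(substr(al, 47, 54)))
  if (anyNA(xyz)) {
    abort(paste0("format error: unparseable coordinates in PDB file ", path))
  }
  elem <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  elem[elem == ""] <- guess_element(substr(al[elem == ""], 13, 16))
  occ <- num(substr(al, 55, 60))
  occ[is.na(occ)] <- 1
  tibble::tibble(
    atom = name,
    element = elem,
    residue_name = trimws(substr(al, 18, 20)),
    residue_number = as.integer(num(substr(al, 23, 26))),
    chain_id = trimws(substr(al, 22, 22)),
    altloc = substr(al, 17, 17),
    occupancy = occ,
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
    model_id = model_of[is_atom]
  )
}

parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0) {
    abort(paste("format error: no _atom_site loop in", path))
  }
  tags <- sub("^_atom_site\\.([^ ]+).*$", "\\1", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  if (length(body) == 0) abort(paste("format error: empty _atom_site loop in", path))
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != length(tags))) {
    abort(sprintf("format error: ragged _atom_site row (line %d) in %s",
                  body_start + which(nf != length(tags))[1] - 1, path))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  col <- function(nm, default = NA_character_) {
    if (nm %in% tags) m[, nm] else rep(default, nrow(m))
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  name <- gsub('"', "", col("auth_atom_id", NA))
  if (all(is.na(name))) name <- gsub('"', "", col("label_atom_id"))
  resname <- col("auth_comp_id")
  if (all(is.na(resname))) resname <- col("label_comp_id")
  chain <- col("auth_asym_id")
  if (all(is.na(chain))) chain <- col("label_asym_id", "A")
  alt <- col("label_alt_id", ".")
  alt[alt %in% c(".", "?")] <- " "
  occ <- num(col("occupancy", "1"))
  occ[is.na(occ)] <- 1
  elem <- col("type_symbol")
  elem[is.na(elem) | elem %in% c(".", "?")] <-
    guess_element(name[is.na(elem) | elem %in% c(".", "?")])
  model_id <- suppressWarnings(as.integer(col("pdbx_PDB_model_num", "1")))
  model_id[is.na(model_id)] <- 1L
  xyz <- cbind(num(col("Cartn_x")), num(col("Cartn_y")), num(col("Cartn_z")))
  if (anyNA(xyz)) abort(paste("format error: unparseable coordinates in", path))
  tibble::tibble(
    atom = name, element = toupper(elem), residue_name = resname,
    residue_number = as.integer(num(col("auth_seq_id", col("label_seq_id")))),
    chain_id = chain, altloc = alt, occupancy = occ,
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
    model_id = model_id
  )
}

#' Write a structure to PDB or mmCIF
#'
#' @param structure An `ionbind_structure`.
#' @param path Output path.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  a <- structure
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000,
      ifelse(nchar(a$atom) >= 4, a$atom, paste0(" ", a$atom)),
      a$altloc, a$residue_name, a$chain_id, a$residue_number,
      a$x * 10, a$y * 10, a$z * 10, a$occupancy, 0, a$element
    )
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_structure", "#", "loop_",
             paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                     "auth_atom_id", "auth_comp_id",
                                     "auth_asym_id", "auth_seq_id",
                                     "label_alt_id", "Cartn_x", "Cartn_y",
                                     "Cartn_z", "occupancy",
                                     "pdbx_PDB_model_num")))
    rows <- sprintf("ATOM %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %d",
                    seq_len(nrow(a)), a$element, a$atom, a$residue_name,
                    a$chain_id, a$residue_number,
                    ifelse(a$altloc == " ", ".", a$altloc),
                    a$x * 10, a$y * 10, a$z * 10, a$occupancy, a$model_id)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}
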