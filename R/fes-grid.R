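#' Free-energy surface on a CV grid
#'
#' Container for a free energy surface (FES): a [grid_spec()] plus an array
#' of free energies in kJ/mol, minimum over finite cells shifted to zero.
#' Unvisited cells are `NA`, never zero. Constructed by
#' [reference_fes_by_quadrature()], [reweight_to_fes()] and [project_fes()].
#'
#' @param grid A [grid_spec()].
#' @param free_energy Numeric array with dim `grid$n_bins` (kJ/mol).
#' @param RT Thermal energy in kJ/mol.
#' @param provenance Named list recording how the surface was obtained.
#' @param counts Optional array of per-cell effective sample sizes.
#'
#' @return An object of class `fes_grid`.
#' @export
fes_grid <- function(grid, free_energy, RT, provenance = list(), counts = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  free_energy <- array(free_energy, dim = grid$n_bins)
  fin <- is.finite(free_energy)
  if (!any(fin)) abort("fes_grid: no finite free-energy cells")
  free_energy[!fin] <- NA_real_
  free_energy <- free_energy - min(free_energy, na.rm = TRUE)
  structure(list(grid = grid, free_energy = free_energy, RT = RT,
                 provenance = provenance, counts = counts),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid>", paste(x$grid$n_bins, collapse = " x "), "cells over",
      paste(x$grid$cv_names, collapse = ", "), "\n")
  cat("  finite cells:", sum(is.finite(x$free_energy)), "of",
      length(x$free_energy),
      "| max F:", signif(max(x$free_energy, na.rm = TRUE), 4), "kJ/mol\n")
  invisible(x)
}

#' Long-format view of a free-energy surface
#'
#' @param x A [fes_grid()].
#' @param ... Unused.
#' @return A tibble with one row per grid cell: bin-center columns named
#'   after the CVs, `fes_kj_mol`, and `n_eff` when available.
#' @export
as_tibble.fes_grid <- function(x, ...) {
  out <- grid_centers_tbl(x$grid)
  out$fes_kj_mol <- as.vector(x$free_energy)
  if (!is.null(x$counts)) out$n_eff <- as.vector(x$counts)
  out
}

#' Write / read a free-energy surface as CSV
#'
#' The CSV holds the long-format view (`cv..., fes_kj_mol`); grid geometry is
#' recovered from the bin centers on read.
#'
#' @param fes A [fes_grid()].
#' @param path File path.
#' @return `write_fes` returns `path` invisibly; `read_fes` a [fes_grid()].
#' @export
write_fes <- function(fes, path) {
  readr::write_csv(as_tibble(fes), path)
  invisible(path)
}

#' @rdname write_fes
#' @param RT Thermal energy attached to the re-read surface.
#' @export
read_fes <- function(path, RT = 2.577) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  cvn <- setdiff(names(tb), c("fes_kj_mol", "n_eff"))
  centers <- purrr::map(cvn, ~ sort(unique(tb[[.x]])))
  w <- purrr::map_dbl(centers, ~ if (length(.x) > 1) min(diff(.x)) else 1)
  grid <- grid_spec(cvn,
                    min = purrr::map_dbl(centers, 1) - w / 2,
                    max = purrr::map_dbl(centers, ~ .x[length(.x)]) + w / 2,
                    n_bins = lengths(centers))
  # order rows to the grid's linear layout
  idx <- grid_linear_index(grid, grid_bin_index(grid, as.matrix(tb[cvn])))
  fe <- rep(NA_real_, prod(grid$n_bins))
  fe[idx] <- tb$fes_kj_mol
  fes_grid(grid, fe, RT = RT, provenance = list(source = path))
}
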