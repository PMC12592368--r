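#' Specify a rectangular grid over collective variables
#'
#' A `grid_spec` describes the domain on which free-energy surfaces are
#' histogrammed: per collective variable (CV) a `[min, max)` range divided
#' into `n_bins` equal half-open bins. Samples exactly at the global upper
#' edge are assigned to the last bin.
#'
#' @param cv_names Character vector of CV names.
#' @param min,max Numeric vectors (recycled) of lower/upper bounds per CV.
#' @param n_bins Integer vector (recycled) of bin counts per CV, each >= 2.
#'
#' @return An object of class `grid_spec`: a list with `cv_names`, `min`,
#'   `max`, `n_bins`, and a `centers` list of bin-center vectors.
#' @export
#' @examples
#' grid_spec(c("L1", "L2"), min = 0, max = 2.6, n_bins = 52)
grid_spec <- function(cv_names, min, max, n_bins) {
  d <- length(cv_names)
  min <- rep_len(as.numeric(min), d)
  max <- rep_len(as.numeric(max), d)
  n_bins <- rep_len(as.integer(n_bins), d)
  if (any(max <= min)) abort("grid_spec: max must exceed min for every CV")
  if (any(n_bins < 2L)) abort("grid_spec: n_bins must be >= 2")
  centers <- purrr::pmap(list(min, max, n_bins), function(lo, hi, n) {
    w <- (hi - lo) / n
    lo + w * (seq_len(n) - 0.5)
  })
  names(centers) <- cv_names
  structure(
    list(cv_names = cv_names, min = min, max = max, n_bins = n_bins,
         centers = centers),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste0(
    x$cv_names, " [", signif(x$min, 4), ", ", signif(x$max, 4), ") x ",
    x$n_bins, collapse = "; "
  ), "\n")
  invisible(x)
}

grid_dim <- function(grid) length(grid$cv_names)

grid_bin_width <- function(grid) (grid$max - grid$min) / grid$n_bins

# Map an n x d matrix of CV values to per-dimension bin indices (NA outside).
# Half-open bins [lo, hi); values exactly at the global max edge go to the
# last bin.
grid_bin_index <- function(grid, cv) {
  cv <- as.matrix(cv)
  d <- grid_dim(grid)
  stopifnot(ncol(cv) == d)
  w <- grid_bin_width(grid)
  idx <- matrix(NA_integer_, nrow(cv), d)
  for (j in seq_len(d)) {
    k <- floor((cv[, j] - grid$min[j]) / w[j]) + 1
    k[cv[, j] == grid$max[j]] <- grid$n_bins[j]
    k[k < 1 | k > grid$n_bins[j]] <- NA_integer_
    idx[, j] <- as.integer(k)
  }
  idx
}

# Collapse per-dimension indices to a single linear index (NA if any NA).
grid_linear_index <- function(grid, idx) {
  d <- grid_dim(grid)
  lin <- idx[, 1]
  mult <- 1L
  if (d > 1) {
    for (j in 2:d) {
      mult <- mult * grid$n_bins[j - 1]
      lin <- lin + (idx[, j] - 1L) * mult
    }
  }
  lin
}

# Long-format tibble of all bin centers, column order = cv_names.
grid_centers_tbl <- function(grid) {
  g <- rev(grid$centers)
  out <- tidyr::expand_grid(!!!g)
  out <- out[, rev(seq_along(g)), drop = FALSE]
  tibble::as_tibble(out)
}
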