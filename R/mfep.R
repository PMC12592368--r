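# bilinear interpolation of a 2D grid field (NA cells -> high plateau so the
# string avoids unvisited regions); returns value and central-difference
# gradient helpers

bilinear_field <- function(fes) {
  g <- fes$grid
  F <- fes$free_energy
  plateau <- max(F, na.rm = TRUE) + 5 * fes$RT
  F[is.na(F)] <- plateau
  cx <- g$centers[[1]]; cy <- g$centers[[2]]
  wx <- grid_bin_width(g)[1]; wy <- grid_bin_width(g)[2]
  value <- function(p) {
    ux <- (p[, 1] - cx[1]) / wx; uy <- (p[, 2] - cy[1]) / wy
    ux <- pmin(pmax(ux, 0), length(cx) - 1)
    uy <- pmin(pmax(uy, 0), length(cy) - 1)
    ix <- pmin(floor(ux), length(cx) - 2) + 1
    iy <- pmin(floor(uy), length(cy) - 2) + 1
    fx <- ux - (ix - 1); fy <- uy - (iy - 1)
    F[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      F[cbind(ix + 1, iy)] * fx * (1 - fy) +
      F[cbind(ix, iy + 1)] * (1 - fx) * fy +
      F[cbind(ix + 1, iy + 1)] * fx * fy
  }
  gradient <- function(p) {
    hx <- wx / 2; hy <- wy / 2
    gx <- (value(cbind(p[, 1] + hx, p[, 2])) -
             value(cbind(p[, 1] - hx, p[, 2]))) / (2 * hx)
    gy <- (value(cbind(p[, 1], p[, 2] + hy)) -
             value(cbind(p[, 1], p[, 2] - hy))) / (2 * hy)
    cbind(gx, gy)
  }
  list(value = value, gradient = gradient, plateau = plateau)
}

# equal-arclength reparameterisation of a polyline (endpoints kept)
reparam_equal_arclength <- function(nodes) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(nodes)
  t_new <- seq(0, s[length(s)], length.out = nrow(nodes))
  cbind(approx(s, nodes[, 1], xout = t_new)$y,
        approx(s, nodes[, 2], xout = t_new)$y)
}

# lowest-cost path over finite cells (uniform-cost search via igraph),
# used to seed the string when the straight line crosses missing cells
grid_seed_path <- function(fes, a, b) {
  g <- fes$grid
  nx <- g$n_bins[1]; ny <- g$n_bins[2]
  F <- fes$free_energy
  finite <- is.finite(F)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  edges <- list(); wts <- list()
  Fv <- as.vector(F)
  for (dxy in list(c(1L, 0L), c(0L, 1L))) {
    ix <- seq_len(nx - dxy[1]); iy <- seq_len(ny - dxy[2])
    from <- as.vector(outer(ix, iy, id))
    to <- as.vector(outer(ix + dxy[1], iy + dxy[2], id))
    keep <- finite[from] & finite[to]
    edges[[length(edges) + 1]] <- rbind(from[keep], to[keep])
    wts[[length(wts) + 1]] <- (Fv[from[keep]] + Fv[to[keep]]) / 2 + 1e-9
  }
  gr <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                           n = nx * ny, directed = FALSE)
  ia <- grid_bin_index(g, matrix(a, 1)); ib <- grid_bin_index(g, matrix(b, 1))
  if (anyNA(ia) || anyNA(ib)) abort("string_minimize: endpoints outside the grid")
  va <- id(ia[1], ia[2]); vb <- id(ib[1], ib[2])
  if (!finite[va] || !finite[vb]) {
    abort("string_minimize: an endpoint lies in a missing cell")
  }
  sp <- igraph::shortest_paths(gr, va, vb, weights = unlist(wts))$vpath[[1]]
  if (length(sp) == 0) abort("string_minimize: endpoints not connected through finite cells")
  v <- as.integer(sp)
  iy <- (v - 1L) %/% nx + 1L; ix <- v - (iy - 1L) * nx
  cbind(g$centers[[1]][ix], g$centers[[2]][iy])
}

#' Minimum free-energy path by the zero-temperature string method
#'
#' Finds the lowest-free-energy route between two points of a 2D FES: a chain
#' of nodes is moved down the bilinearly interpolated FES gradient and
#' reparameterised to equal arclength each iteration until the maximum node
#' displacement falls below `tol`. Endpoints stay fixed. The string is
#' initialised with the straight segment between the endpoints, or, when that
#' crosses unvisited (missing) cells, with a lowest-cost path over finite
#' cells.
#'
#' @param fes A 2D [fes_grid()].
#' @param endpoint_a,endpoint_b Numeric length-2 CV points inside the grid.
#' @param n_nodes Number of string nodes (default 100).
#' @param step_size Gradient-descent step in CV units (default: a quarter of
#'   the smaller grid spacing).
#' @param tol Convergence threshold on the maximum node displacement per
#'   iteration, in units of the smaller grid spacing (default 1e-4).
#' @param max_iter Iteration cap (default 5000); non-convergence returns the
#'   current path with `converged = FALSE` attribute.
#'
#' @return An `mfep_path` tibble: `node`, `arclength`, CV columns, and
#'   `fes_kj_mol`; attributes `converged`, `n_iterations`.
#' @export
string_minimize <- function(fes, endpoint_a, endpoint_b, n_nodes = 100,
                            step_size = NULL, tol = 1e-4, max_iter = 5000) {
  stopifnot(inherits(fes, "fes_grid"), length(fes$grid$cv_names) == 2)
  g <- fes$grid
  w <- grid_bin_width(g)
  step_size <- step_size %||% (min(w) / 4)
  fld <- bilinear_field(fes)

  idx_ab <- grid_bin_index(g, rbind(endpoint_a, endpoint_b))
  if (anyNA(idx_ab)) abort("string_minimize: endpoints must lie inside the grid")

  # initial path: straight line unless it crosses missing cells
  t0 <- seq(0, 1, length.out = n_nodes)
  nodes <- cbind(endpoint_a[1] + t0 * (endpoint_b[1] - endpoint_a[1]),
                 endpoint_a[2] + t0 * (endpoint_b[2] - endpoint_a[2]))
  lin_idx <- grid_linear_index(g, grid_bin_index(g, nodes))
  if (any(!is.finite(as.vector(fes$free_energy)[lin_idx]))) {
    seed <- grid_seed_path(fes, endpoint_a, endpoint_b)
    s <- c(0, cumsum(sqrt(rowSums(diff(seed)^2))))
    tt <- seq(0, s[length(s)], length.out = n_nodes)
    nodes <- cbind(approx(s, seed[, 1], xout = tt)$y,
                   approx(s, seed[, 2], xout = tt)$y)
  }

  lo <- g$min + w / 2; hi <- g$max - w / 2
  clamped <- FALSE
  converged <- FALSE
  it <- 0
  interior <- 2:(n_nodes - 1)
  step <- step_size
  prev_disp <- Inf
  while (it < max_iter) {
    it <- it + 1
    grad <- fld$gradient(nodes[interior, , drop = FALSE])
    gn <- sqrt(rowSums(grad^2))
    # cap per-iteration node moves at one grid cell
    scale <- ifelse(gn > 0, pmin(1, max(w) / (step * gn)), 0)
    prop <- nodes
    prop[interior, ] <- nodes[interior, ] - step * grad * scale
    outside <- prop[, 1] < lo[1] | prop[, 1] > hi[1] |
      prop[, 2] < lo[2] | prop[, 2] > hi[2]
    if (any(outside)) clamped <- TRUE
    prop[, 1] <- pmin(pmax(prop[, 1], lo[1]), hi[1])
    prop[, 2] <- pmin(pmax(prop[, 2], lo[2]), hi[2])
    prop <- reparam_equal_arclength(prop)
    disp <- max(sqrt(rowSums((prop - nodes)^2)))
    nodes <- prop
    if (disp < tol * min(w)) { converged <- TRUE; break }
    # on noisy surfaces the string oscillates around the valley floor; damp
    # the step whenever the displacement stops decreasing
    if (disp > prev_disp) step <- step * 0.8
    prev_disp <- disp
  }
  if (clamped) warn("string_minimize: path touched the grid boundary and was clamped")
  if (!converged) {
    warn(sprintf("string_minimize: not converged after %d iterations", max_iter))
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(nodes)^2))))
  out <- tibble::tibble(node = seq_len(n_nodes), arclength = arc)
  out[[g$cv_names[1]]] <- nodes[, 1]
  out[[g$cv_names[2]]] <- nodes[, 2]
  out$fes_kj_mol <- fld$value(nodes)
  attr(out, "converged") <- converged
  attr(out, "n_iterations") <- it
  class(out) <- c("mfep_path", class(out))
  out
}

#' Free-energy profile along a path
#'
#' Bilinearly interpolated FES values against cumulative arclength for an
#' ordered set of CV-space nodes.
#'
#' @param fes A 2D [fes_grid()].
#' @param path An `mfep_path` or a 2-column matrix of nodes.
#' @return A tibble with `arclength` and `fes_kj_mol` (monotone arclength).
#' @export
path_energy_profile <- function(fes, path) {
  g <- fes$grid
  nodes <- if (is.matrix(path)) path else as.matrix(path[, g$cv_names])
  idx <- grid_linear_index(g, grid_bin_index(g, nodes))
  missing_cell <- is.na(idx) | !is.finite(as.vector(fes$free_energy)[idx])
  if (any(missing_cell)) {
    abort(sprintf("path_energy_profile: node %d lies in a missing cell",
                  which(missing_cell)[1]))
  }
  fld <- bilinear_field(fes)
  arc <- c(0, cumsum(sqrt(rowSums(diff(nodes)^2))))
  tibble::tibble(arclength = arc, fes_kj_mol = fld$value(nodes))
}
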