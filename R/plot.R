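#' Plot a free-energy surface
#'
#' 1D surfaces plot as a profile; 2D surfaces as a filled heatmap with
#' contours, optionally overlaid with a minimum free-energy path.
#'
#' @param object A [fes_grid()].
#' @param mfep Optional `mfep_path` to overlay (2D only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes_grid <- function(object, mfep = NULL, ...) {
  tb <- as_tibble(object)
  cvn <- object$grid$cv_names
  if (length(cvn) == 1) {
    return(
      ggplot2::ggplot(tb, ggplot2::aes(.data[[cvn[1]]], .data$fes_kj_mol)) +
        ggplot2::geom_line() +
        ggplot2::labs(y = "free energy (kJ/mol)") +
        ggplot2::theme_minimal()
    )
  }
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data[[cvn[1]]], .data[[cvn[2]]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fes_kj_mol)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$fes_kj_mol),
                          colour = "white", alpha = 0.4, binwidth = 2.577) +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(mfep)) {
    p <- p + ggplot2::geom_path(data = mfep, colour = "black", linewidth = 0.8)
  }
  p
}

#' Plot a potential of mean force
#'
#' @param object A `pmf_profile` from [pmf_along_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cv, .data$pmf_kj_mol)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "cv_name") %||% "CV (nm)",
                  y = "PMF (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a block-analysis convergence curve
#'
#' SEM versus block size; a plateau indicates converged error estimates.
#'
#' @param object A `block_analysis_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.block_analysis_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$block_size, .data$sem)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "block size (samples)", y = "SEM") +
    ggplot2::theme_minimal()
}

#' Plot a pore-radius profile
#'
#' @param object A `pore_profile` from [pore_profile()].
#' @param water_radius Reference radius drawn as a dashed line (nm; default
#'   0.14, one water molecule).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_profile <- function(object, water_radius = 0.14, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$radius_nm, .data$z_nm)) +
    ggplot2::geom_vline(xintercept = water_radius, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "pore radius (nm)", y = "axial coordinate (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy profile along a minimum free-energy path
#'
#' @param object An `mfep_path` from [string_minimize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfep_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$arclength, .data$fes_kj_mol)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arclength (nm)", y = "free energy (kJ/mol)") +
    ggplot2::theme_minimal()
}
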