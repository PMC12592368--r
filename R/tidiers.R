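#' Tidy a binding free-energy result
#'
#' @param x A `binding_free_energy` from [standard_binding_free_energy()].
#' @param ... Unused.
#' @return One row per energy term: `term`, `estimate` (kJ/mol).
#' @export
tidy.binding_free_energy <- function(x, ...) {
  tibble::tibble(
    term = c("dG_PMF", "dG_V", "dG_I", "dG0"),
    estimate = c(x$dG_pmf, x$dG_V, x$dG_I, x$dG0)
  )
}

#' @rdname tidy.binding_free_energy
#' @return `glance`: a one-row tibble with `dG0`, `sem`, `n_blocks`,
#'   `ionic_strength`, `RT`.
#' @export
glance.binding_free_energy <- function(x, ...) {
  tibble::tibble(
    dG0 = x$dG0, sem = x$sem,
    n_blocks = if (is.null(x$blocks)) NA_integer_ else max(x$blocks$block_count),
    ionic_strength = x$settings$charges$I,
    RT = x$settings$constants$RT
  )
}

#' Tidy a block-analysis result
#'
#' @param x A `block_analysis_result` from [block_analysis()].
#' @param ... Unused.
#' @return The underlying tibble (`block_count`, `block_size`, `mean`, `sem`).
#' @export
tidy.block_analysis_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.block_analysis_result
#' @export
glance.block_analysis_result <- function(x, ...) {
  tibble::tibble(plateau_value = attr(x, "plateau_value"),
                 plateau_sem = attr(x, "plateau_sem"),
                 plateau_reached = attr(x, "plateau_reached") %||% NA)
}
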