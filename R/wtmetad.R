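#' Sampler parameters for the toy Langevin/WTMetaD engine
#'
#' @param n_steps Steps per walker.
#' @param seed Mandatory RNG seed (R's RNG drives the noise, so runs are
#'   bit-for-bit reproducible given seed, walker count and strides).
#' @param dt Timestep (toy units). `NULL` (default) lets [run_wtmetad()]
#'   derive a stable Euler-Maruyama step from the stiffest force constant in
#'   the system, `dt = 0.5 * friction / K_max` (the stability bound is
#'   `2 * friction / K_max`).
#' @param friction Friction coefficient (default 1); the diffusion constant
#'   is `RT/friction`.
#' @param RT Thermal energy, kJ/mol (default 2.577, 310 K).
#' @param deposit_stride Steps between hill depositions (default 500).
#' @param record_stride Steps between recorded samples (default 10).
#' @param h0 Base hill height, kJ/mol (default `0.3 * RT`; 0 disables bias).
#' @param gamma Well-tempered bias factor (> 1; default 5).
#' @param hill_widths Hill widths per CV; default 0.05 nm for distance CVs
#'   and 0.1 for coordination-number CVs (set by [run_wtmetad()] when `NULL`).
#'
#' @return A list of class `sampler_params`.
#' @export
sampler_params <- function(n_steps, seed, dt = NULL, friction = 1,
                           RT = 2.577, deposit_stride = 500,
                           record_stride = 10, h0 = 0.3 * RT, gamma = 5,
                           hill_widths = NULL) {
  if (missing(seed)) abort("sampler_params: a seed is mandatory")
  stopifnot(is.null(dt) || dt > 0, friction > 0, RT > 0, n_steps >= 1,
            deposit_stride >= 1,
            record_stride >= 1, h0 >= 0)
  if (h0 > 0 && gamma <= 1) abort("sampler_params: gamma must be > 1")
  structure(list(n_steps = as.integer(n_steps), seed = as.integer(seed),
                 dt = dt, friction = friction, RT = RT,
                 deposit_stride = as.integer(deposit_stride),
                 record_stride = as.integer(record_stride),
                 h0 = h0, gamma = gamma, hill_widths = hill_widths),
            class = "sampler_params")
}

#' Well-tempered hill height
#'
#' The height of the next deposited Gaussian given the bias already
#' accumulated at its centre: `h = h0 * exp(-V / ((gamma - 1) RT))`. Heights
#' decay geometrically at a repeatedly visited point; as `gamma -> Inf`
#' standard metadynamics (constant height) is recovered.
#'
#' @param h0 Base height, kJ/mol.
#' @param bias_at_center Accumulated bias at the hill centre, kJ/mol.
#' @param gamma Bias factor (> 1).
#' @param RT Thermal energy, kJ/mol.
#' @return The tempered height in kJ/mol.
#' @export
#' @examples
#' well_tempered_height(0.773, 0, 5, 2.577)          # h0
#' well_tempered_height(1, 4 * 2.577, 5, 2.577)      # h0 / e
well_tempered_height <- function(h0, bias_at_center, gamma, RT) {
  if (gamma <= 1) abort("well_tempered_height: gamma must be > 1")
  h0 * exp(-bias_at_center / ((gamma - 1) * RT))
}

#' Construct a bias state from a hills table
#'
#' @param hills Tibble with columns `time`, one centre column per CV (named
#'   after the CV), `sigma_<cv>` width columns, `height`, and optionally
#'   `biasf`.
#' @param gamma Bias factor.
#' @param h0 Base hill height.
#' @param cv_names CV names (defaults to the centre columns found).
#' @return A tibble of class `bias_state`.
#' @export
bias_state <- function(hills, gamma = 5, h0 = NULL, cv_names = NULL) {
  cv_names <- cv_names %||%
    setdiff(names(hills), c("time", "height", "biasf",
                            grep("^sigma_", names(hills), value = TRUE)))
  stopifnot(all(c("time", "height", cv_names,
                  paste0("sigma_", cv_names)) %in% names(hills)))
  if (any(hills$height < 0)) abort("bias_state: hill heights must be >= 0")
  if (any(as.matrix(hills[paste0("sigma_", cv_names)]) <= 0)) {
    abort("bias_state: hill widths must be > 0")
  }
  out <- tibble::as_tibble(hills)
  attr(out, "gamma") <- gamma
  attr(out, "h0") <- h0 %||% if (nrow(out)) max(out$height) else 0
  attr(out, "cv_names") <- cv_names
  class(out) <- c("bias_state", class(out))
  out
}

# Total bias of a hills set at arbitrary CV points (n x d matrix).
# Vectorised over samples, looped over hills, 5-sigma truncation unless exact.
bias_at <- function(bias, cv, exact = FALSE) {
  cvn <- attr(bias, "cv_names")
  cv <- if (is.matrix(cv)) cv else matrix(cv, ncol = length(cvn))
  V <- numeric(nrow(cv))
  if (nrow(bias) == 0) return(V)
  centers <- as.matrix(bias[cvn])
  sigmas <- as.matrix(bias[paste0("sigma_", cvn)])
  for (i in seq_len(nrow(bias))) {
    z2 <- 0
    for (k in seq_along(cvn)) {
      z2 <- z2 + ((cv[, k] - centers[i, k]) / sigmas[i, k])^2
    }
    if (exact) {
      V <- V + bias$height[i] * exp(-z2 / 2)
    } else {
      ok <- z2 < 25
      if (any(ok)) V[ok] <- V[ok] + bias$height[i] * exp(-z2[ok] / 2)
    }
  }
  V
}

default_hill_widths <- function(cvs) {
  purrr::map_dbl(cvs, ~ if (.x$kind == "coordination_number") 0.1 else 0.05)
}

default_bias_grid <- function(potential, cvs) {
  res <- potential$restraint
  lims <- purrr::map(cvs, function(cv) {
    switch(cv$kind,
      distance_to_anchor = {
        hi <- if (!is.null(res$axial_range)) {
          diff(range(c(res$axial_range, 0))) + res$R_cyl + 0.3
        } else 3
        c(0, hi)
      },
      raw_coordinate = {
        rng <- res$axial_range %||% c(-1, 3)
        rng + c(-0.2, 0.2)
      },
      coordination_number =
        c(potential$h_bulk - potential$hydration_coupling - 1.5,
          potential$h_bulk + 1.5)
    )
  })
  grid_spec(purrr::map_chr(cvs, "name"),
            min = purrr::map_dbl(lims, 1),
            max = purrr::map_dbl(lims, 2),
            n_bins = purrr::map_int(lims, ~ as.integer(ceiling(diff(.x) / 0.025))))
}

#' Run multiple-walker well-tempered metadynamics on a model landscape
#'
#' Euler-Maruyama overdamped Langevin dynamics on
#' `potential + shared bias + restraint`, with all walkers reading and
#' depositing into one shared bias in a fixed round-robin order every
#' `deposit_stride` steps. The bias is held on a CV-grid cache with hills
#' truncated at 5 sigma; `exact_bias = TRUE` switches to exact hill
#' summation (slower; used to validate the cache).
#'
#' @param potential A [model_potential()].
#' @param cvs List of [cv_spec()]s to bias.
#' @param params A [sampler_params()].
#' @param n_walkers Number of walkers (default 4).
#' @param init Optional matrix of initial positions (walkers x dims);
#'   defaults to deterministic positions spread along the restraint axis.
#' @param bias_grid Optional [grid_spec()] for the bias cache.
#' @param exact_bias Use exact hill summation instead of the grid cache.
#'
#' @return A list with `trajectories` (list of per-walker tibbles of class
#'   `ionbind_trajectory`: `step`, coordinate columns, CV columns, `bias`)
#'   and `bias` (a [bias_state()]).
#' @export
run_wtmetad <- function(potential, cvs, params, n_walkers = 4, init = NULL,
                        bias_grid = NULL, exact_bias = FALSE) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "sampler_params"), n_walkers >= 1)
  ndim <- potential$n_dim
  cv_names <- purrr::map_chr(cvs, "name")
  hill_widths <- params$hill_widths %||% default_hill_widths(cvs)
  stopifnot(length(hill_widths) == length(cvs), all(hill_widths > 0))
  bias_grid <- bias_grid %||% default_bias_grid(potential, cvs)
  if (is.null(params$dt)) {
    # Euler-Maruyama stability: dt < 2 friction / K for the stiffest force
    k_max <- max(potential$restraint$K_res,
                 potential$well_depths / potential$well_widths^2,
                 if (potential$kind == "two_anchor_3d_hydration") potential$k_h else 0)
    params$dt <- 0.5 * params$friction / k_max
  }

  if (is.null(init)) {
    res <- potential$restraint
    if (ndim == 1) {
      init <- matrix(seq(res$axial_range[1] + 0.1, res$axial_range[2] - 0.1,
                         length.out = max(n_walkers, 2))[seq_len(n_walkers)],
                     ncol = 1)
    } else {
      rng <- res$axial_range %||% c(0, 1)
      t0 <- seq(rng[1] + 0.15, rng[2] - 0.15,
                length.out = max(n_walkers, 2))[seq_len(n_walkers)]
      xyz <- t(vapply(t0, function(t) res$origin + t * res$axis, numeric(3)))
      init <- if (ndim == 4) cbind(xyz, potential$h_bulk) else xyz
    }
  }
  stopifnot(nrow(init) == n_walkers, ncol(init) == ndim)

  pot_in <- list(
    kind = switch(potential$kind, double_well_1d = 1L, two_anchor_3d = 2L,
                  two_anchor_3d_hydration = 3L),
    anchors = potential$anchors, ndim = ndim,
    depths = potential$well_depths, widths = potential$well_widths,
    rep_radius = potential$repulsion_radius, RT = potential$RT,
    hyd_c = potential$hydration_coupling, h_bulk = potential$h_bulk,
    k_h = potential$k_h
  )
  res <- potential$restraint
  res_in <- list(
    kind = switch(res$kind, flat_bottom_cylinder = 1L,
                  flat_bottom_interval = 2L, harmonic_point = 3L),
    axis = if (length(res$axis) == 3) res$axis else c(1, 0, 0),
    origin = if (length(res$origin) == 3) res$origin else c(0, 0, 0),
    R_cyl = res$R_cyl, K = res$K_res,
    has_axial = !is.null(res$axial_range),
    ax_lo = res$axial_range[1] %||% 0, ax_hi = res$axial_range[2] %||% 0
  )
  cvs_in <- purrr::map(cvs, function(cv) {
    list(kind = switch(cv$kind, distance_to_anchor = 1L, raw_coordinate = 2L,
                       coordination_number = 3L),
         index = if (is.na(cv$index)) 1L else cv$index,
         anchor = cv$anchor %||% c(0, 0, 0))
  })
  par_in <- list(dt = params$dt, friction = params$friction, RT = params$RT,
                 n_steps = params$n_steps,
                 deposit_stride = params$deposit_stride,
                 record_stride = params$record_stride, h0 = params$h0,
                 gamma = params$gamma, exact_bias = exact_bias,
                 hill_widths = hill_widths)
  grid_in <- list(min = bias_grid$min, max = bias_grid$max,
                  n_bins = bias_grid$n_bins)

  set.seed(params$seed)
  out <- .run_wtmetad_cpp(pot_in, cvs_in, res_in, par_in, grid_in, init)

  coord_names <- paste0("x", seq_len(ndim))
  trajectories <- purrr::imap(out$records, function(m, w) {
    colnames(m) <- c("step", coord_names, cv_names, "bias")
    tb <- tibble::as_tibble(m)
    tb$step <- as.integer(tb$step)
    attr(tb, "walker_id") <- w
    attr(tb, "params") <- params
    attr(tb, "cv_names") <- cv_names
    class(tb) <- c("ionbind_trajectory", class(tb))
    tb
  })
  hm <- out$hills
  hills <- tibble::as_tibble(
    setNames(as.data.frame(hm),
             c("time", cv_names, paste0("sigma_", cv_names), "height", "biasf"))
  )
  list(trajectories = trajectories,
       bias = bias_state(hills, gamma = params$gamma, h0 = params$h0,
                         cv_names = cv_names))
}
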