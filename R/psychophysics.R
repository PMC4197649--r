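#' Decision-stage configuration for 2AFC simulation
#'
#' One trial presents a dynamic RDS at a crossed or uncrossed disparity; each
#' detector's response is averaged over `frames_per_trial` independent dot
#' patterns; the near-minus-far difference is corrupted by a single draw of
#' zero-mean Gaussian decision noise and thresholded at zero to yield the
#' choice. Each psychometric data point pools `2 * trials_per_side *
#' n_blocks` trials (crossed and uncrossed interleaved within blocks; the
#' block structure is bookkeeping only).
#'
#' @param frames_per_trial Dot patterns averaged per trial.
#' @param noise_sigma SD of the decision noise. `NULL` (default) selects the
#'   model-appropriate value in [psychometric_curve()]: 0.1 for the
#'   correlation/matching detectors, 1000 for the energy detectors.
#' @param trials_per_side Trials per block for each of crossed and uncrossed.
#' @param n_blocks Number of blocks.
#' @param seed Optional integer seed applied before simulation.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(frames_per_trial = 16L, noise_sigma = NULL,
                            trials_per_side = 30L, n_blocks = 20L,
                            seed = NULL) {
  if (frames_per_trial < 1 || trials_per_side < 1 || n_blocks < 1)
    abort("all trial counts must be positive")
  if (!is.null(noise_sigma) && noise_sigma < 0)
    abort("noise_sigma must be >= 0")
  structure(list(frames_per_trial = as.integer(frames_per_trial),
                 noise_sigma = noise_sigma,
                 trials_per_side = as.integer(trials_per_side),
                 n_blocks = as.integer(n_blocks),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "decision_config")
}

psychometric_models <- c("matching", "correlation", "threshold_energy", "energy")

default_noise_sigma <- function(model) {
  if (model %in% c("matching", "correlation")) 0.1 else 1000
}

# Per-frame near/far detector outputs for n frames of a stimulus with
# disparity sign `side` (+1 uncrossed, -1 crossed). Pixel models use the
# square-window operators on single-pixel RDSs; energy models use Gabor
# detectors on dot-based RDSs.
detector_frame_outputs <- function(model, n, density, correlation, side,
                                   stim, units) {
  if (model %in% c("matching", "correlation")) {
    mag <- abs(stim$stimulus_disparity)
    out <- .frame_outputs_cpp(n, stim$center_size, stim$surround_size,
                              density, correlation, side * mag, -mag, mag)
    if (model == "correlation") out[, 1:2, drop = FALSE]
    else out[, 3:4, drop = FALSE]
  } else {
    spec <- stim
    spec$dot_density <- density
    spec$binocular_correlation <- correlation
    spec$stimulus_disparity <- side * abs(stim$stimulus_disparity)
    spec$seed <- NULL
    energy_detector_outputs(n, spec, units$near, units$far,
                            model = if (model == "energy") "energy"
                            else "threshold_energy")
  }
}

# Simulate all trials of one stimulus side at one correlation level.
# Returns logical vector: TRUE where the choice was "near".
simulate_choices <- function(model, n_trials, density, correlation, side,
                             sigma, frames_per_trial, stim, units) {
  out <- detector_frame_outputs(model, n_trials * frames_per_trial,
                                density, correlation, side, stim, units)
  diff <- colMeans(matrix(out[, 1] - out[, 2], nrow = frames_per_trial))
  z <- diff + if (sigma > 0) rnorm(n_trials, 0, sigma) else 0
  ties <- z == 0
  if (any(ties)) z[ties] <- runif(sum(ties)) - 0.5  # fair coin on exact ties
  z > 0
}

#' Run a single 2AFC near/far trial
#'
#' @param model One of `"matching"`, `"correlation"`, `"threshold_energy"`,
#'   `"energy"`.
#' @param density,correlation Stimulus dot density and binocular correlation.
#' @param crossed `TRUE` for the crossed (near) stimulus disparity.
#' @param cfg A [decision_config()].
#' @param stim Stimulus template: an [rds_spec()] for the pixel models
#'   (default 32/34-px geometry, disparity magnitude 2) or a
#'   [dot_rds_spec()] for the energy models (default 24-px field, 8-px dots,
#'   disparity magnitude 8).
#' @param params [gabor_params()] for the energy models.
#' @return `"near"` or `"far"`.
#' @export
run_trial <- function(model = psychometric_models, density = 0.25,
                      correlation = 1, crossed = TRUE,
                      cfg = decision_config(), stim = NULL, params = NULL) {
  model <- match.arg(model)
  setup <- psychometric_setup(model, cfg, stim, params)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  near <- simulate_choices(model, 1L, density, correlation,
                           if (crossed) -1 else 1, setup$sigma,
                           cfg$frames_per_trial, setup$stim, setup$units)
  if (near) "near" else "far"
}

psychometric_setup <- function(model, cfg, stim, params) {
  sigma <- cfg$noise_sigma %||% default_noise_sigma(model)
  if (model %in% c("matching", "correlation")) {
    stim <- stim %||% rds_spec()
    if (!inherits(stim, "rds_spec"))
      abort("pixel models need an rds_spec stimulus template")
    units <- NULL
  } else {
    stim <- stim %||% dot_rds_spec()
    if (!inherits(stim, "dot_rds_spec"))
      abort("energy models need a dot_rds_spec stimulus template")
    params <- params %||% gabor_params(field_size = stim$image_size)
    d_deg <- abs(stim$stimulus_disparity) * params$pixel_pitch
    units <- list(near = energy_unit(-d_deg, params),
                  far = energy_unit(d_deg, params))
  }
  list(stim = stim, units = units, sigma = sigma)
}

#' Simulated psychometric function for near/far discrimination
#'
#' Percent correct as a function of binocular correlation at a fixed dot
#' density, from opponent decoding of a near and a far detector. Crossed
#' trials count as correct when the model chooses "near", uncrossed when it
#' chooses "far"; both are pooled per level.
#'
#' @inheritParams run_trial
#' @param levels Binocular-correlation levels, strictly increasing, in
#'   `[-1, 1]`.
#' @return A tibble of class `psychometric_curve` with columns `correlation`,
#'   `n_trials`, `n_correct`, `pct_correct`, `se`, and attributes `model`,
#'   `density`, `noise_sigma`, `frames_per_trial`, `zero_crossing`.
#' @export
#' @examples
#' cfg <- decision_config(trials_per_side = 5, n_blocks = 2, seed = 1)
#' psychometric_curve("matching", density = 0.25,
#'                    levels = c(-1, 0, 1), cfg = cfg)
psychometric_curve <- function(model = psychometric_models, density = 0.25,
                               levels = seq(-1, 1, by = 0.25),
                               cfg = decision_config(), stim = NULL,
                               params = NULL) {
  model <- match.arg(model)
  if (any(abs(levels) > 1)) abort("correlation levels must lie in [-1, 1]")
  if (is.unsorted(levels, strictly = TRUE))
    abort("correlation levels must be strictly increasing")
  setup <- psychometric_setup(model, cfg, stim, params)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_side <- cfg$trials_per_side * cfg$n_blocks
  res <- purrr::map(levels, function(cc) {
    near_when_crossed <- simulate_choices(
      model, n_side, density, cc, -1, setup$sigma, cfg$frames_per_trial,
      setup$stim, setup$units)
    near_when_uncrossed <- simulate_choices(
      model, n_side, density, cc, 1, setup$sigma, cfg$frames_per_trial,
      setup$stim, setup$units)
    n_correct <- sum(near_when_crossed) + sum(!near_when_uncrossed)
    tibble(correlation = cc, n_trials = 2L * n_side, n_correct = n_correct)
  })
  out <- bind_rows(res)
  out$pct_correct <- 100 * out$n_correct / out$n_trials
  p <- out$n_correct / out$n_trials
  out$se <- 100 * sqrt(p * (1 - p) / out$n_trials)
  attr(out, "model") <- model
  attr(out, "density") <- density
  attr(out, "noise_sigma") <- setup$sigma
  attr(out, "frames_per_trial") <- cfg$frames_per_trial
  attr(out, "zero_crossing") <- estimate_zero_crossing(out)
  class(out) <- c("psychometric_curve", class(out))
  out
}

#' Zero crossing of a psychometric curve
#'
#' Binocular correlation at which the curve crosses 50% correct: linear
#' interpolation between the first adjacent pair of levels bracketing 50%
#' (a level exactly at 50% is returned as is). `NA` when no bracket exists.
#'
#' @param curve A [psychometric_curve()] or any data frame with columns
#'   `correlation` and `pct_correct`.
#' @return A correlation value, or `NA` if the curve never crosses chance.
#' @export
estimate_zero_crossing <- function(curve) {
  x <- curve$correlation
  p <- curve$pct_correct - 50
  if (length(x) < 2L) return(NA_real_)
  exact <- which(p == 0)
  cross <- which(p[-length(p)] * p[-1] < 0)
  if (length(exact) && (!length(cross) || exact[1] <= cross[1]))
    return(x[exact[1]])
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  x[i] + (x[i + 1] - x[i]) * (-p[i]) / (p[i + 1] - p[i])
}

#' Psychometric curves across dot densities
#'
#' @inheritParams psychometric_curve
#' @param densities Dot densities to test.
#' @return A tibble of class `psychometric_family`: one
#'   [psychometric_curve()] per density, stacked, with a `density` column.
#' @export
density_sweep <- function(model = psychometric_models,
                          densities = c(0.25, 0.5, 0.75, 1),
                          levels = seq(-1, 1, by = 0.25),
                          cfg = decision_config(), stim = NULL,
                          params = NULL) {
  model <- match.arg(model)
  curves <- purrr::map(densities, function(rho) {
    cv <- psychometric_curve(model, rho, levels, cfg, stim, params)
    mutate(as_tibble(cv), density = rho,
           zero_crossing = attr(cv, "zero_crossing"))
  })
  out <- bind_rows(curves)
  attr(out, "model") <- model
  class(out) <- c("psychometric_family", class(out))
  out
}

#' Psychometric curves across decision-noise levels
#'
#' @inheritParams density_sweep
#' @param sigmas Decision-noise SDs.
#' @return A `psychometric_family` tibble with `noise_sigma` and `density`
#'   columns.
#' @export
noise_sweep <- function(model = psychometric_models,
                        sigmas = c(0.025, 0.05, 0.1, 0.2),
                        densities = 0.25,
                        levels = seq(-1, 1, by = 0.25),
                        cfg = decision_config(), stim = NULL,
                        params = NULL) {
  model <- match.arg(model)
  if (any(sigmas <= 0)) abort("noise SDs must be positive")
  grid <- tidyr::expand_grid(noise_sigma = sigmas, density = densities)
  out <- bind_rows(purrr::pmap(grid, function(noise_sigma, density) {
    cfg$noise_sigma <- noise_sigma
    cv <- psychometric_curve(model, density, levels, cfg, stim, params)
    mutate(as_tibble(cv), noise_sigma = noise_sigma, density = density,
           zero_crossing = attr(cv, "zero_crossing"))
  }))
  attr(out, "model") <- model
  class(out) <- c("psychometric_family", class(out))
  out
}
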