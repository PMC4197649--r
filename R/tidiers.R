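#' Tidy and summarise result objects
#'
#' broom-style methods. `tidy()` returns the per-observation table as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x A result object (`tuning_curve`, `psychometric_curve`,
#'   `psychometric_family`, `operator_distribution`, `sd_surface`).
#' @param ... Unused.
#' @return A tibble.
#' @name stereomatch-tidiers
NULL

strip_result_class <- function(x) {
  class(x) <- setdiff(class(x), c("tuning_curve", "psychometric_curve",
                                  "psychometric_family", "signal_surface",
                                  "sd_surface", "operator_distribution"))
  as_tibble(x)
}

#' @rdname stereomatch-tidiers
#' @export
tidy.tuning_curve <- function(x, ...) {
  mutate(strip_result_class(x), operator = attr(x, "operator"), .before = 1)
}

#' @rdname stereomatch-tidiers
#' @export
glance.tuning_curve <- function(x, ...) {
  i <- which.max(x$value)
  tibble(operator = attr(x, "operator"),
         peak_disparity = x$disparity[i], peak_value = x$value[i],
         baseline_value = mean(x$value[-i]), n_frames = x$n_frames[1])
}

#' @rdname stereomatch-tidiers
#' @export
tidy.psychometric_curve <- function(x, ...) {
  mutate(strip_result_class(x), model = attr(x, "model"),
         density = attr(x, "density"), .before = 1)
}

#' @rdname stereomatch-tidiers
#' @export
glance.psychometric_curve <- function(x, ...) {
  tibble(model = attr(x, "model"), density = attr(x, "density"),
         noise_sigma = attr(x, "noise_sigma"),
         frames_per_trial = attr(x, "frames_per_trial"),
         zero_crossing = attr(x, "zero_crossing"),
         n_trials = sum(x$n_trials))
}

#' @rdname stereomatch-tidiers
#' @export
glance.psychometric_family <- function(x, ...) {
  out <- x |>
    strip_result_class() |>
    group_by(dplyr::across(dplyr::any_of(c("density", "noise_sigma")))) |>
    summarise(zero_crossing = zero_crossing[1],
              n_trials = sum(n_trials), .groups = "drop")
  mutate(out, model = attr(x, "model"), .before = 1)
}

#' @rdname stereomatch-tidiers
#' @export
tidy.operator_distribution <- function(x, ...) strip_result_class(x)

#' @rdname stereomatch-tidiers
#' @export
glance.operator_distribution <- function(x, ...) {
  tibble(model = attr(x, "model"), k = attr(x, "k"),
         mean = attr(x, "mean"), sd = attr(x, "sd"),
         interval_lower = attr(x, "interval")[1],
         interval_upper = attr(x, "interval")[2])
}

#' @rdname stereomatch-tidiers
#' @export
glance.sd_surface <- function(x, ...) {
  x |>
    strip_result_class() |>
    group_by(model) |>
    summarise(max_sd = max(sd), .groups = "drop") |>
    mutate(k = attr(x, "k"), n_patterns = attr(x, "n_patterns"),
           n_runs = attr(x, "n_runs"))
}

utils::globalVariables(c("model", "zero_crossing", "n_trials", "density",
                         "correlation", "value", "pct_correct", "disparity",
                         "se", "probability"))
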