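#' Binocular combination probabilities
#'
#' Probability that a window pixel forms a contrast-matched, contrast-reversed
#' or background combination. When the window disparity equals the stimulus
#' disparity the pair samples corresponding dots, giving
#' `((1 + c) rho / 2, (1 - c) rho / 2, 1 - rho)`; at any other disparity the
#' two samples are independent dots, giving `(rho^2/2, rho^2/2, 1 - rho^2)`.
#'
#' @param c Binocular correlation in `[-1, 1]`.
#' @param rho Dot density in `[0, 1]`.
#' @param at_match `TRUE` for the aligned (matched) window disparity.
#' @return A tibble with columns `p_matched`, `p_reversed`, `p_background`
#'   (one row per input element; `c` and `rho` are recycled).
#' @export
#' @examples
#' combination_probabilities(c = 0, rho = 0.5, at_match = FALSE)
combination_probabilities <- function(c, rho, at_match = TRUE) {
  check_c_rho(c, rho)
  n <- max(length(c), length(rho), length(at_match))
  c <- rep_len(c, n); rho <- rep_len(rho, n); at_match <- rep_len(at_match, n)
  p_m <- ifelse(at_match, (1 + c) * rho / 2, rho^2 / 2)
  p_r <- ifelse(at_match, (1 - c) * rho / 2, rho^2 / 2)
  tibble(p_matched = p_m, p_reversed = p_r, p_background = 1 - p_m - p_r)
}

check_c_rho <- function(c, rho) {
  if (any(abs(c) > 1)) abort("binocular correlation must lie in [-1, 1]")
  if (any(rho < 0 | rho > 1)) abort("dot density must lie in [0, 1]")
  invisible(NULL)
}

#' Expected single-disparity operator value
#'
#' Expected value of a frame operator at the matched or an unmatched window
#' disparity, from the combination probabilities with codes `(1, -1, 0)`
#' (cross-correlation) or `(1, 0, 0)` (cross-matching).
#'
#' @param model `"correlation"` or `"matching"`.
#' @inheritParams combination_probabilities
#' @return Numeric vector of expected operator outputs.
#' @export
expected_operator_value <- function(model = c("correlation", "matching"),
                                    c, rho, at_match = TRUE) {
  model <- match.arg(model)
  p <- combination_probabilities(c, rho, at_match)
  codes <- if (model == "correlation") c(1, -1, 0) else c(1, 0, 0)
  as.numeric(as.matrix(p) %*% codes)
}

#' Expected signal strength
#'
#' Signed signal strength is the expected operator value at the matched
#' window disparity minus the value at an unmatched disparity
#' (peak - baseline):
#' * cross-correlation: `S_C(c, rho) = c * rho`, separable and odd-symmetric
#'   in `c`;
#' * cross-matching: `S_M(c, rho) = (c + 1) rho / 2 - rho^2 / 2`, not
#'   separable; its zero contour is the line `c = rho - 1`, and at `c = 0` it
#'   peaks at 50% density.
#'
#' @inheritParams combination_probabilities
#' @return Numeric vector (inputs recycled).
#' @export
#' @examples
#' signal_strength_matching(0, 0.5)      # 0.125, the c = 0 maximum
#' signal_strength_correlation(0.5, 0.25)
signal_strength_correlation <- function(c, rho) {
  check_c_rho(c, rho)
  c * rho
}

#' @rdname signal_strength_correlation
#' @export
signal_strength_matching <- function(c, rho) {
  check_c_rho(c, rho)
  (c + 1) * rho / 2 - rho^2 / 2
}

#' Trinomial probability of a window composition
#'
#' Probability that a window of `k = n_m + n_r + n_b` pixels contains exactly
#' `n_m` contrast-matched, `n_r` contrast-reversed and `n_b` background
#' combinations, the pixels being independent with a common probability
#' triple. Evaluated in log space (via [stats::dmultinom()]) so large `k`
#' stays finite.
#'
#' @param counts Length-3 nonnegative integer vector `(n_m, n_r, n_b)`, or a
#'   matrix with one such row per evaluation.
#' @param probs Length-3 probability vector `(p_m, p_r, p_b)` summing to 1,
#'   e.g. one row of [combination_probabilities()].
#' @param log Return log-probability?
#' @return Numeric vector of (log-)probabilities.
#' @export
trinomial_pmf <- function(counts, probs, log = FALSE) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L || any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    abort("probs must be three nonnegative values summing to 1")
  counts <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  if (ncol(counts) != 3L || any(counts < 0))
    abort("counts must be three nonnegative integers per row")
  apply(counts, 1, function(n) dmultinom(n, prob = probs, log = log))
}

# Exact E[[n_m - n_r]^+] for (n_m, n_r) trinomial-distributed over k pixels
# with per-pixel probabilities (p_m, p_r). Marginalizes the background count:
# m = n_m + n_r ~ Binom(k, p_m + p_r); n_m | m ~ Binom(m, p_m / (p_m + p_r)).
expected_rectified_diff <- function(p_m, p_r, k) {
  q <- p_m + p_r
  if (q <= 0) return(0)
  w <- p_m / q
  total <- 0
  for (m in seq_len(k)) {
    n_m <- 0:m
    pos <- 2 * n_m - m
    keep <- pos > 0
    if (!any(keep)) next
    total <- total + dbinom(m, k, q) *
      sum(dbinom(n_m[keep], m, w) * pos[keep])
  }
  total
}

#' Expected signal strength of generalized cross-matching
#'
#' Generalized cross-matching rectifies after averaging over a `k`-pixel
#' window; its value for a window composition `n` is `[n_m - n_r]^+ / k`.
#' The expected signal strength is the exact trinomial expectation at the
#' matched probabilities minus at the unmatched ones, enumerated over
#' `(n_m, n_r)` in `O(k^2)`. `k = 1` reproduces the original cross-matching
#' [signal_strength_matching()]; `k = Inf` gives the half-wave-rectified
#' cross-correlation `[c * rho]^+`.
#'
#' @inheritParams combination_probabilities
#' @param k Spatial-window size in pixels (positive integer) or `Inf`.
#' @return Numeric vector (over recycled `c`, `rho`).
#' @export
#' @examples
#' signal_strength_generalized(0, 0.5, k = 2)   # 0.078125
#' signal_strength_generalized(-1, 0.25, k = Inf)
signal_strength_generalized <- function(c, rho, k) {
  check_c_rho(c, rho)
  if (length(k) != 1L || is.na(k) || k < 1)
    abort("k must be a single positive integer or Inf")
  n <- max(length(c), length(rho))
  c <- rep_len(c, n); rho <- rep_len(rho, n)
  if (is.infinite(k)) return(pmax(c * rho, 0))
  k <- as.integer(k)
  pm <- combination_probabilities(c, rho, at_match = TRUE)
  pu <- combination_probabilities(c, rho, at_match = FALSE)
  vapply(seq_len(n), function(i) {
    (expected_rectified_diff(pm$p_matched[i], pm$p_reversed[i], k) -
       expected_rectified_diff(pu$p_matched[i], pu$p_reversed[i], k)) / k
  }, numeric(1))
}

#' Exact distribution of a frame operator output
#'
#' Probability mass function of the single-frame operator output over the
#' randomness of the dot pattern: `(n_m - n_r)/k` for cross-correlation,
#' `n_m/k` for cross-matching, with `(n_m, n_r)` trinomial. Also reports a
#' central interval: the equal-tail cut leaving at most 2.5% probability
#' strictly outside each end (so coverage is at least 95%).
#'
#' @param model `"correlation"` or `"matching"`.
#' @inheritParams combination_probabilities
#' @param k Window size in pixels.
#' @return A tibble of class `operator_distribution` with columns `value`,
#'   `probability`, and attributes `interval` (length-2), `mean`, `sd`,
#'   `model`, `k`.
#' @export
#' @examples
#' d <- operator_distribution("matching", c = 0, rho = 0.25, k = 64)
#' attr(d, "interval")
operator_distribution <- function(model = c("correlation", "matching"),
                                  c, rho, k, at_match = TRUE) {
  model <- match.arg(model)
  check_c_rho(c, rho)
  k <- as.integer(k)
  if (k < 1L) abort("k must be a positive integer")
  p <- combination_probabilities(c, rho, at_match)
  p_m <- p$p_matched; p_r <- p$p_reversed
  if (model == "matching") {
    value <- (0:k) / k
    probability <- dbinom(0:k, k, p_m)
  } else {
    q <- p_m + p_r
    probability <- numeric(2L * k + 1L)  # index s + k + 1, s = n_m - n_r
    if (q == 0) {
      probability[k + 1L] <- 1
    } else {
      w <- p_m / q
      for (m in 0:k) {
        n_m <- 0:m
        s <- 2L * n_m - m
        probability[s + k + 1L] <- probability[s + k + 1L] +
          dbinom(m, k, q) * dbinom(n_m, m, w)
      }
    }
    value <- (-k:k) / k
    keep <- probability > 0 | value == 0
    value <- value[keep]; probability <- probability[keep]
  }
  cum <- cumsum(probability)
  # equal-tail cut: largest lo with P(X < lo) <= 0.025, smallest hi with
  # P(X > hi) <= 0.025; boundary atoms included, so coverage >= 95%
  lo <- value[which(cum > 0.025)[1]]
  hi <- value[which(1 - cum <= 0.025)[1]]
  mu <- sum(value * probability)
  out <- tibble(value = value, probability = probability)
  attr(out, "interval") <- c(lo, hi)
  attr(out, "mean") <- mu
  attr(out, "sd") <- sqrt(max(sum(value^2 * probability) - mu^2, 0))
  attr(out, "model") <- model
  attr(out, "k") <- k
  class(out) <- c("operator_distribution", class(out))
  out
}

#' Expected signal-strength surface over correlation and density
#'
#' Evaluates the expected signal strength of a named model on a
#' (binocular correlation x dot density) grid.
#'
#' @param model `"correlation"`, `"matching"`, or `"generalized"` (then `k`
#'   is required).
#' @param c_grid,rho_grid Numeric grids; defaults span `[-1, 1]` in 0.1 steps
#'   and `(0, 1]` in 0.05 steps.
#' @param k Window size for the generalized model (integer or `Inf`).
#' @return A tibble of class `signal_surface` with columns `model`,
#'   `correlation`, `density`, `value`.
#' @export
signal_surface <- function(model = c("correlation", "matching", "generalized"),
                           c_grid = seq(-1, 1, by = 0.1),
                           rho_grid = seq(0.05, 1, by = 0.05),
                           k = NULL) {
  model <- match.arg(model)
  grid <- tidyr::expand_grid(correlation = c_grid, density = rho_grid)
  value <- switch(model,
    correlation = signal_strength_correlation(grid$correlation, grid$density),
    matching = signal_strength_matching(grid$correlation, grid$density),
    generalized = {
      if (is.null(k)) abort("the generalized model needs a window size k")
      signal_strength_generalized(grid$correlation, grid$density, k)
    })
  out <- mutate(grid, model = if (model == "generalized")
    sprintf("generalized(k=%s)", format(k)) else model,
    value = value)[, c("model", "correlation", "density", "value")]
  class(out) <- c("signal_surface", class(out))
  out
}

#' Monte-Carlo variability surface of the differential disparity signal
#'
#' For each grid cell, simulates dynamic RDS frames (central square of
#' `center_size` px within `surround_size` px, stimulus disparity `d_s`),
#' computes the near-minus-far differential signal of each frame — the
#' operator output of a detector window at `d_near` minus one at `d_far` —
#' takes the standard deviation over `n_patterns` frames, and averages it
#' over `n_runs` repetitions. Both the cross-correlation and cross-matching
#' operators are evaluated on the same frames.
#'
#' @inheritParams signal_surface
#' @param center_size,surround_size,stimulus_disparity RDS geometry; the
#'   detector windows have `k = center_size^2` pixels.
#' @param d_near,d_far Window disparities of the near and far detectors.
#' @param n_patterns Frames per run over which the SD is taken.
#' @param n_runs Runs whose SDs are averaged.
#' @param seed Optional integer seed.
#' @return A tibble of class `sd_surface` with columns `model`,
#'   `correlation`, `density`, `sd`.
#' @export
sd_surface <- function(c_grid = seq(-1, 1, by = 0.1),
                       rho_grid = seq(0.05, 1, by = 0.05),
                       center_size = 32L, surround_size = 34L,
                       stimulus_disparity = -2L,
                       d_near = -2L, d_far = 2L,
                       n_patterns = 1000L, n_runs = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(correlation = c_grid, density = rho_grid)
  res <- purrr::pmap(list(grid$correlation, grid$density), function(cc, rr) {
    sds <- matrix(NA_real_, n_runs, 2)
    for (run in seq_len(n_runs)) {
      out <- .frame_outputs_cpp(n_patterns, center_size, surround_size,
                                rr, cc, stimulus_disparity, d_near, d_far)
      sds[run, 1] <- sd(out[, 1] - out[, 2])  # cross-correlation
      sds[run, 2] <- sd(out[, 3] - out[, 4])  # cross-matching
    }
    colMeans(sds)
  })
  res <- do.call(rbind, res)
  out <- bind_rows(
    mutate(grid, model = "correlation", sd = res[, 1]),
    mutate(grid, model = "matching", sd = res[, 2]))
  out <- out[, c("model", "correlation", "density", "sd")]
  attr(out, "k") <- as.integer(center_size)^2
  attr(out, "n_patterns") <- as.integer(n_patterns)
  attr(out, "n_runs") <- as.integer(n_runs)
  class(out) <- c("sd_surface", class(out))
  out
}
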