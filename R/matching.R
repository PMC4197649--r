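#' Binocular match window
#'
#' A window is a set of left-image pixel coordinates together with a window
#' (receptive-field) disparity `d`. An operator applied through the window
#' pairs each left-eye pixel `(x, y)` with the right-eye pixel `(x - d, y)`.
#'
#' @param x,y Integer vectors of equal length: 1-based left-image pixel
#'   coordinates (`x` rightward, `y` downward).
#' @param d Window disparity in signed pixels (negative = crossed).
#' @return An object of class `match_window`.
#' @export
match_window <- function(x, y, d = 0L) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 1L) abort("a match window needs at least one pixel")
  structure(list(x = x, y = y, d = as.integer(d), k = length(x)),
            class = "match_window")
}

#' Detector window aligned with the central-square geometry
#'
#' Builds the square window a disparity detector uses: the full central
#' square, positioned with the same symmetric eye split as the stimulus, so
#' that the window at disparity `d` exactly overlays a central square whose
#' stimulus disparity is `d`.
#'
#' @param d Window disparity in signed pixels.
#' @param center_size,surround_size Geometry, as in [rds_spec()].
#' @return A [match_window()] with `k = center_size^2` pixels.
#' @export
detector_window <- function(d, center_size = 32L, surround_size = 34L) {
  base <- (surround_size - center_size) %/% 2L
  off <- split_offsets(d)
  slack <- surround_size - center_size
  if (base + off[["left"]] < 0L || base + off[["left"]] > slack ||
      base + off[["right"]] < 0L || base + off[["right"]] > slack)
    abort(sprintf("window disparity %d does not fit the %d/%d-px geometry",
                  as.integer(d), center_size, surround_size))
  xs <- base + off[["left"]] + seq_len(center_size)
  ys <- base + seq_len(center_size)
  match_window(rep(xs, each = center_size), rep(ys, times = center_size), d)
}

check_window <- function(pair, window) {
  if (!inherits(window, "match_window")) abort("window must be a match_window")
  h <- nrow(pair$left); w <- ncol(pair$left)
  xr <- window$x - window$d
  if (any(window$x < 1L) || any(window$x > w) || any(window$y < 1L) ||
      any(window$y > h) || any(xr < 1L) || any(xr > w))
    abort("window (or its disparity-shifted counterpart) falls outside the image")
  invisible(window)
}

window_products <- function(pair, window) {
  l <- pair$left[cbind(window$y, window$x)]
  r <- pair$right[cbind(window$y, window$x - window$d)]
  l * r
}

#' Frame-level binocular matching operators
#'
#' Single-frame outputs of the window-based stereo operators. All operators
#' average pixelwise products of left and right luminance contrasts over the
#' window's `k` pixels, pairing `I_L(x, y)` with `I_R(x - d, y)`:
#'
#' * `cross_correlation_frame()`: plain average of `I_L * I_R`, in `[-1, 1]`.
#' * `cross_matching_frame()`: average of the half-wave-rectified products
#'   `[I_L * I_R]^+`, i.e. the fraction of window pixels forming
#'   contrast-matched dotted combinations; in `[0, 1]`.
#' * `generalized_cross_matching_frame()`: rectification applied after the
#'   window average, `[C]^+`; the window size `k` is the extent of spatial
#'   averaging that precedes the threshold.
#' * `onoff_cross_matching_frame()`: ON/OFF-channel form
#'   `[I_L]^+ [I_R]^+ + [-I_L]^+ [-I_R]^+`, averaged; algebraically identical
#'   to `cross_matching_frame()` on ternary images.
#'
#' Expectation over frames is a separate step (see [tuning_curve()]), so the
#' same pure frame operators serve tuning curves, variability surfaces, and
#' psychophysical simulation.
#'
#' @param pair A `stereo_pair`.
#' @param window A [match_window()]. Windows whose disparity-shifted
#'   counterpart would exit the image raise an error rather than being
#'   clipped (clipping would silently change `k`).
#' @return A single numeric value.
#' @export
cross_correlation_frame <- function(pair, window) {
  check_window(pair, window)
  mean(window_products(pair, window))
}

#' @rdname cross_correlation_frame
#' @export
cross_matching_frame <- function(pair, window) {
  check_window(pair, window)
  mean(pmax(window_products(pair, window), 0L))
}

#' @rdname cross_correlation_frame
#' @export
generalized_cross_matching_frame <- function(pair, window) {
  max(cross_correlation_frame(pair, window), 0)
}

#' @rdname cross_correlation_frame
#' @export
onoff_cross_matching_frame <- function(pair, window) {
  check_window(pair, window)
  l <- pair$left[cbind(window$y, window$x)]
  r <- pair$right[cbind(window$y, window$x - window$d)]
  mean(pmax(l, 0L) * pmax(r, 0L) + pmax(-l, 0L) * pmax(-r, 0L))
}

frame_operators <- list(
  correlation = cross_correlation_frame,
  matching = cross_matching_frame,
  generalized = generalized_cross_matching_frame,
  onoff = onoff_cross_matching_frame)

#' Disparity tuning curve of a matching operator
#'
#' Averages a frame operator across the independent frames of a dynamic RDS,
#' at each of a set of window disparities. Windows are positioned with
#' [detector_window()] so the window at `d` overlays a central square of
#' stimulus disparity `d`.
#'
#' @param seq A [frame_sequence()].
#' @param operator One of `"correlation"`, `"matching"`, `"generalized"`,
#'   `"onoff"`.
#' @param disparities Integer vector of window disparities; all must fit the
#'   sequence's geometry.
#' @return A tibble of class `tuning_curve` with columns `disparity`,
#'   `value` (mean across frames), `se`, `n_frames`, and attributes
#'   `operator` and `spec`.
#' @export
#' @examples
#' seq <- frame_sequence(rds_spec(center_size = 8, surround_size = 16,
#'                                stimulus_disparity = 0), 50, seed = 1)
#' tuning_curve(seq, "matching", -3:3)
tuning_curve <- function(seq, operator = c("correlation", "matching",
                                           "generalized", "onoff"),
                         disparities = -4:4) {
  if (!inherits(seq, "frame_sequence")) abort("seq must be a frame_sequence")
  operator <- match.arg(operator)
  f <- frame_operators[[operator]]
  spec <- seq$spec
  windows <- lapply(disparities, detector_window,
                    center_size = spec$center_size,
                    surround_size = spec$surround_size)
  if (!is.null(seq$seed)) set.seed(seq$seed)
  spec$seed <- NULL  # frames must be mutually independent
  vals <- matrix(NA_real_, seq$n_frames, length(disparities))
  for (fr in seq_len(seq$n_frames)) {
    pair <- generate_rds(spec)
    vals[fr, ] <- vapply(windows, function(w) f(pair, w), numeric(1))
  }
  out <- tibble(disparity = as.integer(disparities),
                value = colMeans(vals),
                se = apply(vals, 2, sd) / sqrt(seq$n_frames),
                n_frames = seq$n_frames)
  attr(out, "operator") <- operator
  attr(out, "spec") <- spec
  class(out) <- c("tuning_curve", class(out))
  out
}
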