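#' Specify a random-dot stereogram
#'
#' An RDS consists of a central square carrying a disparity plane, embedded in
#' a zero-disparity, perfectly correlated surround of the same dot density.
#' Pixels take ternary luminance-contrast values: +1 (bright dot), -1 (dark
#' dot), 0 (background). Within the central square each pixel independently
#' carries a dot with probability `dot_density`; a dotted pixel is
#' contrast-matched between the eyes with probability `(1 + c) / 2` and
#' contrast-reversed otherwise, so the expected binocular correlation of the
#' dots is exactly `binocular_correlation`.
#'
#' Disparity convention: sampling the right eye at `x - d` against the left
#' eye at `x` aligns the two copies of a patch whose disparity is `d`.
#' Negative disparities are crossed (near), positive uncrossed (far).
#' Both stimulus and window disparities are split symmetrically between the
#' eyes (left x-offset `floor(d/2)`, right `floor(d/2) - d`), which lets a
#' 32-px square take +/-2 px of disparity inside a 34-px surround.
#'
#' @param center_size Side of the central square, pixels.
#' @param surround_size Side of the full image, pixels; must leave room for
#'   the disparity-shifted square.
#' @param dot_density Probability that a pixel carries a dot, in `[0, 1]`.
#' @param binocular_correlation Expected contrast correlation `c` of the
#'   central dots, in `[-1, 1]`: +1 correlated, -1 anticorrelated, 0
#'   half-matched.
#' @param stimulus_disparity Signed disparity of the central square in pixels
#'   (negative = crossed).
#' @param dot_size Dot side in pixels. 1 gives per-pixel dots; larger values
#'   are used by [generate_dot_rds()].
#' @param seed Optional integer; when set, [generate_rds()] seeds the RNG
#'   before drawing so the pair is reproducible from the spec alone.
#' @return An object of class `rds_spec`.
#' @seealso [generate_rds()], [frame_sequence()]
#' @export
#' @examples
#' spec <- rds_spec(dot_density = 0.25, binocular_correlation = 1)
#' pair <- generate_rds(spec)
#' table(pair$left)
rds_spec <- function(center_size = 32L, surround_size = 34L,
                     dot_density = 0.25, binocular_correlation = 1,
                     stimulus_disparity = -2L, dot_size = 1L, seed = NULL) {
  spec <- structure(
    list(center_size = as.integer(center_size),
         surround_size = as.integer(surround_size),
         dot_density = as.numeric(dot_density),
         binocular_correlation = as.numeric(binocular_correlation),
         stimulus_disparity = as.integer(stimulus_disparity),
         dot_size = as.integer(dot_size),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "rds_spec")
  validate_rds_spec(spec)
  spec
}

validate_rds_spec <- function(spec) {
  if (spec$center_size < 1L || spec$surround_size < 1L)
    abort("image dimensions must be positive integers")
  if (spec$surround_size < spec$center_size)
    abort("invariant violated: surround_size >= center_size")
  if (spec$dot_density < 0 || spec$dot_density > 1)
    abort("invariant violated: dot_density must lie in [0, 1]")
  if (abs(spec$binocular_correlation) > 1)
    abort("invariant violated: binocular_correlation must lie in [-1, 1]")
  if (abs(spec$stimulus_disparity) > spec$surround_size - spec$center_size)
    abort("invariant violated: |stimulus_disparity| must not exceed surround_size - center_size")
  off <- split_offsets(spec$stimulus_disparity)
  base <- (spec$surround_size - spec$center_size) %/% 2L
  slack <- spec$surround_size - spec$center_size
  if (any(base + off < 0L) || any(base + off > slack))
    abort("invariant violated: disparity-shifted square must fit in the surround")
  invisible(spec)
}

# Symmetric eye split of a disparity: left x-offset, right x-offset
# (right content is displaced by -d relative to the left).
split_offsets <- function(d) {
  h_l <- as.integer(floor(d / 2))
  c(left = h_l, right = h_l - as.integer(d))
}

#' Generate one random-dot stereogram
#'
#' Draws a fresh dot pattern from an [rds_spec()]. Uses R's global RNG (so
#' `set.seed()` makes runs reproducible); if the spec carries a `seed`, the
#' RNG is seeded from it first.
#'
#' @param spec An [rds_spec()].
#' @return A `stereo_pair`: list with integer matrices `left` and `right`
#'   (values in `{-1, 0, +1}`, rows = y, columns = x), the generating `spec`,
#'   and the 1-based x/y offsets of the central square in each eye.
#' @export
generate_rds <- function(spec) {
  validate_rds_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  raw <- .gen_rds_cpp(spec$center_size, spec$surround_size, spec$dot_density,
                      spec$binocular_correlation, spec$stimulus_disparity)
  new_stereo_pair(raw$left, raw$right, spec,
                  x_offset_left = raw$x_offset_left,
                  x_offset_right = raw$x_offset_right,
                  y_offset = raw$y_offset)
}

new_stereo_pair <- function(left, right, spec = NULL, ...) {
  stopifnot(all(dim(left) == dim(right)))
  structure(list(left = left, right = right, spec = spec, ...),
            class = "stereo_pair")
}

#' Construct a stereo pair from two contrast images
#'
#' @param left,right Integer matrices with values in `{-1, 0, +1}` and equal
#'   dimensions.
#' @return A `stereo_pair`.
#' @export
stereo_pair <- function(left, right) {
  left <- as.matrix(left); right <- as.matrix(right)
  storage.mode(left) <- "integer"; storage.mode(right) <- "integer"
  if (!all(dim(left) == dim(right)))
    abort("left and right images must have identical dimensions")
  if (!all(left %in% -1:1) || !all(right %in% -1:1))
    abort("contrast images must contain only values -1, 0, +1")
  new_stereo_pair(left, right)
}

#' @export
print.stereo_pair <- function(x, ...) {
  d <- dim(x$left)
  cat(sprintf("<stereo_pair> %d x %d px", d[2], d[1]))
  if (!is.null(x$spec))
    cat(sprintf("  (rho = %g, c = %g, d_s = %d px)", x$spec$dot_density,
                x$spec$binocular_correlation, x$spec$stimulus_disparity))
  cat("\n")
  invisible(x)
}

#' Specify a dot-based random-dot stereogram
#'
#' Stimulus used with the energy-model detectors: square dots of several
#' pixels are thrown at uniformly random positions on a flat (single-plane)
#' field, later dots overwriting earlier ones; the whole field carries the
#' stimulus disparity. Each dot is bright or dark with equal probability and
#' contrast-reversed in the right eye with probability `(1 - c) / 2`. The
#' number of dots is `round(density * image_area / dot_area)`, i.e. density
#' is the expected pixel coverage before overwrite. Dots may straddle the
#' image border and are cropped, as in a windowed view of a larger dot field.
#'
#' @param image_size Image side, pixels.
#' @param dot_size Dot side, pixels; must not exceed `image_size`.
#' @param dot_density Expected fraction of pixels covered, in `[0, 1]`.
#' @param binocular_correlation Dot-contrast correlation `c` in `[-1, 1]`.
#' @param stimulus_disparity Whole-field disparity in signed pixels, split
#'   between the eyes as in [rds_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `dot_rds_spec`.
#' @export
dot_rds_spec <- function(image_size = 24L, dot_size = 8L, dot_density = 0.25,
                         binocular_correlation = 1, stimulus_disparity = -8L,
                         seed = NULL) {
  spec <- structure(
    list(image_size = as.integer(image_size), dot_size = as.integer(dot_size),
         dot_density = as.numeric(dot_density),
         binocular_correlation = as.numeric(binocular_correlation),
         stimulus_disparity = as.integer(stimulus_disparity),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "dot_rds_spec")
  if (spec$dot_size > spec$image_size)
    abort("invariant violated: dot_size must not exceed image_size")
  if (spec$dot_size < 1L) abort("dot_size must be a positive integer")
  if (spec$dot_density < 0 || spec$dot_density > 1)
    abort("invariant violated: dot_density must lie in [0, 1]")
  if (abs(spec$binocular_correlation) > 1)
    abort("invariant violated: binocular_correlation must lie in [-1, 1]")
  spec
}

#' Generate one dot-based RDS
#'
#' @param spec A [dot_rds_spec()].
#' @param n_dots Optional dot-count override (e.g. `1` to force a single
#'   dot); defaults to `round(density * image_area / dot_area)`.
#' @return A `stereo_pair` of `image_size` x `image_size` contrast images.
#' @export
generate_dot_rds <- function(spec, n_dots = NULL) {
  if (!inherits(spec, "dot_rds_spec")) abort("spec must be a dot_rds_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  b <- gen_dot_frames(1L, spec, n_dots = n_dots)
  new_stereo_pair(matrix(b$left[, 1], spec$image_size, spec$image_size),
                  matrix(b$right[, 1], spec$image_size, spec$image_size),
                  spec)
}

# Batched dot-RDS generation: returns integer matrices (image_size^2 x n),
# one frame per column, column-major pixels (row = y, col = x).
gen_dot_frames <- function(n, spec, n_dots = NULL) {
  sz <- spec$image_size; ds <- spec$dot_size
  n_dots <- n_dots %||% max(0L, as.integer(round(
    spec$dot_density * sz^2 / ds^2)))
  off <- split_offsets(spec$stimulus_disparity)
  left <- matrix(0L, sz * sz, n)
  right <- matrix(0L, sz * sz, n)
  if (n_dots == 0L) return(list(left = left, right = right))
  frame_base <- (seq_len(n) - 1L) * sz * sz
  # Paint one dot per frame (vectorized over frames) into an eye's stack;
  # out-of-bounds pixels are cropped. Later dots overwrite earlier ones.
  paint <- function(img, x0, y0, val) {
    for (dx in 0:(ds - 1L)) {
      x <- x0 + dx
      okx <- x >= 1L & x <= sz
      if (!any(okx)) next
      for (dy in 0:(ds - 1L)) {
        y <- y0 + dy
        ok <- okx & y >= 1L & y <= sz
        if (!any(ok)) next
        img[frame_base[ok] + (x[ok] - 1L) * sz + y[ok]] <- val[ok]
      }
    }
    img
  }
  # Per dot and frame: top-left corner uniform over positions with any
  # overlap (before the eye shift), contrast sign, reversal flag.
  # Draw order: for each dot, x0, y0, sign, reversal across frames.
  for (t in seq_len(n_dots)) {
    x0 <- as.integer(floor(runif(n, 1 - ds, sz + 1)))  # 1-based, may be < 1
    y0 <- as.integer(floor(runif(n, 1 - ds, sz + 1)))
    s <- ifelse(runif(n) < 0.5, 1L, -1L)
    m <- ifelse(runif(n) < (1 + spec$binocular_correlation) / 2, 1L, -1L)
    left <- paint(left, x0 + off[["left"]], y0, s)
    right <- paint(right, x0 + off[["right"]], y0, s * m)
  }
  list(left = left, right = right)
}

#' A sequence of independent RDS frames
#'
#' Dynamic RDSs refresh the dot pattern over time while the disparity
#' structure stays fixed; operators are averaged across frames. This record
#' just binds a spec to a frame count and an optional seed; frames are drawn
#' lazily by consumers such as [tuning_curve()].
#'
#' @param spec An [rds_spec()].
#' @param n_frames Number of independent frames.
#' @param seed Optional integer seed applied before the first frame.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(spec, n_frames, seed = NULL) {
  validate_rds_spec(spec)
  if (n_frames < 1) abort("n_frames must be >= 1")
  structure(list(spec = spec, n_frames = as.integer(n_frames),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "frame_sequence")
}

#' Empirical dot statistics of a stereo pair
#'
#' Test instrumentation: at a given window disparity, counts the window
#' pixels that form dotted binocular combinations (both eyes dotted) and,
#' among those, the fraction that are contrast-matched.
#'
#' @param pair A `stereo_pair`.
#' @param window A [match_window()]; its disparity `d` determines the
#'   right-eye sampling offset.
#' @return A tibble with columns `n_pixels`, `dotted_fraction`,
#'   `match_fraction` (`NA` when no dotted combination exists).
#' @export
measure_pair_statistics <- function(pair, window) {
  check_window(pair, window)
  l <- pair$left[cbind(window$y, window$x)]
  r <- pair$right[cbind(window$y, window$x - window$d)]
  dotted <- l != 0L & r != 0L
  tibble(n_pixels = length(l),
         dotted_fraction = mean(dotted),
         match_fraction = if (any(dotted)) mean(l[dotted] == r[dotted]) else NA_real_)
}
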