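#' Gabor receptive-field parameters
#'
#' Parameters of the model simple cells' receptive fields: two-dimensional
#' Gabors with an isotropic Gaussian envelope and a vertically oriented
#' carrier (luminance modulated along x). Defaults follow the small-field
#' configuration used with 24 x 24-px dot RDSs: envelope SD 0.05 deg, pixel
#' pitch 0.0175 deg/px, position disparity +/-0.14 deg (8 px).
#'
#' The carrier frequency is a free configuration parameter; the default puts
#' about one carrier cycle per 2 envelope SDs (10 cycles/deg at SD 0.05 deg),
#' a stereo-plausible band-pass choice. `amplitude` is an overall output
#' gain; it only scales detector responses, and the default places those
#' responses on the order of the decision noise used by
#' [psychometric_curve()] for energy detectors (sigma = 1000).
#'
#' @param sigma Envelope SD, degrees (same in x and y).
#' @param carrier_freq Carrier spatial frequency, cycles/degree.
#' @param pixel_pitch Degrees per pixel.
#' @param field_size Receptive-field (and stimulus) side, pixels.
#' @param amplitude Peak amplitude of the phase-0 Gabor.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(sigma = 0.05, carrier_freq = 10,
                         pixel_pitch = 0.0175, field_size = 24L,
                         amplitude = 14) {
  if (sigma <= 0 || pixel_pitch <= 0 || field_size < 1)
    abort("field size, pixel pitch and envelope SD must be positive")
  structure(list(sigma = sigma, carrier_freq = carrier_freq,
                 pixel_pitch = pixel_pitch,
                 field_size = as.integer(field_size),
                 amplitude = amplitude),
            class = "gabor_params")
}

#' Sample a Gabor receptive field on the pixel grid
#'
#' @param params A [gabor_params()].
#' @param phase Carrier phase in radians: 0 (even-symmetric) or `pi/2`
#'   (odd-symmetric) for the two subunits of an energy unit.
#' @param center_offset_px Horizontal offset of the Gabor center from the
#'   field center, pixels (half the unit's position disparity, opposite
#'   signs in the two eyes).
#' @return A `field_size` x `field_size` numeric matrix (rows = y,
#'   columns = x).
#' @export
make_receptive_field <- function(params, phase = 0, center_offset_px = 0) {
  sz <- params$field_size
  sigma_px <- params$sigma / params$pixel_pitch
  freq_px <- params$carrier_freq * params$pixel_pitch  # cycles per pixel
  cx <- (sz + 1) / 2 + center_offset_px
  cy <- (sz + 1) / 2
  if (abs(center_offset_px) > sz / 2 - 2 * sigma_px)
    warn("position disparity shifts the Gabor envelope close to the field edge")
  x <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - cx
  y <- matrix(seq_len(sz), sz, sz) - cy
  params$amplitude * exp(-(x^2 + y^2) / (2 * sigma_px^2)) *
    cos(2 * pi * freq_px * x + phase)
}

#' Binocular energy unit
#'
#' A disparity-energy unit: two simple-cell subunits in phase quadrature
#' (carrier phases 0 and pi/2), each with a left-eye and a right-eye Gabor
#' receptive field that differ only by the unit's position disparity. The
#' disparity is split symmetrically: the left field is shifted by
#' `+disparity/2`, the right by `-disparity/2` (so that right-eye content
#' displaced by `-disparity` px, the stimulus convention, aligns with the
#' unit's preference).
#'
#' @param position_disparity Preferred disparity, degrees (negative = near).
#' @param params A [gabor_params()].
#' @return An object of class `energy_unit` holding the four receptive
#'   fields.
#' @export
energy_unit <- function(position_disparity = -0.14, params = gabor_params()) {
  d_px <- position_disparity / params$pixel_pitch
  structure(list(
    left_even = make_receptive_field(params, 0, d_px / 2),
    left_odd = make_receptive_field(params, pi / 2, d_px / 2),
    right_even = make_receptive_field(params, 0, -d_px / 2),
    right_odd = make_receptive_field(params, pi / 2, -d_px / 2),
    position_disparity = position_disparity, params = params),
    class = "energy_unit")
}

check_energy_input <- function(pair, unit) {
  sz <- unit$params$field_size
  if (!all(dim(pair$left) == c(sz, sz)))
    abort(sprintf("stimulus must match the receptive-field size (%d x %d px)",
                  sz, sz))
  invisible(NULL)
}

#' Responses of energy-model detectors
#'
#' * `energy_response()`: for each subunit, the monocular inner products are
#'   summed across the eyes and squared; subunit outputs are summed. Always
#'   nonnegative.
#' * `binocular_interaction()`: the binocular component of the energy
#'   response, i.e. the response minus the two monocular (one eye blank)
#'   responses; equals `2 * sum over subunits of <RF_L, I_L> <RF_R, I_R>`.
#' * `threshold_energy_response()`: the binocular interaction passed through
#'   half-wave rectification (zero threshold).
#'
#' @param pair A `stereo_pair` whose images match the unit's field size.
#' @param unit An [energy_unit()].
#' @return A single numeric value.
#' @export
energy_response <- function(pair, unit) {
  check_energy_input(pair, unit)
  (sum(unit$left_even * pair$left) + sum(unit$right_even * pair$right))^2 +
    (sum(unit$left_odd * pair$left) + sum(unit$right_odd * pair$right))^2
}

#' @rdname energy_response
#' @export
binocular_interaction <- function(pair, unit) {
  check_energy_input(pair, unit)
  2 * (sum(unit$left_even * pair$left) * sum(unit$right_even * pair$right) +
         sum(unit$left_odd * pair$left) * sum(unit$right_odd * pair$right))
}

#' @rdname energy_response
#' @export
threshold_energy_response <- function(pair, unit) {
  max(binocular_interaction(pair, unit), 0)
}

# Batched detector outputs for an energy-model pair of opponent detectors.
# Returns an n_frames x 2 matrix (near, far) of per-frame responses of the
# chosen model to dot RDSs drawn from `spec`.
energy_detector_outputs <- function(n_frames, spec, near, far,
                                    model = c("threshold_energy", "energy")) {
  model <- match.arg(model)
  b <- gen_dot_frames(n_frames, spec)
  rf_l <- cbind(c(near$left_even), c(near$left_odd),
                c(far$left_even), c(far$left_odd))
  rf_r <- cbind(c(near$right_even), c(near$right_odd),
                c(far$right_even), c(far$right_odd))
  vl <- crossprod(rf_l, b$left)   # 4 x n
  vr <- crossprod(rf_r, b$right)
  if (model == "energy") {
    resp <- (vl + vr)^2
    cbind(near = resp[1, ] + resp[2, ], far = resp[3, ] + resp[4, ])
  } else {
    inter <- 2 * vl * vr
    cbind(near = pmax(inter[1, ] + inter[2, ], 0),
          far = pmax(inter[3, ] + inter[4, ], 0))
  }
}
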