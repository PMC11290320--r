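#' Retinotopic map container
#'
#' @param position_deg per-pixel visual-field coordinate in degrees, in
#'   `[0, span_deg]`.
#' @param axis `"azimuth"` or `"elevation"`.
#' @param span_deg visual-field span (110 for azimuth, 60 for elevation).
#' @param magnitude per-pixel response magnitude.
#' @param delay_estimate_s estimated hemodynamic delay (s).
#' @param valid_mask logical matrix.
#' @return an object of class `retinotopic_map`.
#' @export
retinotopic_map <- function(position_deg, axis, span_deg, magnitude = NULL,
                            delay_estimate_s = NA_real_, valid_mask = NULL) {
  stopifnot(is.matrix(position_deg), axis %in% c("azimuth", "elevation"),
            span_deg > 0)
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(position_deg))
  if (is.null(magnitude)) magnitude <- array(1, dim(position_deg))
  v <- position_deg[valid_mask]
  if (any(v < 0 | v > span_deg))
    stop("positions outside [0, span]")
  structure(list(position_deg = position_deg, axis = axis,
                 span_deg = span_deg, magnitude = magnitude,
                 delay_estimate_s = delay_estimate_s,
                 valid_mask = valid_mask),
            class = "retinotopic_map")
}

#' Orientation preference map container
#'
#' @param orientation_deg per-pixel preferred orientation in `[0, 180)`.
#' @param magnitude per-pixel response magnitude.
#' @param delay_estimate_s estimated hemodynamic delay (s).
#' @param valid_mask logical matrix.
#' @return an object of class `orientation_map`.
#' @export
orientation_map <- function(orientation_deg, magnitude = NULL,
                            delay_estimate_s = NA_real_, valid_mask = NULL) {
  stopifnot(is.matrix(orientation_deg))
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(orientation_deg))
  if (is.null(magnitude)) magnitude <- array(1, dim(orientation_deg))
  v <- orientation_deg[valid_mask]
  if (any(v < 0 | v >= 180)) stop("orientations outside [0, 180)")
  structure(list(orientation_deg = orientation_deg, magnitude = magnitude,
                 delay_estimate_s = delay_estimate_s,
                 valid_mask = valid_mask),
            class = "orientation_map")
}

check_pair <- function(a, b) {
  if (!all(dim(a$phase) == dim(b$phase)))
    stop("phase maps have different geometry")
  if (abs(a$f_analysis_hz - b$f_analysis_hz) > 1e-12)
    stop("phase maps have different analysis frequencies")
}

#' Retinotopic map from a forward/reverse phase-map pair
#'
#' The stimulus-position phase and the hemodynamic delay phase are entangled
#' in each session: `Phi_fwd = phi_pos + phi_delay`,
#' `Phi_rev = -phi_pos + phi_delay` (mod 2*pi). Under the assumption that the
#' delay is below half the stimulation period, the per-pixel delay phase is
#' `((Phi_fwd + Phi_rev) mod 2*pi) / 2` and the position phase is the
#' delay-corrected forward phase, `(Phi_fwd - phi_delay) mod 2*pi`. This
#' equals half the difference of the two phase maps up to the wrap
#' convention, which the sum-based delay estimate resolves. Positions are
#' mapped linearly onto `[0, span]` degrees.
#'
#' @param fwd,rev [phase_map()]s of the two opposite sweep directions.
#' @param span_deg visual-field span in degrees (110 azimuth, 60 elevation).
#' @param axis map axis label.
#' @return a [retinotopic_map()]; `delay_estimate_s` is the median per-pixel
#'   delay phase divided by `2*pi*f`.
#' @export
retinotopy_from_pair <- function(fwd, rev, span_deg,
                                 axis = c("azimuth", "elevation")) {
  axis <- match.arg(axis)
  stopifnot(inherits(fwd, "phase_map"), inherits(rev, "phase_map"))
  check_pair(fwd, rev)
  f <- fwd$f_analysis_hz
  delay_phase <- wrap_period(fwd$phase + rev$phase) / 2
  position <- span_deg * wrap_period(fwd$phase - delay_phase) / (2 * pi)
  valid <- fwd$valid_mask & rev$valid_mask
  magnitude <- (fwd$magnitude + rev$magnitude) / 2
  retinotopic_map(position, axis, span_deg, magnitude,
                  delay_estimate_s =
                    stats::median(delay_phase[valid]) / (2 * pi * f),
                  valid_mask = valid)
}

#' Orientation map from an anticlockwise/clockwise phase-map pair
#'
#' The rotation sessions encode the preferred orientation with opposite
#' signs, `Phi+ = phi_delay + 2*theta` and `Phi- = phi_delay - 2*theta`
#' (angle-doubled because orientation is 180-degree periodic). The shared
#' delay phase is estimated as the magnitude-weighted circular mean over
#' valid pixels of `((Phi+ + Phi-) mod 2*pi) / 2`, subtracted from both maps,
#' and the two delay-corrected orientation estimates are averaged on the
#' 180-degree circle. Pixels whose two estimates are antipodal on that circle
#' are flagged invalid.
#'
#' @param ccw,cw [phase_map()]s of the two rotation directions, demodulated
#'   at the orientation analysis frequency.
#' @return an [orientation_map()] with orientations in `[0, 180)` degrees.
#' @export
orientation_from_pair <- function(ccw, cw) {
  stopifnot(inherits(ccw, "phase_map"), inherits(cw, "phase_map"))
  check_pair(ccw, cw)
  f <- ccw$f_analysis_hz
  valid <- ccw$valid_mask & cw$valid_mask
  magnitude <- (ccw$magnitude + cw$magnitude) / 2

  per_px_delay <- wrap_period(ccw$phase + cw$phase) / 2   # in [0, pi)
  delay_phase <- circular_mean(per_px_delay[valid], magnitude[valid],
                               period = pi)
  a <- wrap_period(ccw$phase - delay_phase) / 2           # theta estimate 1
  b <- wrap_period(-(wrap_period(cw$phase - delay_phase) / 2), pi)
  z <- exp(2i * a) + exp(2i * b)                          # mean on 180 circle
  degenerate <- Mod(z) < 1e-9
  ori <- wrap_period(Arg(z)) / 2 * 180 / pi
  ori[degenerate] <- 0
  valid <- valid & !degenerate
  orientation_map(ori, magnitude,
                  delay_estimate_s = delay_phase / (2 * pi * f),
                  valid_mask = valid)
}
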