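#' Ground truth for synthetic intrinsic-imaging sessions
#'
#' Bundles the planted quantities a synthetic movie encodes: the per-pixel
#' visual-field coordinate (for retinotopy) or preferred orientation (for
#' orientation maps), the hemodynamic delay, the per-pixel response
#' magnitude, and the nuisance levels (additive Gaussian noise and slow
#' drift). Recovery tests compare pipeline output against these fields.
#'
#' @param position_map_deg matrix of visual-field coordinates in degrees, or
#'   `NULL` for orientation-only truths.
#' @param orientation_map_deg matrix of preferred orientations in
#'   `[0, 180)` degrees, or `NULL`.
#' @param delay_s hemodynamic delay in seconds (>= 0).
#' @param magnitude_map per-pixel response amplitude; a scalar is recycled.
#' @param noise_sd standard deviation of the additive Gaussian noise. The
#'   default 0.3 (for unit response magnitude) is a mid-quality recording;
#'   see also [noise_sd_for_snr()].
#' @param drift_amp amplitude of the slow drift (linear trend plus a
#'   0.005 Hz sinusoid); default 1, i.e. drift as large as the signal.
#' @param seed RNG seed; the same truth passed to a generator twice produces
#'   bit-identical movies.
#' @return an object of class `imaging_truth`.
#' @export
imaging_truth <- function(position_map_deg = NULL, orientation_map_deg = NULL,
                          delay_s = 1.5, magnitude_map = 1, noise_sd = 0.3,
                          drift_amp = 1, seed = 1L) {
  stopifnot(delay_s >= 0, noise_sd >= 0, drift_amp >= 0)
  dims <- dim(if (!is.null(position_map_deg)) position_map_deg
              else orientation_map_deg)
  if (is.null(dims)) stop("need a position or orientation map")
  if (!is.null(orientation_map_deg) &&
      (any(orientation_map_deg < 0) || any(orientation_map_deg >= 180)))
    stop("orientations must lie in [0, 180)")
  if (length(magnitude_map) == 1)
    magnitude_map <- matrix(magnitude_map, dims[1], dims[2])
  stopifnot(all(magnitude_map >= 0), all(dim(magnitude_map) == dims))
  structure(list(position_map_deg = position_map_deg,
                 orientation_map_deg = orientation_map_deg,
                 delay_s = delay_s, magnitude_map = magnitude_map,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 seed = as.integer(seed)),
            class = "imaging_truth")
}

#' Noise level for a target stimulus-locked amplitude SNR
#'
#' SNR here is the time-domain amplitude ratio between the stimulus-locked
#' sinusoidal component and the additive noise: `noise_sd = magnitude / snr`.
#'
#' @param magnitude response amplitude.
#' @param snr target amplitude signal-to-noise ratio.
#' @return noise standard deviation.
#' @export
noise_sd_for_snr <- function(magnitude, snr) {
  stopifnot(snr > 0)
  magnitude / snr
}

#' Default planted retinotopy: a linear visual-field gradient
#'
#' Positions run linearly from `span/(2*ncol)` to `span*(1 - 1/(2*ncol))`
#' across columns (azimuth) or rows (elevation), keeping pixel centers away
#' from the wrap-around at 0/span degrees.
#'
#' @param grid `c(height, width)` in pixels (default desk scale 64 x 64).
#' @param span_deg visual-field span in degrees.
#' @param axis `"azimuth"` (gradient along columns) or `"elevation"` (rows).
#' @return a position matrix in degrees.
#' @export
gradient_position_map <- function(grid = c(64, 64), span_deg = 110,
                                  axis = c("azimuth", "elevation")) {
  axis <- match.arg(axis)
  h <- grid[1]; w <- grid[2]
  if (axis == "azimuth") {
    pos <- matrix(rep(span_deg * (seq_len(w) - 0.5) / w, each = h), h, w)
  } else {
    pos <- matrix(rep(span_deg * (seq_len(h) - 0.5) / h, times = w), h, w)
  }
  pos
}

#' Default planted orientation map: cardinal patches
#'
#' Blocks of preferred orientation cycling through 0, 45, 90 and 135 degrees,
#' mimicking the patchy orientation representation of the superior colliculus
#' (dominated by cardinal contours at coarse scale).
#'
#' @param grid `c(height, width)` in pixels.
#' @param patch_px patch side length in pixels.
#' @return an orientation matrix in `[0, 180)` degrees.
#' @export
patch_orientation_map <- function(grid = c(64, 64), patch_px = 16) {
  h <- grid[1]; w <- grid[2]
  br <- (ceiling(row(matrix(0, h, w)) / patch_px) +
         ceiling(col(matrix(0, h, w)) / patch_px)) %% 4
  matrix(c(0, 45, 90, 135)[br + 1], h, w)
}

# slow drift: linear trend plus a 0.005 Hz sinusoid, shared by all pixels
drift_trace <- function(t, amp) {
  if (amp == 0) return(numeric(length(t)))
  amp * (2 * (t - mean(t)) / max(t[length(t)], 1) +
         sin(2 * pi * 0.005 * t))
}

# steady-state response of a gamma kernel (shape 4, scale 0.6 s) at f:
# complex gain applied to the stimulus-locked sinusoid
gamma_kernel_gain <- function(f, shape = 4, scale = 0.6) {
  # Fourier transform of the (unit-mass) gamma density
  (1 + 2i * pi * f * scale)^(-shape)
}

# assemble n x P signal matrix M*cos(2*pi*f*t - Phi) + drift + noise
periodic_movie <- function(phase, magnitude, f, t, drift_amp, noise_sd,
                           frame_rate, protocol) {
  wt <- 2 * pi * f * t
  x <- tcrossprod(cos(wt), as.vector(magnitude * cos(phase))) +
       tcrossprod(sin(wt), as.vector(magnitude * sin(phase)))
  x <- x + drift_trace(t, drift_amp)
  if (noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
  dim(x) <- c(length(t), dim(phase))
  oi_movie(x, frame_rate, protocol)
}

#' Generate a forward/reverse pair of synthetic retinotopy sessions
#'
#' Each pixel responds at the sweep frequency with phase
#' `2*pi*position/span + 2*pi*f_stim*delay` in the forward session; the
#' position-dependent part of the phase is negated in the reverse session
#' while the delay part is shared. Slow drift and Gaussian noise are added on
#' top. Optionally the response is passed through a hemodynamic gamma kernel
#' (shape 4, scale 0.6 s), which scales the amplitude and adds the kernel
#' phase at the stimulation frequency; the phase-level model is the default
#' since the analysis only measures the single-frequency component.
#'
#' @param truth an [imaging_truth()] with a `position_map_deg`.
#' @param protocol a [stim_protocol()] whose `direction` is one of the four
#'   sweep directions; the span is chosen accordingly (azimuth 110, elevation
#'   60 by default).
#' @param gamma_kernel logical; apply the gamma hemodynamic kernel
#'   (default `FALSE`).
#' @return list with `forward` and `reverse` [oi_movie()]s and the `truth`.
#' @export
make_retinotopy_sessions <- function(truth, protocol = stim_protocol(),
                                     gamma_kernel = FALSE) {
  stopifnot(inherits(truth, "imaging_truth"),
            inherits(protocol, "stim_protocol"))
  if (is.null(truth$position_map_deg)) stop("truth has no position map")
  if (protocol$direction %in% c("ccw", "cw"))
    stop("protocol direction is a rotation; use make_orientation_sessions()")
  axis <- if (protocol$direction %in% c("rightward", "leftward"))
    "azimuth" else "elevation"
  span <- if (axis == "azimuth") protocol$span_azimuth_deg
          else protocol$span_elevation_deg
  pos <- truth$position_map_deg
  if (any(pos < 0) || any(pos > span))
    stop(sprintf("positions must lie in [0, %g] degrees", span))
  f <- protocol$f_stim_hz
  if (truth$delay_s >= 1 / (2 * f))
    stop("delay must be below half the stimulation period")
  fr <- protocol$frame_rate_hz
  dur <- protocol_duration_s(protocol, "sweep")
  n <- dur * fr
  if (abs(n - round(n)) > 1e-9)
    stop("protocol duration is not an integer number of frames")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1) / fr

  phi_pos <- 2 * pi * pos / span
  phi_del <- 2 * pi * f * truth$delay_s
  mag <- truth$magnitude_map
  if (gamma_kernel) {
    g <- gamma_kernel_gain(f)
    mag <- mag * Mod(g)
    phi_del <- phi_del - Arg(g)   # kernel lag adds to the apparent delay
  }
  set.seed(truth$seed)
  fwd <- periodic_movie(wrap_period(phi_pos + phi_del), mag, f, t,
                        truth$drift_amp, truth$noise_sd, fr, protocol)
  rev_prot <- protocol
  rev_prot$direction <- c(rightward = "leftward", leftward = "rightward",
                          downward = "upward", upward = "downward")[
                            protocol$direction]
  rev <- periodic_movie(wrap_period(-phi_pos + phi_del), mag, f, t,
                        truth$drift_amp, truth$noise_sd, fr, rev_prot)
  list(forward = fwd, reverse = rev, truth = truth)
}

#' Generate a ccw/cw pair of synthetic orientation sessions
#'
#' Each pixel responds at the orientation analysis frequency (1/15 Hz for a
#' 2 rpm rotation) with phase `2*pi*f*delay + 2*theta` in the anticlockwise
#' session and `2*pi*f*delay - 2*theta` in the clockwise session, where
#' `theta` is the preferred orientation in radians of the 180-degree cycle.
#'
#' @inheritParams make_retinotopy_sessions
#' @param truth an [imaging_truth()] with an `orientation_map_deg`.
#' @return list with `ccw` and `cw` [oi_movie()]s and the `truth`.
#' @export
make_orientation_sessions <- function(truth, protocol = stim_protocol(),
                                      gamma_kernel = FALSE) {
  stopifnot(inherits(truth, "imaging_truth"),
            inherits(protocol, "stim_protocol"))
  if (is.null(truth$orientation_map_deg)) stop("truth has no orientation map")
  f <- protocol$f_analysis_hz
  if (truth$delay_s >= 1 / (2 * f))
    stop("delay must be below half the analysis period")
  fr <- protocol$frame_rate_hz
  dur <- protocol_duration_s(protocol, "rotation")
  n <- dur * fr
  if (abs(n - round(n)) > 1e-9)
    stop("protocol duration is not an integer number of frames")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1) / fr

  theta2 <- 2 * truth$orientation_map_deg * pi / 180
  phi_del <- 2 * pi * f * truth$delay_s
  mag <- truth$magnitude_map
  if (gamma_kernel) {
    g <- gamma_kernel_gain(f)
    mag <- mag * Mod(g)
    phi_del <- phi_del - Arg(g)
  }
  set.seed(truth$seed)
  prot_ccw <- protocol; prot_ccw$direction <- "ccw"
  ccw <- periodic_movie(wrap_period(phi_del + theta2), mag, f, t,
                        truth$drift_amp, truth$noise_sd, fr, prot_ccw)
  prot_cw <- protocol; prot_cw$direction <- "cw"
  cw <- periodic_movie(wrap_period(phi_del - theta2), mag, f, t,
                       truth$drift_amp, truth$noise_sd, fr, prot_cw)
  list(ccw = ccw, cw = cw, truth = truth)
}
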