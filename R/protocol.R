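#' Stimulus protocol for periodic intrinsic-imaging sessions
#'
#' Describes the continuous periodic stimulation used to drive either a
#' retinotopy session (a bar sweeping across the screen at `f_stim_hz`) or an
#' orientation session (a drifting grating rotating at `f_rot_rpm`). The
#' monitor covers 110 degrees of azimuth and 60 degrees of elevation.
#'
#' For a sweep session the movie duration is `n_repeats / f_stim_hz` seconds;
#' for a rotation session it is `n_cycles * 60 / f_rot_rpm` seconds.
#'
#' @param frame_rate_hz camera sampling rate in Hz. The acquisition rate of
#'   the CCD camera is not part of the stimulation protocol, so it is a free
#'   parameter; the desk-scale default is 5 Hz.
#' @param f_stim_hz sweep repetition frequency in Hz (default 1/8).
#' @param f_rot_rpm grating rotation speed in rotations per minute (default 2).
#' @param f_analysis_hz analysis frequency for orientation sessions in Hz
#'   (default 1/15; see [orientation_analysis_frequency()]).
#' @param n_repeats number of bar sweeps per retinotopy session (default 30).
#' @param n_cycles number of grating rotations per orientation session
#'   (default 20).
#' @param span_azimuth_deg,span_elevation_deg visual-field extent of the
#'   screen in degrees (defaults 110 and 60).
#' @param direction stimulus direction, one of `"rightward"`, `"leftward"`,
#'   `"downward"`, `"upward"`, `"ccw"`, `"cw"`.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(frame_rate_hz = 5,
                          f_stim_hz = 1 / 8,
                          f_rot_rpm = 2,
                          f_analysis_hz = 1 / 15,
                          n_repeats = 30,
                          n_cycles = 20,
                          span_azimuth_deg = 110,
                          span_elevation_deg = 60,
                          direction = c("rightward", "leftward", "downward",
                                        "upward", "ccw", "cw")) {
  direction <- match.arg(direction)
  stopifnot(frame_rate_hz > 0, f_stim_hz > 0, f_rot_rpm > 0,
            f_analysis_hz > 0, n_repeats >= 1, n_cycles >= 1,
            span_azimuth_deg > 0, span_elevation_deg > 0)
  structure(
    list(frame_rate_hz = frame_rate_hz,
         f_stim_hz = f_stim_hz,
         f_rot_rpm = f_rot_rpm,
         f_analysis_hz = f_analysis_hz,
         n_repeats = n_repeats,
         n_cycles = n_cycles,
         span_azimuth_deg = span_azimuth_deg,
         span_elevation_deg = span_elevation_deg,
         direction = direction),
    class = "stim_protocol")
}

#' Session duration implied by a stimulus protocol
#'
#' @param protocol a [stim_protocol()].
#' @param kind `"sweep"` for retinotopy sessions, `"rotation"` for
#'   orientation sessions.
#' @return duration in seconds: `n_repeats / f_stim_hz` for sweeps,
#'   `n_cycles * 60 / f_rot_rpm` for rotations.
#' @export
protocol_duration_s <- function(protocol, kind = c("sweep", "rotation")) {
  kind <- match.arg(kind)
  if (kind == "sweep") protocol$n_repeats / protocol$f_stim_hz
  else protocol$n_cycles * 60 / protocol$f_rot_rpm
}

#' Orientation analysis frequency for a rotating grating
#'
#' A sine-wave grating is 180-degree periodic: after half a rotation the
#' stimulus orientation has cycled once. The orientation-locked response
#' therefore repeats twice per rotation, and the analysis frequency is twice
#' the rotation frequency. At 2 rpm (1/30 Hz) this gives 1/15 Hz.
#'
#' @param f_rot_rpm rotation speed in rotations per minute.
#' @return analysis frequency in Hz.
#' @export
orientation_analysis_frequency <- function(f_rot_rpm = 2) {
  stopifnot(f_rot_rpm > 0)
  2 * f_rot_rpm / 60
}

#' Default pipeline configuration
#'
#' Returns the full set of constants used by the pipeline stages: protocol
#' frequencies and spans, significance threshold, camera pixel pitch
#' (10.5 um/pixel), pose-tracking likelihood threshold and the
#' baseline/arrest averaging windows. Grating drift rate (1.5 Hz) and spatial
#' frequency (0.015 cpd) are recorded as stimulus metadata only; they do not
#' enter any computation.
#'
#' @param ... named overrides of top-level entries (partial lists are merged).
#' @return a nested list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    protocol = list(frame_rate_hz = 5, f_stim_hz = 1 / 8, f_rot_rpm = 2,
                    f_analysis_hz = 1 / 15, n_repeats = 30, n_cycles = 20,
                    span_azimuth_deg = 110, span_elevation_deg = 60,
                    grating_drift_hz = 1.5, grating_spatial_freq_cpd = 0.015),
    imaging = list(grid = c(64L, 64L), pixel_pitch_um = 10.5),
    stats = list(alpha = 0.05, n_mc = 100000L),
    coverage = list(cell_deg = 5),
    behavior = list(frame_rate_hz = 25, likelihood_threshold = 0.9,
                    smooth_window = 5L, sg_window = 7L, sg_order = 2L,
                    baseline_window_s = 1, arrest_delay_s = 1,
                    arrest_window_s = 3, min_baseline_cms = 2,
                    arena_diameter_cm = 30),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Entries missing from the file are filled with [default_config()] values.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

validate_config <- function(cfg) {
  p <- cfg$protocol
  stopifnot(p$f_stim_hz > 0, p$f_rot_rpm > 0, p$f_analysis_hz > 0,
            p$frame_rate_hz > 0, p$span_azimuth_deg > 0,
            p$span_elevation_deg > 0,
            cfg$stats$alpha > 0, cfg$stats$alpha < 1,
            cfg$imaging$pixel_pitch_um > 0,
            cfg$behavior$likelihood_threshold >= 0,
            cfg$behavior$likelihood_threshold <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# wrap x into [0, period)
wrap_period <- function(x, period = 2 * pi) {
  y <- x %% period
  # guard against period itself from floating-point of negative inputs
  y[y >= period] <- 0
  y
}
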