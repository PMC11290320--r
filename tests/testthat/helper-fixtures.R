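# shared fixtures: tiny protocols, the demodulation pipeline, circular error

# desk-scale protocol, optionally shortened for cheap tests
tiny_protocol <- function(direction = "rightward", n_repeats = 6,
                          n_cycles = 2, frame_rate_hz = 5) {
  stim_protocol(frame_rate_hz = frame_rate_hz, n_repeats = n_repeats,
                n_cycles = n_cycles, direction = direction)
}

# detrend + demodulate one movie at f
demod <- function(movie, f) {
  extract_fourier_component(remove_slow_components(movie, f), f)
}

# run a session pair through the full retinotopy pipeline
recover_retinotopy <- function(sessions, protocol) {
  span <- if (protocol$direction %in% c("rightward", "leftward"))
    protocol$span_azimuth_deg else protocol$span_elevation_deg
  axis <- if (protocol$direction %in% c("rightward", "leftward"))
    "azimuth" else "elevation"
  retinotopy_from_pair(demod(sessions$forward, protocol$f_stim_hz),
                       demod(sessions$reverse, protocol$f_stim_hz),
                       span, axis)
}

recover_orientation <- function(sessions, protocol) {
  orientation_from_pair(demod(sessions$ccw, protocol$f_analysis_hz),
                        demod(sessions$cw, protocol$f_analysis_hz))
}

# absolute error on a circle of the given period
circ_err <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# single-pixel movie from a raw trace
trace_movie <- function(x, frame_rate_hz = 5, protocol = NULL) {
  oi_movie(array(x, c(length(x), 1, 1)), frame_rate_hz, protocol)
}

# demodulate a raw single-pixel trace (no detrending)
demod_raw <- function(x, frame_rate_hz = 5, f = 1 / 8) {
  extract_fourier_component(trace_movie(x, frame_rate_hz), f)
}

# a simple retinotopic map pair on a shared grid, unit magnitude
toy_map_pair <- function(h = 48, w = 48) {
  list(azimuth = retinotopic_map(gradient_position_map(c(h, w), 110,
                                                       "azimuth"),
                                 "azimuth", 110,
                                 magnitude = matrix(1, h, w)),
       elevation = retinotopic_map(gradient_position_map(c(h, w), 60,
                                                         "elevation"),
                                   "elevation", 60,
                                   magnitude = matrix(1, h, w)))
}

# rigidly transform a retinotopic map (planted-transform fixtures)
warp_retmap <- function(m, angle_deg, dx, dy) {
  pos <- apply_rigid_field(m$position_deg, angle_deg, dx, dy,
                           circular = TRUE, period = m$span_deg)
  valid <- !is.na(pos)
  pos[!valid] <- 0
  mag <- apply_rigid_field(m$magnitude, angle_deg, dx, dy)
  mag[is.na(mag)] <- 0
  retinotopic_map(pos, m$axis, m$span_deg, mag, valid_mask = valid)
}

# group_map_set with n identical copies of a value matrix
stack_group <- function(value, magnitude, n, period, kind = "retinotopy") {
  h <- nrow(value); w <- ncol(value)
  group_map_set(array(rep(value, n), c(h, w, n)),
                array(rep(magnitude, n), c(h, w, n)),
                array(TRUE, c(h, w, n)), period, kind)
}
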