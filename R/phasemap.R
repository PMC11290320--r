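#' Intrinsic-imaging movie container
#'
#' A movie is a time x height x width array of pixel intensities recorded at
#' a fixed frame rate under a periodic stimulation protocol. Row 1 of each
#' frame is the top of the field of view and columns increase rightward.
#'
#' @param data numeric array, time x height x width, finite values.
#' @param frame_rate_hz sampling rate in Hz.
#' @param protocol the [stim_protocol()] the movie was recorded under.
#' @return an object of class `oi_movie`.
#' @export
oi_movie <- function(data, frame_rate_hz, protocol = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, frame_rate_hz > 0)
  if (!all(is.finite(data))) stop("movie contains non-finite values")
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 protocol = protocol),
            class = "oi_movie")
}

#' @export
print.oi_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("oi_movie: %d frames of %dx%d px at %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, d[1] / x$frame_rate_hz))
  invisible(x)
}

# time x pixels matrix view of a movie
movie_matrix <- function(movie) {
  d <- dim(movie$data)
  dim(movie$data) <- c(d[1], d[2] * d[3])
  movie$data
}

#' Remove slow signal components unrelated to the stimulation
#'
#' Per-pixel detrending prior to demodulation: subtracts the temporal mean, a
#' least-squares line, and a centered moving average whose window is one
#' stimulation period. A moving average over exactly one period contains no
#' power at the stimulation frequency, so subtracting it removes DC and slow
#' drift while leaving the stimulus-locked component intact. Windows that
#' would extend past the movie are replaced by the nearest full-length
#' window, so every subtracted value remains a full-period mean.
#'
#' @param movie an [oi_movie()].
#' @param f_stim_hz stimulation frequency in Hz; the moving-average window is
#'   `round(frame_rate / f_stim)` frames.
#' @return the detrended `oi_movie`.
#' @export
remove_slow_components <- function(movie, f_stim_hz) {
  stopifnot(inherits(movie, "oi_movie"), f_stim_hz > 0)
  d <- dim(movie$data)
  n <- d[1]
  if (n < 2 * movie$frame_rate_hz / f_stim_hz)
    stop("movie shorter than 2 stimulation cycles")
  x <- movie_matrix(movie)

  # mean + least-squares line
  tc <- seq_len(n) - (n + 1) / 2
  x <- sweep(x, 2, colMeans(x))
  slope <- crossprod(tc, x) / sum(tc^2)
  x <- x - tcrossprod(tc, as.vector(slope))

  # centered moving average over one stimulation period, full windows only
  w <- max(2L, as.integer(round(movie$frame_rate_hz / f_stim_hz)))
  if (w < n) {
    cs <- rbind(0, apply(x, 2, cumsum))
    win_means <- (cs[(w + 1):(n + 1), , drop = FALSE] -
                  cs[1:(n - w + 1), , drop = FALSE]) / w
    h1 <- w %/% 2                       # window i covers [i - h1, i + (w-1-h1)]
    idx <- pmin(pmax(seq_len(n) - h1, 1L), n - w + 1L)
    x <- x - win_means[idx, , drop = FALSE]
  }
  x <- sweep(x, 2, colMeans(x))

  dim(x) <- d
  movie$data <- x
  movie
}

#' Per-pixel phase map container
#'
#' Holds the per-pixel phase and magnitude of a movie at one analysis
#' frequency, under the convention `x(t) ~ M * cos(2*pi*f*t - Phi)` with
#' `Phi` wrapped to `[0, 2*pi)`. Masked pixels carry phase 0 and magnitude 0.
#'
#' @param phase,magnitude height x width matrices.
#' @param f_analysis_hz analysis frequency in Hz.
#' @param valid_mask logical matrix; defaults to all `TRUE`.
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phase, magnitude, f_analysis_hz, valid_mask = NULL) {
  stopifnot(is.matrix(phase), all(dim(phase) == dim(magnitude)),
            f_analysis_hz > 0)
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(phase))
  stopifnot(all(dim(valid_mask) == dim(phase)))
  phase <- wrap_period(phase)
  if (any(magnitude < 0)) stop("magnitudes must be non-negative")
  phase[!valid_mask] <- 0
  magnitude[!valid_mask] <- 0
  structure(list(phase = phase, magnitude = magnitude,
                 f_analysis_hz = f_analysis_hz, valid_mask = valid_mask),
            class = "phase_map")
}

#' Single-frequency Fourier demodulation of a movie
#'
#' Computes, per pixel, the complex demodulate
#' `C = (2/N) * sum_n x_n * exp(-i*2*pi*f*t_n)` over the largest prefix of
#' the movie covering an integer number of analysis cycles, and returns
#' magnitude `M = |C|` and phase `Phi = -Arg(C) mod 2*pi`, so that
#' `x(t) = M*cos(2*pi*f*t - Phi)` yields exactly `(M, Phi)`.
#'
#' @param movie an [oi_movie()].
#' @param f_analysis_hz analysis frequency; must not exceed the Nyquist
#'   frequency. If the movie duration is not an integer number of analysis
#'   cycles it is truncated to the largest integer-cycle prefix (with a
#'   message).
#' @return a [phase_map()].
#' @export
extract_fourier_component <- function(movie, f_analysis_hz) {
  stopifnot(inherits(movie, "oi_movie"), f_analysis_hz > 0)
  fr <- movie$frame_rate_hz
  if (f_analysis_hz > fr / 2 + 1e-12)
    stop("analysis frequency above Nyquist")
  d <- dim(movie$data)
  n <- d[1]
  n_cycles <- floor(n / fr * f_analysis_hz + 1e-9)
  if (n_cycles < 1) stop("movie shorter than one analysis cycle")
  n_keep <- as.integer(round(n_cycles / f_analysis_hz * fr))
  n_keep <- min(n_keep, n)
  if (n_keep < n)
    message(sprintf(
      "truncating movie from %d to %d frames (%d full analysis cycles)",
      n, n_keep, n_cycles))
  x <- movie_matrix(movie)[seq_len(n_keep), , drop = FALSE]
  tn <- (seq_len(n_keep) - 1) / fr
  wt <- 2 * pi * f_analysis_hz * tn
  C <- complex(real = as.vector(crossprod(x, cos(wt))),
               imaginary = -as.vector(crossprod(x, sin(wt)))) * (2 / n_keep)
  phase <- matrix(wrap_period(-Arg(C)), d[2], d[3])
  magnitude <- matrix(Mod(C), d[2], d[3])
  phase_map(phase, magnitude, f_analysis_hz)
}
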