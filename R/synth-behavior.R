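#' Generate a synthetic arrest-assay pose track
#'
#' Simulates a mouse running at constant speed along a circular path inside a
#' cylindrical arena, with the speed dropping by `arrest_fraction` from
#' `arrest_delay_s` after the first flash onward (by default the drop
#' persists to the end of the recording). Body-part positions (snout,
#' barycenter, tail base) integrate the speed profile; positional Gaussian
#' noise and likelihood dropouts emulate pose-estimation output at 25 frames
#' per second. Dropout frames receive likelihoods uniform on [0, 0.9); valid
#' frames uniform on [0.95, 1].
#'
#' @param v_baseline_cms baseline running speed (cm/s, default 10).
#' @param arrest_fraction fractional speed drop in `[0, 1]`; the planted
#'   modulation index.
#' @param flash_time_s first flash onset (s); must allow a 1 s baseline and
#'   the 4 s post-flash analysis window inside the recording.
#' @param duration_s recording length (s, default 20).
#' @param frame_rate acquisition rate (default 25 frames/s).
#' @param noise_sd positional noise on each coordinate (px, default 0).
#' @param dropout_rate per-frame probability of a likelihood dropout
#'   (default 0).
#' @param seed RNG seed.
#' @param arrest_delay_s latency from flash to the speed drop (default 1 s).
#' @param arrest_duration_s duration of the drop (default `Inf`: the arrest
#'   persists to the end of the recording).
#' @param arena_diameter_cm arena diameter (30 cm).
#' @param px_per_cm camera scale (default 10 px/cm).
#' @return list with `track` (a [pose_track()]), `flash_onsets_s` (three
#'   flashes spanning 1 s) and `truth` (planted parameters, including the
#'   planted modulation index and the dropout mask).
#' @export
make_arrest_trajectory <- function(v_baseline_cms = 10, arrest_fraction = 0.8,
                                   flash_time_s = 10, duration_s = 20,
                                   frame_rate = 25, noise_sd = 0,
                                   dropout_rate = 0, seed = 1L,
                                   arrest_delay_s = 1,
                                   arrest_duration_s = Inf,
                                   arena_diameter_cm = 30, px_per_cm = 10) {
  stopifnot(arrest_fraction >= 0, arrest_fraction <= 1,
            v_baseline_cms >= 0, dropout_rate >= 0, dropout_rate <= 1)
  if (flash_time_s <= 0 || flash_time_s >= duration_s)
    stop("flash outside recording")
  n <- as.integer(round(duration_s * frame_rate))
  t <- (seq_len(n) - 1) / frame_rate

  v <- rep(v_baseline_cms, n)
  in_arrest <- t >= flash_time_s + arrest_delay_s &
               t < flash_time_s + arrest_delay_s + arrest_duration_s
  v[in_arrest] <- v_baseline_cms * (1 - arrest_fraction)
  if (any(v < 0)) stop("negative speed")

  # circular path of radius a quarter arena diameter; arc speed equals v
  r_cm <- arena_diameter_cm / 4
  theta <- cumsum(c(0, v[-n])) / frame_rate / r_cm
  center <- arena_diameter_cm / 2
  bary <- cbind(center + r_cm * cos(theta), center + r_cm * sin(theta))
  tangent <- cbind(-sin(theta), cos(theta))
  snout <- bary + 1.5 * tangent
  tail <- bary - 2.0 * tangent

  set.seed(seed)
  parts <- list(snout = snout, barycenter = bary, tail_base = tail)
  df <- data.frame(time_s = t)
  dropout <- matrix(FALSE, n, length(parts),
                    dimnames = list(NULL, names(parts)))
  for (p in names(parts)) {
    xy <- parts[[p]] * px_per_cm
    if (noise_sd > 0)
      xy <- xy + matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
    lik <- stats::runif(n, 0.95, 1)
    drop <- stats::runif(n) < dropout_rate
    lik[drop] <- stats::runif(sum(drop), 0, 0.9)
    dropout[, p] <- drop
    df[[paste0(p, "_x")]] <- xy[, 1]
    df[[paste0(p, "_y")]] <- xy[, 2]
    df[[paste0(p, "_likelihood")]] <- lik
  }
  flashes <- flash_time_s + c(0, 0.35, 0.7)
  track <- pose_track(df, frame_rate_hz = frame_rate,
                      flash_onsets_s = flashes, px_per_cm = px_per_cm)
  list(track = track, flash_onsets_s = flashes,
       truth = list(modulation_index = arrest_fraction,
                    v_baseline_cms = v_baseline_cms,
                    flash_time_s = flash_time_s, dropout = dropout,
                    seed = as.integer(seed)))
}
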