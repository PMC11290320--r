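#' Pose-tracking table
#'
#' A data frame of tracked body-part coordinates at a fixed frame rate, with
#' one `<part>_x`, `<part>_y`, `<part>_likelihood` column triple per body
#' part (snout, barycenter, tail_base by default) and a `time_s` column.
#' Flash onset times and the frame rate travel as attributes.
#'
#' @param df data frame with `time_s` and the coordinate/likelihood columns.
#' @param frame_rate_hz acquisition rate (25 Hz for the arrest assay).
#' @param flash_onsets_s numeric vector of flash onset times (s).
#' @param px_per_cm optional pixel pitch for converting speeds to cm/s.
#' @return an object of class `pose_track` (a data frame).
#' @export
pose_track <- function(df, frame_rate_hz = 25, flash_onsets_s = numeric(),
                       px_per_cm = NULL) {
  stopifnot(is.data.frame(df), "time_s" %in% names(df))
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("time must be strictly increasing")
  lik <- grep("_likelihood$", names(df), value = TRUE)
  if (!length(lik)) stop("no body-part likelihood columns found")
  for (cl in lik) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("likelihoods must lie in [0, 1]")
  }
  structure(df, frame_rate_hz = frame_rate_hz,
            flash_onsets_s = flash_onsets_s, px_per_cm = px_per_cm,
            class = c("pose_track", "data.frame"))
}

track_parts <- function(track) {
  sub("_likelihood$", "", grep("_likelihood$", names(track), value = TRUE))
}

#' Mask unreliable frames and smooth a pose track
#'
#' Frames whose likelihood falls below the threshold are removed (set to
#' `NA`) per body part, gaps are linearly interpolated up to a configurable
#' limit (longer gaps stay missing), and positions are smoothed by a centered
#' moving average over five valid frames.
#'
#' @param track a [pose_track()].
#' @param likelihood_threshold frames below this likelihood are masked
#'   (default 0.9).
#' @param smooth_window moving-average window in frames (default 5).
#' @param max_gap_s longest gap bridged by interpolation, in seconds
#'   (default 0.5).
#' @return the cleaned `pose_track`; the per-part masks are attached as the
#'   `masked` attribute (frames x parts logical matrix).
#' @export
clean_track <- function(track, likelihood_threshold = 0.9,
                        smooth_window = 5L, max_gap_s = 0.5) {
  stopifnot(inherits(track, "pose_track"))
  fr <- attr(track, "frame_rate_hz")
  max_gap <- max(1L, as.integer(round(max_gap_s * fr)))
  parts <- track_parts(track)
  masked <- matrix(FALSE, nrow(track), length(parts),
                   dimnames = list(NULL, parts))
  for (p in parts) {
    bad <- track[[paste0(p, "_likelihood")]] < likelihood_threshold
    masked[, p] <- bad
    if (all(bad)) stop(sprintf("all frames masked for body part '%s'", p))
    for (ax in c("_x", "_y")) {
      v <- track[[paste0(p, ax)]]
      v[bad] <- NA_real_
      v <- zoo::na.approx(v, na.rm = FALSE, maxgap = max_gap)
      v <- zoo::rollapply(v, width = smooth_window, FUN = mean,
                          na.rm = TRUE, partial = TRUE, align = "center")
      v[is.nan(v)] <- NA_real_
      track[[paste0(p, ax)]] <- v
    }
  }
  attr(track, "masked") <- masked
  track
}

#' Running speed of a body part
#'
#' Differentiates the x and y coordinates with a Savitzky-Golay filter and
#' returns the Euclidean speed. Missing stretches (masked frames that could
#' not be bridged) yield `NA` speeds; each contiguous valid run must be at
#' least one filter window long to contribute.
#'
#' @param track a (cleaned) [pose_track()].
#' @param body_part which part to use; the barycenter is the canonical choice
#'   for locomotion.
#' @param sg_window Savitzky-Golay window length in frames (odd, default 7).
#' @param sg_order polynomial order (default 2).
#' @param cm_per_px optional scale; if given, speeds are in cm/s, otherwise
#'   px/s.
#' @return a [speed_trace()].
#' @export
compute_speed <- function(track, body_part = "barycenter", sg_window = 7L,
                          sg_order = 2L, cm_per_px = NULL) {
  stopifnot(inherits(track, "pose_track"))
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  fr <- attr(track, "frame_rate_hz")
  x <- track[[paste0(body_part, "_x")]]
  y <- track[[paste0(body_part, "_y")]]
  if (is.null(x)) stop(sprintf("no body part '%s' in track", body_part))
  n <- length(x)
  if (sum(is.finite(x)) < sg_window) stop("fewer valid frames than sg_window")

  speed <- rep(NA_real_, n)
  ok <- is.finite(x) & is.finite(y)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < sg_window) next
    idx <- starts[i]:ends[i]
    vx <- signal::sgolayfilt(x[idx], p = sg_order, n = sg_window, m = 1,
                             ts = 1 / fr)
    vy <- signal::sgolayfilt(y[idx], p = sg_order, n = sg_window, m = 1,
                             ts = 1 / fr)
    speed[idx] <- sqrt(vx^2 + vy^2)
  }
  units <- "px/s"
  if (is.null(cm_per_px)) {
    ppc <- attr(track, "px_per_cm")
    if (!is.null(ppc)) cm_per_px <- 1 / ppc
  }
  if (!is.null(cm_per_px)) {
    speed <- speed * cm_per_px
    units <- "cm/s"
  }
  speed_trace(track$time_s, speed, units = units,
              flash_onsets_s = attr(track, "flash_onsets_s"))
}

#' Speed trace container
#'
#' @param time_s sample times (s), strictly increasing.
#' @param speed non-negative speeds (`NA` allowed for untracked frames).
#' @param units `"px/s"` or `"cm/s"`.
#' @param flash_onsets_s optional flash onset times.
#' @return an object of class `speed_trace`.
#' @export
speed_trace <- function(time_s, speed, units = "cm/s",
                        flash_onsets_s = numeric()) {
  stopifnot(length(time_s) == length(speed))
  if (any(speed < 0, na.rm = TRUE)) stop("speeds must be non-negative")
  structure(list(time_s = time_s, speed = speed, units = units,
                 flash_onsets_s = flash_onsets_s),
            class = "speed_trace")
}

#' Baseline and arrest speed around the first light flash
#'
#' `V_baseline` is the mean running speed in the 1 s window immediately
#' before the first flash, `V_arrest` the mean in the 3 s window starting 1 s
#' after it, and the speed-modulation index is
#' `(V_baseline - V_arrest) / V_baseline`: 1 indicates a full stop, 0 no
#' change, and a speed increase gives a negative index (no clipping).
#'
#' A trial in which the animal was not running (`V_baseline` below
#' `min_baseline`) is not an analysis failure: it is returned with
#' `rejected = TRUE`, `modulation_index = NA`, and a
#' `collimap_trial_rejected` warning, distinct from errors raised for windows
#' outside the recording.
#'
#' @param trace a [speed_trace()].
#' @param first_flash_s onset of the first flash (s); defaults to the first
#'   entry of the trace's flash onsets.
#' @param baseline_window_s,arrest_delay_s,arrest_window_s window geometry in
#'   seconds (defaults 1, 1, 3).
#' @param min_baseline minimum baseline speed for the trial to count as
#'   "in motion" (same units as the trace; default 2, i.e. 2 cm/s for cm/s
#'   traces).
#' @return an object of class `arrest_metrics`: list with `v_baseline`,
#'   `v_arrest`, `modulation_index`, `rejected`, `units`.
#' @export
arrest_metrics <- function(trace, first_flash_s = NULL,
                           baseline_window_s = 1, arrest_delay_s = 1,
                           arrest_window_s = 3, min_baseline = 2) {
  stopifnot(inherits(trace, "speed_trace"))
  if (is.null(first_flash_s)) {
    if (!length(trace$flash_onsets_s)) stop("no flash onset given")
    first_flash_s <- min(trace$flash_onsets_s)
  }
  tt <- trace$time_s
  t0 <- first_flash_s
  if (t0 - baseline_window_s < tt[1] ||
      t0 + arrest_delay_s + arrest_window_s > tt[length(tt)])
    stop("analysis windows extend outside the recording")
  base_idx <- tt >= t0 - baseline_window_s & tt < t0
  arr_idx <- tt >= t0 + arrest_delay_s &
             tt < t0 + arrest_delay_s + arrest_window_s
  vb <- mean(trace$speed[base_idx], na.rm = TRUE)
  va <- mean(trace$speed[arr_idx], na.rm = TRUE)
  if (!is.finite(vb) || !is.finite(va))
    stop("no tracked frames inside an analysis window")
  rejected <- vb < min_baseline
  idx <- if (rejected) NA_real_ else (vb - va) / vb
  if (rejected)
    warning(structure(class = c("collimap_trial_rejected", "warning",
                                "condition"),
                      list(message = sprintf(
                             "trial rejected: baseline speed %.3g below %g",
                             vb, min_baseline),
                           call = sys.call())))
  structure(list(v_baseline = vb, v_arrest = va, modulation_index = idx,
                 rejected = rejected, units = trace$units),
            class = "arrest_metrics")
}

#' Mean and standard error of a set of modulation indices
#'
#' @param indices numeric vector (rejected trials' `NA`s are dropped).
#' @return list with `mean`, `sem`, `n`.
#' @export
group_summary <- function(indices) {
  x <- indices[is.finite(indices)]
  n <- length(x)
  if (!n) stop("no usable indices")
  list(mean = mean(x),
       sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
       n = n)
}
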