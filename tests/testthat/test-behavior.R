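test_that("track cleaning masks unreliable frames and smooths the rest", {
  n <- 100
  df <- data.frame(time_s = (0:(n - 1)) / 25,
                   barycenter_x = seq_len(n) * 1.0,
                   barycenter_y = rep(2, n),
                   barycenter_likelihood = rep(1, n))
  tr <- pose_track(df, 25)
  cl <- clean_track(tr)
  # a linear position is invariant under the centered moving average
  interior <- 3:(n - 2)
  expect_equal(cl$barycenter_x[interior], df$barycenter_x[interior],
               tolerance = 1e-12)

  # alternating low likelihood: those frames are masked (then interpolated)
  df2 <- df
  df2$barycenter_likelihood[seq(1, n, by = 2)] <- 0.5
  cl2 <- clean_track(pose_track(df2, 25))
  expect_true(all(attr(cl2, "masked")[seq(1, n, by = 2), "barycenter"]))
  expect_false(any(attr(cl2, "masked")[seq(2, n, by = 2), "barycenter"]))

  df3 <- df
  df3$barycenter_likelihood <- rep(0.1, n)
  expect_error(clean_track(pose_track(df3, 25)), "all frames masked")
})

test_that("long gaps stay missing, short gaps are bridged", {
  n <- 200
  df <- data.frame(time_s = (0:(n - 1)) / 25,
                   barycenter_x = seq_len(n) * 1.0,
                   barycenter_y = rep(0, n),
                   barycenter_likelihood = rep(1, n))
  df$barycenter_likelihood[50:52] <- 0.2        # 0.12 s gap: bridged
  df$barycenter_likelihood[100:130] <- 0.2      # 1.24 s gap: not bridged
  cl <- clean_track(pose_track(df, 25), max_gap_s = 0.5)
  expect_true(all(is.finite(cl$barycenter_x[50:52])))
  expect_true(any(is.na(cl$barycenter_x[105:125])))
})

test_that("planted dropouts match the generator's bookkeeping", {
  tr <- make_arrest_trajectory(arrest_fraction = 0.5, flash_time_s = 8,
                               duration_s = 16, dropout_rate = 0.1,
                               seed = 12)
  cl <- clean_track(tr$track)
  expect_equal(unname(attr(cl, "masked")[, "barycenter"]),
               unname(tr$truth$dropout[, "barycenter"]))
})

test_that("Savitzky-Golay speed is exact for uniform motion", {
  n <- 120
  df <- data.frame(time_s = (0:(n - 1)) / 25,
                   barycenter_x = seq_len(n) * 1.0,   # 1 px/frame
                   barycenter_y = rep(5, n),
                   barycenter_likelihood = rep(1, n))
  sp <- compute_speed(pose_track(df, 25))
  expect_equal(sp$speed[10:(n - 10)], rep(25, n - 19), tolerance = 1e-9)

  still <- df; still$barycenter_x <- rep(1, n)
  sp0 <- compute_speed(pose_track(still, 25))
  expect_lt(max(sp0$speed, na.rm = TRUE), 1e-9)

  expect_error(compute_speed(pose_track(df, 25), sg_window = 6), "odd")
  expect_error(compute_speed(pose_track(df[1:5, ], 25)),
               "fewer valid frames")
})

test_that("speed agrees with a central-difference oracle on noisy tracks", {
  set.seed(51)
  n <- 500
  x <- cumsum(rnorm(n, 1, 0.05)) + rnorm(n, 0, 0.2)
  y <- cumsum(rnorm(n, 0.5, 0.05)) + rnorm(n, 0, 0.2)
  df <- data.frame(time_s = (0:(n - 1)) / 25, barycenter_x = x,
                   barycenter_y = y, barycenter_likelihood = rep(1, n))
  sp <- compute_speed(pose_track(df, 25))
  # oracle: central differences of 5-frame-smoothed positions
  sm <- function(v) stats::filter(v, rep(1 / 5, 5))
  vx <- (sm(x)[3:n] - sm(x)[1:(n - 2)]) / 2 * 25
  vy <- (sm(y)[3:n] - sm(y)[1:(n - 2)]) / 2 * 25
  oracle <- sqrt(vx^2 + vy^2)
  i <- 10:(n - 10)
  rel_rms <- sqrt(mean((sp$speed[i] - oracle[i - 2])^2, na.rm = TRUE)) /
    mean(oracle, na.rm = TRUE)
  expect_lt(rel_rms, 0.05)
})

test_that("arrest metrics implement the printed index formula", {
  t <- seq(0, 20, by = 0.04)
  flash <- 10
  mk <- function(v) speed_trace(t, v)
  # complete stop one second after the flash
  v_stop <- ifelse(t >= flash + 1, 0, 12)
  expect_equal(arrest_metrics(mk(v_stop), flash)$modulation_index, 1)
  # unchanged speed
  expect_equal(arrest_metrics(mk(rep(12, length(t))), flash)$modulation_index,
               0)
  # V_baseline 10, V_arrest 2.5
  v <- ifelse(t >= flash + 1 & t < flash + 4, 2.5, 10)
  expect_equal(arrest_metrics(mk(v), flash)$modulation_index, 0.75)
  # speeding up gives a negative, unclipped index
  v_up <- ifelse(t >= flash + 1, 20, 10)
  expect_equal(arrest_metrics(mk(v_up), flash)$modulation_index, -1)
})

test_that("the index is invariant under rescaling of all speeds", {
  t <- seq(0, 20, by = 0.04)
  v <- ifelse(t >= 11 & t < 14, 3, 9)
  i1 <- arrest_metrics(speed_trace(t, v), 10)$modulation_index
  i2 <- arrest_metrics(speed_trace(t, 7.3 * v), 10)$modulation_index
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("slow trials are rejected distinctly from hard errors", {
  t <- seq(0, 20, by = 0.04)
  slow <- speed_trace(t, rep(0.5, length(t)))
  expect_warning(m <- arrest_metrics(slow, 10), class =
                   "collimap_trial_rejected")
  expect_true(m$rejected)
  expect_true(is.na(m$modulation_index))
  # windows outside the recording are errors, not rejections
  expect_error(arrest_metrics(speed_trace(t, rep(10, length(t))), 0.5),
               "outside the recording")
  expect_error(arrest_metrics(speed_trace(t, rep(10, length(t))), 19),
               "outside the recording")
})

test_that("planted arrest fractions are recovered through the full chain", {
  # noiseless: within 0.02
  tr <- make_arrest_trajectory(arrest_fraction = 0.75, flash_time_s = 10,
                               duration_s = 20, noise_sd = 0, seed = 1)
  sp <- compute_speed(clean_track(tr$track))
  m <- arrest_metrics(sp, tr$flash_onsets_s[1])
  expect_false(m$rejected)
  expect_equal(m$modulation_index, 0.75, tolerance = 0.02)

  # noisy: mean over 50 seeds within 0.1
  idx <- vapply(1:50, function(s) {
    tr <- make_arrest_trajectory(arrest_fraction = 0.6, flash_time_s = 10,
                                 duration_s = 20, noise_sd = 2,
                                 dropout_rate = 0.05, seed = s)
    sp <- compute_speed(clean_track(tr$track))
    arrest_metrics(sp, tr$flash_onsets_s[1])$modulation_index
  }, numeric(1))
  expect_equal(mean(idx), 0.6, tolerance = 0.1)
})

test_that("group summaries are mean +/- SEM", {
  expect_equal(group_summary(c(1, 1, 1)), list(mean = 1, sem = 0, n = 3))
  expect_equal(group_summary(c(0, 1)), list(mean = 0.5, sem = 0.5, n = 2))
  set.seed(52)
  x <- rnorm(17)
  gs <- group_summary(x)
  expect_equal(gs$mean, mean(x))
  expect_equal(gs$sem, stats::sd(x) / sqrt(17))
  expect_equal(group_summary(c(NA, 2, 4))$n, 2)
  expect_error(group_summary(c(NA_real_, NA_real_)), "no usable")
})
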