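test_that("noiseless single-pixel session is a pure delayed cosine", {
  prot <- tiny_protocol()
  truth <- imaging_truth(matrix(0, 1, 1), delay_s = 0, noise_sd = 0,
                         drift_amp = 0)
  ses <- make_retinotopy_sessions(truth, prot)
  n <- dim(ses$forward$data)[1]
  tt <- (seq_len(n) - 1) / prot$frame_rate_hz
  expect_equal(as.vector(ses$forward$data), cos(2 * pi * prot$f_stim_hz * tt),
               tolerance = 1e-12)
  # position 0 and no delay: forward and reverse coincide
  expect_equal(ses$forward$data, ses$reverse$data, tolerance = 1e-12)
})

test_that("the same seed reproduces movies bit for bit", {
  prot <- tiny_protocol()
  truth <- imaging_truth(gradient_position_map(c(8, 8), 110), noise_sd = 0.5,
                         drift_amp = 1, seed = 99)
  a <- make_retinotopy_sessions(truth, prot)
  b <- make_retinotopy_sessions(truth, prot)
  expect_identical(a$forward$data, b$forward$data)
  expect_identical(a$reverse$data, b$reverse$data)
  prot2 <- tiny_protocol("ccw")
  to <- imaging_truth(orientation_map_deg = patch_orientation_map(c(8, 8), 4),
                      noise_sd = 0.5, seed = 98)
  oa <- make_orientation_sessions(to, prot2)
  ob <- make_orientation_sessions(to, prot2)
  expect_identical(oa$ccw$data, ob$ccw$data)
})

test_that("generator rejects inconsistent inputs", {
  prot <- tiny_protocol()
  expect_error(make_retinotopy_sessions(
    imaging_truth(matrix(150, 1, 1)), prot), "positions")
  expect_error(make_retinotopy_sessions(
    imaging_truth(matrix(10, 1, 1), delay_s = 5), prot), "delay")
  expect_error(stim_protocol(frame_rate_hz = -5))
  # non-integer number of frames per session
  expect_error(make_retinotopy_sessions(
    imaging_truth(matrix(10, 1, 1)),
    stim_protocol(frame_rate_hz = 0.07)), "integer number of frames")
})

test_that("orientation sessions encode the doubled angle", {
  prot <- tiny_protocol("ccw")
  f <- prot$f_analysis_hz
  zero <- imaging_truth(orientation_map_deg = matrix(0, 1, 1), delay_s = 0,
                        noise_sd = 0, drift_amp = 0)
  ses <- make_orientation_sessions(zero, prot)
  expect_equal(ses$ccw$data, ses$cw$data, tolerance = 1e-12)

  phase_of <- function(deg) {
    tr <- imaging_truth(orientation_map_deg = matrix(deg, 1, 1), delay_s = 0,
                        noise_sd = 0, drift_amp = 0)
    s <- make_orientation_sessions(tr, prot)
    extract_fourier_component(s$ccw, f)$phase[1, 1]
  }
  expect_lt(circ_err(phase_of(135) - phase_of(45), pi, 2 * pi), 1e-9)
})

test_that("hemodynamic gamma kernel attenuates and lags the response", {
  prot <- tiny_protocol()
  truth <- imaging_truth(matrix(55, 1, 1), delay_s = 0, noise_sd = 0,
                         drift_amp = 0)
  plain <- make_retinotopy_sessions(truth, prot)
  kern <- make_retinotopy_sessions(truth, prot, gamma_kernel = TRUE)
  pm_p <- extract_fourier_component(plain$forward, prot$f_stim_hz)
  pm_k <- extract_fourier_component(kern$forward, prot$f_stim_hz)
  expect_lt(pm_k$magnitude[1, 1], pm_p$magnitude[1, 1])
  # the kernel phase lag is positive (a delay)
  lag <- (pm_k$phase[1, 1] - pm_p$phase[1, 1]) %% (2 * pi)
  expect_gt(lag, 0)
  expect_lt(lag, pi)
})

test_that("noiseless planted retinotopy is recovered within 0.5 degrees", {
  prot <- tiny_protocol(n_repeats = 10)
  truth <- imaging_truth(gradient_position_map(c(16, 16), 110),
                         delay_s = 1.5, noise_sd = 0, drift_amp = 1,
                         seed = 4)
  rec <- recover_retinotopy(make_retinotopy_sessions(truth, prot), prot)
  expect_lt(max(circ_err(rec$position_deg, truth$position_map_deg, 110)),
            0.5)
  expect_equal(rec$delay_estimate_s, 1.5, tolerance = 0.01)
})

test_that("noiseless planted orientation is recovered within 1 degree", {
  prot <- tiny_protocol("ccw", n_cycles = 2)
  truth <- imaging_truth(orientation_map_deg = patch_orientation_map(c(16, 16),
                                                                     4),
                         delay_s = 1.5, noise_sd = 0, drift_amp = 1,
                         seed = 5)
  rec <- recover_orientation(make_orientation_sessions(truth, prot), prot)
  expect_lt(max(circ_err(rec$orientation_deg, truth$orientation_map_deg,
                         180)), 1)
})

test_that("doubling the noise does not bias the recovered phase", {
  prot <- tiny_protocol(n_repeats = 4)
  f <- prot$f_stim_hz
  bias_at <- function(noise_sd) {
    errs <- vapply(1:120, function(s) {
      truth <- imaging_truth(matrix(27.5, 1, 1), delay_s = 1, noise_sd =
                               noise_sd, drift_amp = 0, seed = s)
      ses <- make_retinotopy_sessions(truth, prot)
      pm <- extract_fourier_component(ses$forward, f)
      planted <- 2 * pi * 27.5 / 110 + 2 * pi * f * 1
      d <- (pm$phase[1, 1] - planted) %% (2 * pi)
      if (d > pi) d - 2 * pi else d
    }, numeric(1))
    c(mean(errs), stats::sd(errs) / sqrt(length(errs)))
  }
  b1 <- bias_at(0.5)
  b2 <- bias_at(1.0)
  expect_lt(abs(b1[1]), 3 * b1[2])
  expect_lt(abs(b2[1]), 3 * b2[2])
})

test_that("coupling generator truncates at the surface and respects seeds", {
  nw <- make_coupling_network(200, 150, 150, injection_depth_um = 100,
                              seed = 3)
  expect_equal(nrow(nw$network$cells_xy), 200)
  # all cells inside the tissue (y > 0 for the flat default surface)
  expect_true(all(nw$network$cells_xy[, 2] > 0))
  # dorsal max extent cannot exceed the injection depth under truncation
  e <- directional_extents(nw$network, "max")
  expect_lte(e$dorsal, 100)
  nw2 <- make_coupling_network(200, 150, 150, injection_depth_um = 100,
                               seed = 3)
  expect_identical(nw$network$cells_xy, nw2$network$cells_xy)
  expect_error(make_coupling_network(10, 50, 50, injection_depth_um = -5),
               "outside the tissue")
})

test_that("single-cell networks have non-negative extents", {
  nw <- make_coupling_network(1, 50, 50, injection_depth_um = 400, seed = 1)
  e <- directional_extents(nw$network, "max")
  expect_gte(e$dorsal, 0)
  expect_gte(e$ventral, 0)
  expect_gte(e$medial, 0)
  expect_gte(e$lateral, 0)
})

test_that("arrest trajectories freeze after the flash when fraction is 1", {
  tr <- make_arrest_trajectory(arrest_fraction = 1, flash_time_s = 8,
                               duration_s = 16, noise_sd = 0, seed = 2)
  t <- tr$track$time_s
  x <- tr$track$barycenter_x
  after <- t >= 9.05          # arrest starts at flash + 1 s
  expect_lt(max(abs(diff(x[after]))), 1e-9)
  # planted index 0 when nothing changes
  tr0 <- make_arrest_trajectory(arrest_fraction = 0, flash_time_s = 8,
                                duration_s = 16, noise_sd = 0, seed = 2)
  expect_equal(tr0$truth$modulation_index, 0)
  expect_error(make_arrest_trajectory(flash_time_s = 30, duration_s = 16),
               "flash outside")
  expect_error(make_arrest_trajectory(arrest_fraction = 1.5))
})
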