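mk_pm <- function(phase, f = 1 / 8, mag = NULL) {
  if (is.null(mag)) mag <- array(1, dim(phase))
  phase_map(phase, mag, f)
}

test_that("retinotopy from a phase-map pair: analytic anchors", {
  z <- matrix(0, 4, 4)
  r0 <- retinotopy_from_pair(mk_pm(z), mk_pm(z), 110)
  expect_equal(max(abs(r0$position_deg)), 0)
  expect_equal(r0$delay_estimate_s, 0)

  # forward pi/2 + 0.6, reverse -pi/2 + 0.6: delay phase 0.6, position 27.5
  fwd <- mk_pm(z + pi / 2 + 0.6)
  rev <- mk_pm(z + (-pi / 2 + 0.6) %% (2 * pi))
  r <- retinotopy_from_pair(fwd, rev, 110)
  expect_equal(r$position_deg[1, 1], 27.5, tolerance = 1e-9)
  expect_equal(r$delay_estimate_s, 0.6 / (2 * pi / 8), tolerance = 1e-9)
})

test_that("retinotopy pair construction validates inputs", {
  a <- mk_pm(matrix(0, 4, 4))
  b <- mk_pm(matrix(0, 5, 5))
  expect_error(retinotopy_from_pair(a, b, 110), "geometry")
  c2 <- mk_pm(matrix(0, 4, 4), f = 1 / 15)
  expect_error(retinotopy_from_pair(a, c2, 110), "frequencies")
})

test_that("orientation from a phase-map pair: analytic anchors", {
  f <- 1 / 15
  delta <- 0.9
  z <- matrix(0, 4, 4)
  same <- mk_pm(z + delta, f)
  o0 <- orientation_from_pair(same, same)
  expect_lt(max(circ_err(o0$orientation_deg, 0, 180)), 1e-9)
  expect_equal(o0$delay_estimate_s, delta / (2 * pi * f), tolerance = 1e-9)

  ccw <- mk_pm(z + delta + pi / 2, f)
  cw <- mk_pm(z + delta - pi / 2, f)
  o45 <- orientation_from_pair(ccw, cw)
  expect_lt(max(circ_err(o45$orientation_deg, 45, 180)), 1e-9)
})

test_that("shared delays cancel in the recovered position map", {
  prot <- tiny_protocol(n_repeats = 6)
  pos <- gradient_position_map(c(12, 12), 110)
  ref <- NULL
  for (delay in c(0.1, 1, 2.5, 3.9)) {
    truth <- imaging_truth(pos, delay_s = delay, noise_sd = 0,
                           drift_amp = 0)
    rec <- recover_retinotopy(make_retinotopy_sessions(truth, prot), prot)
    if (is.null(ref)) ref <- rec$position_deg
    expect_lt(max(circ_err(rec$position_deg, ref, 110)), 0.1)
    expect_lt(abs(rec$delay_estimate_s - delay), 1e-4)
  }
})

test_that("circular averaging of registered maps", {
  v <- gradient_position_map(c(8, 8), 110)
  g <- stack_group(v, matrix(1, 8, 8), 3, 110)
  avg <- average_registered_maps(g)
  expect_equal(avg$value_deg, v, tolerance = 1e-9)
  expect_true(all(avg$valid))
  expect_equal(avg$n_contrib, matrix(3, 8, 8))

  # antipodal orientations with equal weight are flagged invalid
  g2 <- group_map_set(array(c(10, 100), c(1, 1, 2)),
                      array(1, c(1, 1, 2)), array(TRUE, c(1, 1, 2)), 180,
                      "orientation")
  avg2 <- average_registered_maps(g2)
  expect_false(avg2$valid[1, 1])

  # matches circular_mean applied pixel by pixel with magnitude weights
  set.seed(31)
  vals <- array(runif(4 * 4 * 3, 0, 180), c(4, 4, 3))
  mags <- array(runif(4 * 4 * 3, 0.5, 2), c(4, 4, 3))
  g3 <- group_map_set(vals, mags, array(TRUE, c(4, 4, 3)), 180,
                      "orientation")
  avg3 <- average_registered_maps(g3)
  for (i in 1:4) for (j in 1:4) {
    expect_lt(circ_err(avg3$value_deg[i, j],
                       circular_mean(vals[i, j, ], mags[i, j, ],
                                     period = 180), 180), 1e-9)
  }
})

test_that("selective domain fraction counts significant border pixels", {
  v <- gradient_position_map(c(10, 10), 110)
  g <- stack_group(v, matrix(1, 10, 10), 3, 110)
  g <- pixelwise_reproducibility(g, alpha = 0.05, n_mc = 2000L, seed = 1)
  d <- selective_domain_fraction(g, pixel_pitch_um = 10.5)
  expect_equal(d$fraction, 1)       # identical strong maps everywhere
  expect_equal(d$area_mm2, 100 * (10.5 / 1000)^2)

  # checkerboard border: fraction relative to border pixels only
  border <- (row(v) + col(v)) %% 2 == 0
  g2 <- pixelwise_reproducibility(stack_group(v, matrix(1, 10, 10), 3, 110),
                                  alpha = 0.05, border_mask = border,
                                  n_mc = 2000L, seed = 1)
  d2 <- selective_domain_fraction(g2)
  expect_equal(d2$n_border, sum(border))
  expect_equal(d2$fraction, 1)
})

test_that("visual-field coverage maps significant pixels to field cells", {
  h <- 22; w <- 22
  az <- gradient_position_map(c(h, w), 110, "azimuth")
  el <- gradient_position_map(c(h, w), 60, "elevation")
  gaz <- pixelwise_reproducibility(stack_group(az, matrix(1, h, w), 3, 110),
                                   n_mc = 2000L, seed = 1)
  gel <- pixelwise_reproducibility(stack_group(el, matrix(1, h, w), 3, 60),
                                   n_mc = 2000L, seed = 1)
  cov <- visual_field_coverage(gaz, gel, cell_deg = 5)
  # full-field uniform maps: area = 110 x 60 within one grid cell ring
  expect_gte(cov$area_deg2, 110 * 60 - 5 * (110 + 60))
  expect_lte(cov$area_deg2, 110 * 60)

  # disjoint significance masks give empty coverage
  gaz2 <- gaz; gaz2$significance_mask[] <- FALSE
  cov2 <- visual_field_coverage(gaz2, gel)
  expect_equal(cov2$area_deg2, 0)
  expect_equal(cov2$n_cells, 0)
})

test_that("structure border detection recovers a planted disk", {
  h <- 40; w <- 40
  cx <- 20.5; cy <- 20.5
  dist <- sqrt((row(matrix(0, h, w)) - cy)^2 + (col(matrix(0, h, w)) - cx)^2)
  mag <- 1 * (dist < 12)
  border <- detect_structure_border(mag, threshold_frac = 0.5)
  disk <- dist < 12
  # recovered within a 1-px dilation of the disk
  expect_true(all(border[dist >= 13] == FALSE))
  expect_true(all(disk[dist < 11] <= border[dist < 11]))

  expect_true(all(detect_structure_border(matrix(2, 5, 5))))
  expect_warning(empty <- detect_structure_border(matrix(0, 5, 5)),
                 "all-zero")
  expect_false(any(empty))
})
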