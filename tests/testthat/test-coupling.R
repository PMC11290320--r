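flat_surface <- cbind(c(-1e4, 1e4), c(0, 0))

test_that("directional extents are plain projection arithmetic", {
  # axis-aligned frame: dorsal (0,-1), medial (1,0) on the left hemisphere
  net <- coupling_network(c(0, 10),
                          rbind(c(0, 10), c(1, 10), c(-1, 10),
                                c(0, 12), c(0, 8)),
                          flat_surface, hemisphere = "left")
  e <- directional_extents(net, "max")
  expect_equal(e$medial, 1)
  expect_equal(e$lateral, 1)
  expect_equal(e$dorsal, 2)     # toward the surface, y decreasing
  expect_equal(e$ventral, 2)
  expect_equal(e$n_cells, 5)
  expect_equal(e$injection_depth_um, 10)

  single <- coupling_network(c(0, 10), matrix(c(0, 10), 1), flat_surface)
  es <- directional_extents(single, "max")
  expect_equal(c(es$dorsal, es$ventral, es$medial, es$lateral),
               c(0, 0, 0, 0))
})

test_that("median and max statistics disagree as expected", {
  net <- coupling_network(c(0, 10),
                          rbind(c(1, 10), c(2, 10), c(9, 10)),
                          flat_surface)
  expect_equal(directional_extents(net, "median")$medial, 2)
  expect_equal(directional_extents(net, "max")$medial, 9)
})

test_that("extents are equivariant under joint rotation of the slice", {
  nw <- make_coupling_network(150, 120, 80, injection_depth_um = 400,
                              seed = 6)
  e0 <- directional_extents(nw$network, "max")
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(m) t(R %*% t(m))
  net_r <- coupling_network(as.vector(R %*% nw$network$injection_xy),
                            rot(nw$network$cells_xy),
                            rot(nw$network$surface_polyline),
                            hemisphere = "left")
  e1 <- directional_extents(net_r, "max")
  for (d in c("dorsal", "ventral", "medial", "lateral"))
    expect_equal(e1[[d]], e0[[d]], tolerance = 1e-9)
})

test_that("directional ratio arithmetic and bounds", {
  net <- coupling_network(c(0, 10), rbind(c(3, 10), c(-1, 10)), flat_surface)
  e <- directional_extents(net, "max")
  expect_equal(directional_ratio(e, "medial", "lateral"), 0.75)
  expect_equal(directional_ratio(e, "lateral", "medial"), 0.25)
  eq <- directional_extents(coupling_network(c(0, 10),
                                             rbind(c(2, 10), c(-2, 10)),
                                             flat_surface), "max")
  expect_equal(directional_ratio(eq, "medial", "lateral"), 0.5)
  zero <- directional_extents(coupling_network(c(0, 10),
                                               matrix(c(0, 10), 1),
                                               flat_surface), "max")
  expect_error(directional_ratio(zero), "both extents are zero")
})

test_that("isotropic deep networks have balanced dorsal/ventral spread", {
  set.seed(44)
  diffs <- vapply(1:60, function(i) {
    nw <- make_coupling_network(200, 100, 100, injection_depth_um = 1200,
                                seed = 500 + i)
    e <- directional_extents(nw$network, "max")
    e$dorsal - e$ventral
  }, numeric(1))
  mc_err <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * mc_err + 1e-9)
})

test_that("OLS regression matches the normal equations and edge cases", {
  set.seed(45)
  x <- rnorm(12, 500, 100)
  y <- 0.8 * x + rnorm(12, 0, 20)
  r <- extent_vs_depth_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_lt(abs(r$intercept - beta[1]), 1e-10)
  expect_lt(abs(r$slope - beta[2]), 1e-10)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_lt(abs(r$R_squared - r2), 1e-10)
  Fst <- r2 / (1 - r2) * 10
  expect_lt(abs(r$F_statistic - Fst), 1e-8)
  expect_lt(abs(r$p_value - stats::pf(Fst, 1, 10, lower.tail = FALSE)),
            1e-12)

  # perfectly collinear points
  rc <- extent_vs_depth_regression(1:5, 2 * (1:5) + 1)
  expect_equal(rc$R_squared, 1, tolerance = 1e-12)
  # constant response
  r0 <- extent_vs_depth_regression(1:5, rep(3, 5))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$R_squared, 0, tolerance = 1e-12)
  expect_error(extent_vs_depth_regression(1:2, 1:2), "at least 3")
  expect_error(extent_vs_depth_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("shallow injections: dorsal extent tracks depth, ventral does not",
{
  depths <- seq(40, 320, by = 40)
  ext <- lapply(seq_along(depths), function(i)
    directional_extents(
      make_coupling_network(400, 300, 300, injection_depth_um = depths[i],
                            seed = 600 + i)$network, "max"))
  dorsal <- vapply(ext, `[[`, numeric(1), "dorsal")
  ventral <- vapply(ext, `[[`, numeric(1), "ventral")
  # truncation: dorsal extent equals depth up to the largest draw below it
  expect_true(all(dorsal <= depths))
  rd <- extent_vs_depth_regression(depths, dorsal)
  rv <- extent_vs_depth_regression(depths, ventral)
  expect_gt(rd$R_squared, 0.9)
  expect_lt(rv$R_squared, 0.5)
})

test_that("cell counting follows the exclude-injected convention", {
  net <- coupling_network(c(0, 10), rbind(c(0, 10), c(1, 11), c(2, 12)),
                          flat_surface)
  expect_equal(count_coupled_cells(net), 2)
  expect_equal(count_coupled_cells(net, exclude_injected = FALSE), 3)
  one <- coupling_network(c(0, 10), matrix(c(0, 10), 1), flat_surface)
  expect_equal(count_coupled_cells(one), 0)
  nw <- make_coupling_network(500, 100, 100, injection_depth_um = 800,
                              seed = 9)
  expect_equal(count_coupled_cells(nw$network), 499)
})
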