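#' Generate a synthetic dye-coupling network
#'
#' Draws cell coordinates from a bivariate Gaussian centered at the injection
#' site, with independent medio-lateral and dorso-ventral standard
#' deviations, truncated by rejection at the tissue surface (only cells on
#' the tissue side of the surface polyline are kept). The isotropic case is
#' `sigma_ml == sigma_dv`. Coordinates are in micrometers, x medio-lateral,
#' y increasing ventrally; see [coupling_network()] for the frame convention.
#'
#' @param n_cells number of cells to draw (>= 1), including the injected
#'   cell.
#' @param sigma_ml,sigma_dv Gaussian standard deviations (um) along the
#'   medio-lateral and dorso-ventral axes; both > 0. Defaults (200 um) give
#'   networks a few hundred micrometers across, the scale of large collicular
#'   networks.
#' @param injection_depth_um depth of the injection site below the surface
#'   (um); must be positive (an injection on the wrong side of the surface is
#'   an error).
#' @param injection_x_um medio-lateral position of the injection (um).
#' @param surface_polyline surface polyline (um); defaults to a flat surface
#'   at y = 0.
#' @param hemisphere passed to [coupling_network()].
#' @param seed RNG seed.
#' @return list with `network` (a [coupling_network()]) and `truth` (planted
#'   parameters).
#' @export
make_coupling_network <- function(n_cells, sigma_ml = 200, sigma_dv = 200,
                                  injection_depth_um = 500,
                                  injection_x_um = 0,
                                  surface_polyline = NULL,
                                  hemisphere = "left", seed = 1L) {
  stopifnot(n_cells >= 1, sigma_ml > 0, sigma_dv > 0)
  if (is.null(surface_polyline))
    surface_polyline <- cbind(c(-1e5, 1e5), c(0, 0))
  surface_polyline <- matrix(as.numeric(surface_polyline), ncol = 2)

  # place the injection at the requested depth along the local inward normal
  probe <- c(injection_x_um, 0)
  f <- polyline_foot(probe, surface_polyline)
  injection <- f$foot + injection_depth_um * f$inward
  if (point_depth(injection, surface_polyline) <= 0)
    stop("injection site lies outside the tissue")

  set.seed(seed)
  kept <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(kept) < n_cells) {
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed to fill the network")
    m <- max(n_cells - nrow(kept), 16L)
    draw <- cbind(stats::rnorm(2 * m, injection[1], sigma_ml),
                  stats::rnorm(2 * m, injection[2], sigma_dv))
    inside <- apply(draw, 1, point_depth, poly = surface_polyline) > 0
    kept <- rbind(kept, draw[inside, , drop = FALSE])
  }
  cells <- kept[seq_len(n_cells), , drop = FALSE]

  net <- coupling_network(injection, cells, surface_polyline,
                          hemisphere = hemisphere)
  list(network = net,
       truth = list(sigma_ml = sigma_ml, sigma_dv = sigma_dv,
                    injection_depth_um = injection_depth_um,
                    n_cells = n_cells, seed = as.integer(seed)))
}
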