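#' Registered per-animal map stack
#'
#' Container for maps of several animals brought into a common pixel frame:
#' a height x width x n_animals stack of map values (visual-field position or
#' preferred orientation, in degrees), response magnitudes and validity
#' masks. The angular period of the values (the visual-field span for
#' retinotopy, 180 for orientation) determines how values are averaged and
#' converted to angles for the reproducibility test.
#'
#' @param value_deg,magnitude numeric arrays, height x width x n.
#' @param valid logical array of the same shape.
#' @param period_deg angular period of the values in degrees.
#' @param kind `"retinotopy"` or `"orientation"`.
#' @return an object of class `group_map_set`.
#' @export
group_map_set <- function(value_deg, magnitude, valid, period_deg,
                          kind = c("retinotopy", "orientation")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(value_deg)) == 3,
            all(dim(value_deg) == dim(magnitude)),
            all(dim(value_deg) == dim(valid)), period_deg > 0)
  structure(list(value_deg = value_deg, magnitude = magnitude,
                 valid = valid, period_deg = period_deg, kind = kind,
                 p_map = NULL, significance_mask = NULL,
                 border_mask = NULL, alpha = NA_real_),
            class = "group_map_set")
}

#' Pixel-wise circular average of registered maps
#'
#' Magnitude-weighted circular mean of the per-animal map values at each
#' pixel, on the circle whose period is the group's `period_deg`. A pixel is
#' valid in the average when at least two animals contribute and the
#' resultant does not vanish (antipodal contributions are flagged invalid).
#'
#' @param group a [group_map_set()].
#' @return list with `value_deg`, `magnitude` (mean over contributing
#'   animals), `n_contrib` and `valid`.
#' @export
average_registered_maps <- function(group) {
  stopifnot(inherits(group, "group_map_set"))
  d <- dim(group$value_deg)
  ang <- group$value_deg * 2 * pi / group$period_deg
  w <- group$magnitude * group$valid
  z <- apply(w * exp(1i * ang), c(1, 2), sum)
  wsum <- apply(w, c(1, 2), sum)
  n_contrib <- apply(group$valid, c(1, 2), sum)
  degenerate <- Mod(z) < 1e-9 * pmax(wsum, 1e-300)
  value <- wrap_period(Arg(z)) * group$period_deg / (2 * pi)
  value[degenerate] <- 0
  valid <- n_contrib >= 2 & !degenerate & wsum > 0
  value[!valid] <- 0
  list(value_deg = value,
       magnitude = ifelse(n_contrib > 0, wsum / pmax(n_contrib, 1), 0),
       n_contrib = n_contrib, valid = valid)
}

# Moore-Rayleigh statistic per pixel for an n x P matrix of angles and
# magnitudes; returns the statistic and the rank matrix
mr_stat_matrix <- function(angles, magnitudes) {
  n <- nrow(angles)
  ranks <- apply(magnitudes, 2, rank)
  s <- sqrt(colSums(ranks * cos(angles))^2 +
            colSums(ranks * sin(angles))^2) / n^1.5
  list(stat = s, ranks = ranks)
}

#' Pixel-wise Moore-Rayleigh test on angle/magnitude samples
#'
#' Low-level vectorized form of the reproducibility test: column `j` of
#' `angles`/`magnitudes` is one pixel's cross-animal sample. Monte-Carlo
#' p-values share cached null tables per rank multiset.
#'
#' @param angles n x P matrix of angles (radians).
#' @param magnitudes n x P matrix of non-negative weights.
#' @param n_mc,seed Monte-Carlo null parameters
#'   (see [moore_rayleigh_pvalue()]).
#' @return list with vectors `stat` and `p` of length P.
#' @export
moore_rayleigh_test_map <- function(angles, magnitudes, n_mc = 100000L,
                                    seed = 20240713L) {
  stopifnot(is.matrix(angles), all(dim(angles) == dim(magnitudes)))
  n <- nrow(angles)
  if (n < 2) stop("need at least 2 animals")
  ms <- mr_stat_matrix(angles, magnitudes)
  p <- rep(NA_real_, ncol(angles))
  keys <- apply(round(ms$ranks, 6), 2, paste, collapse = "|")
  for (k in unique(keys)) {
    j <- keys == k
    p[j] <- moore_rayleigh_pvalue(ms$stat[j], n, n_mc, seed,
                                  ranks = ms$ranks[, which(j)[1]])
  }
  list(stat = ms$stat, p = p)
}

#' Pixel-wise reproducibility of registered maps across animals
#'
#' At every pixel the per-animal (map value, magnitude) tuples form a sample
#' of weighted vectors; map values are converted to angles on the group's
#' period (orientations are thereby angle-doubled onto the full circle) and
#' the Moore-Rayleigh test asks whether the animals agree on a common
#' direction. No multiple-testing correction is applied, mirroring the
#' per-pixel p < alpha convention; pixels where any animal is invalid get
#' `p = NA`.
#'
#' @param group a [group_map_set()].
#' @param alpha per-pixel significance level (default 0.05).
#' @param border_mask optional logical matrix restricting the test to the
#'   imaged structure; defaults to all pixels.
#' @param n_mc,seed Monte-Carlo null parameters.
#' @return the `group_map_set` with `p_map`, `significance_mask`
#'   (`p < alpha` within the border), `border_mask` and `alpha` filled in.
#' @export
pixelwise_reproducibility <- function(group, alpha = 0.05,
                                      border_mask = NULL, n_mc = 100000L,
                                      seed = 20240713L) {
  stopifnot(inherits(group, "group_map_set"), alpha > 0, alpha < 1)
  d <- dim(group$value_deg)
  n <- d[3]
  if (n < 2) stop("need at least 2 animals")
  if (is.null(border_mask)) border_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(all(dim(border_mask) == d[1:2]))

  px_all_valid <- apply(group$valid, c(1, 2), all)
  sel <- which(px_all_valid & border_mask)
  p_map <- matrix(NA_real_, d[1], d[2])
  if (length(sel)) {
    ang <- matrix(aperm(group$value_deg, c(3, 1, 2)), nrow = n)[, sel,
                                                                drop = FALSE]
    ang <- ang * 2 * pi / group$period_deg
    mag <- matrix(aperm(group$magnitude, c(3, 1, 2)), nrow = n)[, sel,
                                                                drop = FALSE]
    res <- moore_rayleigh_test_map(ang, mag, n_mc, seed)
    p_map[sel] <- res$p
  }
  group$p_map <- p_map
  group$alpha <- alpha
  group$border_mask <- border_mask
  sig <- !is.na(p_map) & p_map < alpha & border_mask
  group$significance_mask <- sig
  group
}

#' Area fraction of reproducible ("selective") domains
#'
#' Fraction of structure pixels whose map is statistically reproducible
#' across animals, and the corresponding tissue area given the camera pixel
#' pitch.
#'
#' @param group a [group_map_set()] with a computed significance mask.
#' @param pixel_pitch_um camera resolution (default 10.5 um/pixel).
#' @return list with `fraction`, `n_significant`, `n_border`, `area_mm2`.
#' @export
selective_domain_fraction <- function(group, pixel_pitch_um = 10.5) {
  stopifnot(inherits(group, "group_map_set"))
  if (is.null(group$significance_mask))
    stop("run pixelwise_reproducibility() first")
  border <- group$border_mask
  n_border <- sum(border)
  n_sig <- sum(group$significance_mask)
  list(fraction = if (n_border > 0) n_sig / n_border else NA_real_,
       n_significant = n_sig, n_border = n_border,
       area_mm2 = n_sig * (pixel_pitch_um / 1000)^2)
}

#' Visual-field locations selectively represented in the structure
#'
#' Pixels significant for both azimuth and elevation contribute their
#' averaged (azimuth, elevation) coordinate; the visual field is partitioned
#' into square cells (default 5 x 5 degrees) and the coverage is the set of
#' occupied cells and their total area.
#'
#' @param azimuth_group,elevation_group [group_map_set()]s with computed
#'   significance masks, registered on the same pixel grid.
#' @param cell_deg grid cell size in degrees.
#' @return list with `grid` (logical occupancy matrix, elevation x azimuth),
#'   `area_deg2`, `n_cells`, `cell_deg` and the contributing `points`
#'   (data frame of azimuth/elevation degrees).
#' @export
visual_field_coverage <- function(azimuth_group, elevation_group,
                                  cell_deg = 5) {
  stopifnot(inherits(azimuth_group, "group_map_set"),
            inherits(elevation_group, "group_map_set"))
  if (is.null(azimuth_group$significance_mask) ||
      is.null(elevation_group$significance_mask))
    stop("run pixelwise_reproducibility() on both groups first")
  if (!all(dim(azimuth_group$value_deg)[1:2] ==
           dim(elevation_group$value_deg)[1:2]))
    stop("groups are not on the same pixel grid")
  span_az <- azimuth_group$period_deg
  span_el <- elevation_group$period_deg
  both <- azimuth_group$significance_mask & elevation_group$significance_mask
  avg_az <- average_registered_maps(azimuth_group)
  avg_el <- average_registered_maps(elevation_group)
  both <- both & avg_az$valid & avg_el$valid
  nx <- ceiling(span_az / cell_deg)
  ny <- ceiling(span_el / cell_deg)
  grid <- matrix(FALSE, ny, nx)
  pts <- data.frame(azimuth_deg = avg_az$value_deg[both],
                    elevation_deg = avg_el$value_deg[both])
  if (nrow(pts)) {
    ix <- pmin(pmax(floor(pts$azimuth_deg / cell_deg) + 1, 1), nx)
    iy <- pmin(pmax(floor(pts$elevation_deg / cell_deg) + 1, 1), ny)
    grid[cbind(iy, ix)] <- TRUE
  }
  list(grid = grid, area_deg2 = sum(grid) * cell_deg^2,
       n_cells = sum(grid), cell_deg = cell_deg, points = pts)
}

#' Detect the imaged structure's border from response magnitude
#'
#' The structure (superior colliculus or visual cortex) is taken to be the
#' largest connected component of pixels whose average response magnitude
#' exceeds a fraction of the maximum, morphologically closed to fill small
#' gaps.
#'
#' @param magnitude mean magnitude matrix (e.g. from
#'   [average_registered_maps()]).
#' @param threshold_frac threshold as a fraction of the maximum magnitude
#'   (default 0.5).
#' @param brush_px diameter of the closing brush (default 5 px).
#' @return logical border mask. An all-zero magnitude yields an empty mask
#'   with a warning.
#' @export
detect_structure_border <- function(magnitude, threshold_frac = 0.5,
                                    brush_px = 5) {
  stopifnot(is.matrix(magnitude), threshold_frac > 0, threshold_frac <= 1)
  mx <- max(magnitude)
  if (mx <= 0) {
    warning("all-zero magnitude: empty border mask")
    return(matrix(FALSE, nrow(magnitude), ncol(magnitude)))
  }
  mask <- magnitude > threshold_frac * mx
  if (!any(mask))
    return(matrix(FALSE, nrow(magnitude), ncol(magnitude)))
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  closed <- EBImage::closing(keep * 1, EBImage::makeBrush(brush_px, "disc"))
  closed > 0.5
}
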