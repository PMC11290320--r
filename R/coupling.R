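#' Dye-coupling network container
#'
#' Coordinates of a biocytin-filled astroglial network in a coronal slice.
#' The coordinate frame is in micrometers with x running medio-laterally and
#' y increasing ventrally (downward, away from the tissue surface). The
#' surface polyline must be ordered so that its inward normal -- the segment
#' tangent rotated by +90 degrees, `(x, y) -> (-y, x)` -- points into the
#' tissue; for a flat surface at y = 0 listed left-to-right this is (0, 1).
#'
#' @param injection_xy length-2 numeric, injection-site coordinates (um).
#' @param cells_xy n x 2 matrix of cell coordinates (um), n >= 1. By
#'   convention the table includes the injected (patched) cell.
#' @param surface_polyline m x 2 matrix of ordered surface points (um).
#' @param layer_border_polyline optional m x 2 matrix (border between
#'   superficial and intermediate layers).
#' @param hemisphere `"left"` or `"right"`; fixes the sign of the medial
#'   direction (medial = surface tangent for the left hemisphere, its
#'   opposite for the right).
#' @return an object of class `coupling_network`.
#' @export
coupling_network <- function(injection_xy, cells_xy, surface_polyline,
                             layer_border_polyline = NULL,
                             hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  cells_xy <- matrix(as.numeric(cells_xy), ncol = 2)
  surface_polyline <- matrix(as.numeric(surface_polyline), ncol = 2)
  stopifnot(length(injection_xy) == 2, nrow(cells_xy) >= 1,
            nrow(surface_polyline) >= 2)
  structure(list(injection_xy = as.numeric(injection_xy),
                 cells_xy = cells_xy,
                 surface_polyline = surface_polyline,
                 layer_border_polyline = layer_border_polyline,
                 hemisphere = hemisphere),
            class = "coupling_network")
}

# nearest point on a polyline: returns foot point, inward unit normal and
# unit tangent of the nearest segment
polyline_foot <- function(p, poly) {
  n_seg <- nrow(poly) - 1
  best <- list(d2 = Inf)
  for (i in seq_len(n_seg)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- max(0, min(1, sum((p - a) * ab) / len2))
    foot <- a + t * ab
    d2 <- sum((p - foot)^2)
    if (d2 < best$d2) {
      tang <- ab / sqrt(len2)
      best <- list(d2 = d2, foot = foot, tangent = tang,
                   inward = c(-tang[2], tang[1]))
    }
  }
  if (!is.finite(best$d2)) stop("degenerate surface polyline")
  best
}

# signed depth of a point below the surface (positive inside the tissue)
point_depth <- function(p, poly) {
  f <- polyline_foot(p, poly)
  sign(sum((p - f$foot) * f$inward)) * sqrt(f$d2)
}

# dorsal / medial unit axes at the injection site
network_axes <- function(network) {
  f <- polyline_foot(network$injection_xy, network$surface_polyline)
  dorsal <- -f$inward                       # toward the tissue surface
  medial <- if (network$hemisphere == "left") f$tangent else -f$tangent
  list(dorsal = dorsal, medial = medial)
}

#' Directional extents of a dye-coupling network
#'
#' Projects every coupled cell onto the dorsal, ventral, medial and lateral
#' unit axes anchored at the injection site (dorsal = direction from the
#' injection site toward its foot point on the surface polyline; medial =
#' surface tangent, signed by the hemisphere flag) and summarizes the
#' positive projections per direction with the chosen statistic. Cells lying
#' on the opposite side contribute nothing to a direction; a direction with
#' no cells has extent 0.
#'
#' @param network a [coupling_network()].
#' @param statistic `"median"` (network spread) or `"max"` (maximal extent).
#' @return an object of class `directional_extents`: list with `dorsal`,
#'   `ventral`, `medial`, `lateral` (um), `statistic`, `n_cells` and
#'   `injection_depth_um`.
#' @export
directional_extents <- function(network, statistic = c("median", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(network, "coupling_network"))
  if (nrow(network$cells_xy) < 1) stop("network has no cells")
  ax <- network_axes(network)
  rel <- sweep(network$cells_xy, 2, network$injection_xy)
  stat_fun <- if (statistic == "median") stats::median else max
  one <- function(axis) {
    p <- as.vector(rel %*% axis)
    p <- p[p > 0]
    if (!length(p)) 0 else stat_fun(p)
  }
  structure(list(dorsal = one(ax$dorsal), ventral = one(-ax$dorsal),
                 medial = one(ax$medial), lateral = one(-ax$medial),
                 statistic = statistic, n_cells = nrow(network$cells_xy),
                 injection_depth_um =
                   point_depth(network$injection_xy,
                               network$surface_polyline)),
            class = "directional_extents")
}

#' Isotropy ratio between two directional extents
#'
#' `ratio = extent_a / (extent_a + extent_b)`; 0.5 indicates isotropy between
#' the two directions. The default pair (dorsal vs lateral) follows the
#' extent comparison used for small networks; any pair can be requested.
#'
#' @param extents a [directional_extents()].
#' @param dir_a,dir_b direction names among
#'   `c("dorsal", "ventral", "medial", "lateral")`.
#' @return ratio in `[0, 1]`.
#' @export
directional_ratio <- function(extents, dir_a = "dorsal", dir_b = "lateral") {
  stopifnot(inherits(extents, "directional_extents"),
            dir_a %in% c("dorsal", "ventral", "medial", "lateral"),
            dir_b %in% c("dorsal", "ventral", "medial", "lateral"))
  a <- extents[[dir_a]]; b <- extents[[dir_b]]
  if (a + b <= 0) stop("both extents are zero")
  a / (a + b)
}

#' Ordinary least-squares regression of coupling extent on injection depth
#'
#' Fits `extent ~ depth` by OLS and reports the slope, intercept, R squared,
#' the F statistic on (1, n - 2) degrees of freedom and its two-sided
#' p-value.
#'
#' @param depth_um injection-site distances from the surface (um), >= 3
#'   values with nonzero variance.
#' @param extent_um coupling extents (um), same length.
#' @return an object of class `extent_regression`: list with `slope`,
#'   `intercept`, `R_squared`, `F_statistic`, `df`, `p_value`, `n`.
#' @export
extent_vs_depth_regression <- function(depth_um, extent_um) {
  n <- length(depth_um)
  stopifnot(length(extent_um) == n)
  if (n < 3) stop("need at least 3 points")
  if (stats::var(depth_um) == 0) stop("zero variance in depth")
  fit <- stats::lm(extent_um ~ depth_um)
  ss_tot <- sum((extent_um - mean(extent_um))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  df2 <- n - 2
  Fst <- if (r2 >= 1) Inf else r2 / (1 - r2) * df2
  p <- if (!is.finite(Fst)) 0 else stats::pf(Fst, 1, df2, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 R_squared = r2, F_statistic = Fst, df = c(1, df2),
                 p_value = p, n = n),
            class = "extent_regression")
}

#' Number of coupled cells in a network
#'
#' @param network a [coupling_network()].
#' @param exclude_injected drop the injected (patched) cell from the count
#'   (default `TRUE`), matching the convention that network size counts cells
#'   the tracer spread *into*.
#' @return integer count.
#' @export
count_coupled_cells <- function(network, exclude_injected = TRUE) {
  stopifnot(inherits(network, "coupling_network"))
  n <- nrow(network$cells_xy)
  if (exclude_injected) max(0L, n - 1L) else n
}
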