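## Rigid registration of functional maps across animals.
##
## A transform (angle, dx, dy) acts on image coordinates (col = x, row = y,
## row 1 at the top) as rotate-about-center followed by translation; maps are
## resampled by bilinear interpolation, circular quantities through their
## cosine/sine. The registration objective is the mean circular squared
## error 1 - cos(delta_phi), averaged over the azimuth and elevation phase
## maps on the overlap of the two validity masks; shifts are searched by FFT
## cross-correlation of the cosine/sine fields and the rotation by grid
## search plus local refinement.

#' Resample a scalar or circular field under a rigid transform
#'
#' Output pixel (row, col) takes the value of the input at the source
#' location obtained by undoing the transform (rotation by `angle_deg` about
#' the image center, then translation by `dx, dy` pixels in column/row
#' direction). Bilinear interpolation; pixels mapping outside the input are
#' `NA`. Circular fields are interpolated via cosine and sine.
#'
#' @param field numeric matrix (may contain `NA`s, which propagate).
#' @param angle_deg rotation in degrees (positive rotates image content from
#'   the x toward the y axis, i.e. visually clockwise with row 1 on top).
#' @param dx,dy translation in pixels (columns, rows); may be fractional.
#' @param circular interpolate on the circle of the given `period`.
#' @param period angular period for circular interpolation.
#' @return the resampled matrix.
#' @export
apply_rigid_field <- function(field, angle_deg, dx = 0, dy = 0,
                              circular = FALSE, period = 2 * pi) {
  h <- nrow(field); w <- ncol(field)
  th <- -angle_deg * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xo <- rep(seq_len(w), each = h) - dx - cx
  yo <- rep(seq_len(h), times = w) - dy - cy
  xs <- cos(th) * xo - sin(th) * yo + cx
  ys <- sin(th) * xo + cos(th) * yo + cy

  inside <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  # clamp so that exact-integer coordinates on the far edge stay usable
  x0c <- pmin(pmax(floor(xs), 1), w - 1)
  y0c <- pmin(pmax(floor(ys), 1), h - 1)
  fx <- xs - x0c; fy <- ys - y0c
  bil <- function(f) {
    v <- (1 - fx) * (1 - fy) * f[cbind(y0c, x0c)] +
         fx * (1 - fy) * f[cbind(y0c, x0c + 1)] +
         (1 - fx) * fy * f[cbind(y0c + 1, x0c)] +
         fx * fy * f[cbind(y0c + 1, x0c + 1)]
    v[!inside] <- NA_real_
    matrix(v, h, w)
  }
  if (!circular) return(bil(field))
  ang <- field * 2 * pi / period
  co <- bil(cos(ang)); si <- bil(sin(ang))
  # bilinear weights applied to cos/sin; renormalized by taking the argument
  out <- wrap_period(atan2(si, co)) * period / (2 * pi)
  out[is.na(co) | is.na(si)] <- NA_real_
  matrix(out, h, w)
}

# --- internal field representation for the registration objective ---------

# a retinotopy pair as cos/sin phase fields (zero-filled outside the mask)
pair_fields <- function(az, el) {
  pa <- az$position_deg * 2 * pi / az$span_deg
  pe <- el$position_deg * 2 * pi / el$span_deg
  m <- (az$valid_mask & el$valid_mask) * 1
  list(caz = cos(pa) * m, saz = sin(pa) * m,
       cel = cos(pe) * m, sel = sin(pe) * m, mask = m)
}

rotate_fields <- function(fl, angle_deg) {
  out <- lapply(fl, function(f) {
    g <- apply_rigid_field(f, angle_deg)
    g[is.na(g)] <- 0
    g
  })
  # keep the mask crisp: a pixel is valid only if fully interpolated from
  # valid pixels
  out$mask <- (out$mask > 0.999) * 1
  for (nm in c("caz", "saz", "cel", "sel")) out[[nm]] <- out[[nm]] * out$mask
  out
}

pad_fft <- function(m, P) {
  z <- matrix(0, P, P)
  z[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  stats::fft(z)
}

# mean cosine similarity over shifts: returns the (2S+1)^2 grid of
# mean cos(delta_phi) and of overlap counts, for mov shifted by (dy, dx)
shift_similarity <- function(ref_ffts, mov, P, max_shift) {
  corr <- function(nm) {
    H <- ref_ffts[[nm]] * Conj(pad_fft(mov[[nm]], P))
    Re(stats::fft(H, inverse = TRUE)) / P^2
  }
  S <- corr("caz") + corr("saz") + corr("cel") + corr("sel")
  N <- corr("mask")
  lag <- ((-max_shift):max_shift) %% P + 1
  list(meancos = S[lag, lag] / (2 * pmax(N[lag, lag], 1e-9)),
       overlap = N[lag, lag])
}

best_shift_for_angle <- function(ref_ffts, fl, angle, P, max_shift,
                                 min_overlap_px) {
  mov <- rotate_fields(fl, angle)
  ss <- shift_similarity(ref_ffts, mov, P, max_shift)
  ok <- ss$overlap >= min_overlap_px
  if (!any(ok)) return(list(obj = Inf, dx = 0, dy = 0))
  mc <- ss$meancos
  mc[!ok] <- -Inf
  i <- arrayInd(which.max(mc), dim(mc))
  dy <- i[1] - (max_shift + 1); dx <- i[2] - (max_shift + 1)
  # parabolic sub-pixel refinement of the similarity peak
  sub <- function(km, k0, kp) {
    den <- km - 2 * k0 + kp
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (km - kp) / den))
  }
  ddx <- ddy <- 0
  if (i[1] > 1 && i[1] < nrow(mc) && all(is.finite(mc[i[1] + c(-1, 1), i[2]])))
    ddy <- sub(mc[i[1] - 1, i[2]], mc[i[1], i[2]], mc[i[1] + 1, i[2]])
  if (i[2] > 1 && i[2] < ncol(mc) && all(is.finite(mc[i[1], i[2] + c(-1, 1)])))
    ddx <- sub(mc[i[1], i[2] - 1], mc[i[1], i[2]], mc[i[1], i[2] + 1])
  list(obj = 1 - mc[i[1], i[2]], dx = dx + ddx, dy = dy + ddy)
}

register_one <- function(ref_ffts, fl, P, rot_range, rot_step, max_shift,
                         min_overlap_px) {
  angles <- seq(-rot_range, rot_range, by = rot_step)
  res <- lapply(angles, best_shift_for_angle, ref_ffts = ref_ffts, fl = fl,
                P = P, max_shift = max_shift,
                min_overlap_px = min_overlap_px)
  objs <- vapply(res, `[[`, numeric(1), "obj")
  if (!any(is.finite(objs))) stop("empty overlap after transform")
  k <- which.min(objs)
  # local refinement of the rotation angle
  f <- function(a) best_shift_for_angle(ref_ffts, fl, a, P, max_shift,
                                        min_overlap_px)$obj
  lo <- max(-rot_range, angles[k] - rot_step)
  hi <- min(rot_range, angles[k] + rot_step)
  opt <- stats::optimize(f, c(lo, hi), tol = 0.02)
  best_a <- if (opt$objective < objs[k]) opt$minimum else angles[k]
  fin <- best_shift_for_angle(ref_ffts, fl, best_a, P, max_shift,
                              min_overlap_px)
  list(angle_deg = best_a, dx = fin$dx, dy = fin$dy, objective = fin$obj)
}

apply_rigid_retmap <- function(map, tr) {
  pos <- apply_rigid_field(map$position_deg, tr$angle_deg, tr$dx, tr$dy,
                           circular = TRUE, period = map$span_deg)
  mag <- apply_rigid_field(map$magnitude, tr$angle_deg, tr$dx, tr$dy)
  msk <- apply_rigid_field(map$valid_mask * 1, tr$angle_deg, tr$dx, tr$dy)
  valid <- !is.na(msk) & msk > 0.999 & !is.na(pos)
  pos[!valid] <- 0; mag[!valid] <- 0; mag[is.na(mag)] <- 0
  retinotopic_map(pos, map$axis, map$span_deg, mag,
                  map$delay_estimate_s, valid)
}

#' Register retinotopic map pairs across animals
#'
#' Finds, for every animal, the rigid transform (rotation plus shift) that
#' minimizes the summed squared circular error of the azimuth and elevation
#' position maps against a reference: the first animal on the first pass,
#' then the pixel-wise circular mean of the registered maps. The search is a
#' coarse rotation grid (default +/-15 degrees in 0.5-degree steps) with
#' FFT-based shift search (default +/-20 px) and local refinement; the
#' reported objective is the mean of `1 - cos(delta_phi)` over the overlap
#' and is non-increasing across passes (a pass that would increase the mean
#' objective is discarded).
#'
#' @param maps list with one entry per animal, each a list with `azimuth` and
#'   `elevation` [retinotopic_map()]s on a shared pixel grid. At least 2
#'   animals.
#' @param rot_range_deg,rot_step_deg rotation search range and grid step.
#' @param max_shift_px shift search range.
#' @param n_iter number of reference-refinement passes (default 2).
#' @param min_overlap_frac minimum overlap, as a fraction of the smaller
#'   validity mask, for a transform to be admissible.
#' @return an object of class `registered_group`: list with `azimuth` and
#'   `elevation` [group_map_set()]s, a `transforms` data frame (angle_deg,
#'   dx_px, dy_px, objective per animal) and `objective_trace` (mean
#'   objective per pass).
#' @export
register_group <- function(maps, rot_range_deg = 15, rot_step_deg = 0.5,
                           max_shift_px = 20, n_iter = 2,
                           min_overlap_frac = 0.25) {
  n <- length(maps)
  if (n < 2) stop("need at least 2 animals")
  dims <- dim(maps[[1]]$azimuth$position_deg)
  for (m in maps)
    if (!all(dim(m$azimuth$position_deg) == dims) ||
        !all(dim(m$elevation$position_deg) == dims))
      stop("maps must share geometry")
  P <- 2^ceiling(log2(max(dims) + 2 * max_shift_px + 1))
  fls <- lapply(maps, function(m) pair_fields(m$azimuth, m$elevation))

  ref_fields <- fls[[1]]
  prev_mean_obj <- Inf
  best <- NULL
  for (it in seq_len(n_iter)) {
    ref_ffts <- lapply(ref_fields, pad_fft, P = P)
    min_px <- min_overlap_frac * sum(ref_fields$mask)
    trs <- lapply(fls, function(fl)
      register_one(ref_ffts, fl, P, rot_range_deg, rot_step_deg,
                   max_shift_px, max(min_px, 4)))
    mean_obj <- mean(vapply(trs, `[[`, numeric(1), "objective"))
    if (mean_obj > prev_mean_obj + 1e-12) break   # keep the better pass
    best <- list(trs = trs, mean_obj = mean_obj, it = it)
    prev_mean_obj <- mean_obj
    if (it < n_iter) {
      # reference for the next pass: circular mean of the registered fields
      reg <- lapply(seq_len(n), function(k) {
        tr <- trs[[k]]
        rot <- rotate_fields(fls[[k]], tr$angle_deg)
        lapply(rot, function(f)
          apply_rigid_field(f, 0, tr$dx, tr$dy))
      })
      acc <- function(nm) Reduce(`+`, lapply(reg, function(r) {
        f <- r[[nm]]; f[is.na(f)] <- 0; f
      }))
      cnt <- acc("mask")
      m <- (cnt >= 2) * 1
      nrm <- function(cf, sf) {
        md <- sqrt(cf^2 + sf^2)
        list(c = ifelse(md > 0, cf / md, 0) * m,
             s = ifelse(md > 0, sf / md, 0) * m)
      }
      az <- nrm(acc("caz"), acc("saz"))
      el <- nrm(acc("cel"), acc("sel"))
      ref_fields <- list(caz = az$c, saz = az$s, cel = el$c, sel = el$s,
                         mask = m)
    }
  }
  trs <- best$trs
  reg_az <- lapply(seq_len(n), function(k)
    apply_rigid_retmap(maps[[k]]$azimuth, trs[[k]]))
  reg_el <- lapply(seq_len(n), function(k)
    apply_rigid_retmap(maps[[k]]$elevation, trs[[k]]))
  tdf <- data.frame(animal = seq_len(n),
                    angle_deg = vapply(trs, `[[`, numeric(1), "angle_deg"),
                    dx_px = vapply(trs, `[[`, numeric(1), "dx"),
                    dy_px = vapply(trs, `[[`, numeric(1), "dy"),
                    objective = vapply(trs, `[[`, numeric(1), "objective"))
  structure(list(
    azimuth = group_map_set(
      value_deg = simplify2array(lapply(reg_az, `[[`, "position_deg")),
      magnitude = simplify2array(lapply(reg_az, `[[`, "magnitude")),
      valid = simplify2array(lapply(reg_az, `[[`, "valid_mask")),
      period_deg = maps[[1]]$azimuth$span_deg, kind = "retinotopy"),
    elevation = group_map_set(
      value_deg = simplify2array(lapply(reg_el, `[[`, "position_deg")),
      magnitude = simplify2array(lapply(reg_el, `[[`, "magnitude")),
      valid = simplify2array(lapply(reg_el, `[[`, "valid_mask")),
      period_deg = maps[[1]]$elevation$span_deg, kind = "retinotopy"),
    transforms = tdf,
    objective_trace = prev_mean_obj),
    class = "registered_group")
}

#' Apply registration transforms to per-animal orientation maps
#'
#' Orientation sessions are recorded in the same coordinate frame as the
#' retinotopy sessions of the same animal, so the transforms estimated from
#' retinotopy are reused to bring orientation maps into the common frame.
#'
#' @param maps list of [orientation_map()]s, one per animal.
#' @param transforms the `transforms` data frame of a [register_group()]
#'   result.
#' @return a [group_map_set()] with `period_deg = 180`.
#' @export
apply_transforms <- function(maps, transforms) {
  stopifnot(length(maps) == nrow(transforms))
  reg <- lapply(seq_along(maps), function(k) {
    tr <- list(angle_deg = transforms$angle_deg[k],
               dx = transforms$dx_px[k], dy = transforms$dy_px[k])
    ori <- apply_rigid_field(maps[[k]]$orientation_deg, tr$angle_deg,
                             tr$dx, tr$dy, circular = TRUE, period = 180)
    mag <- apply_rigid_field(maps[[k]]$magnitude, tr$angle_deg, tr$dx, tr$dy)
    msk <- apply_rigid_field(maps[[k]]$valid_mask * 1, tr$angle_deg,
                             tr$dx, tr$dy)
    valid <- !is.na(msk) & msk > 0.999 & !is.na(ori)
    ori[!valid] <- 0; mag[!valid] <- 0; mag[is.na(mag)] <- 0
    list(o = ori, m = mag, v = valid)
  })
  group_map_set(value_deg = simplify2array(lapply(reg, `[[`, "o")),
                magnitude = simplify2array(lapply(reg, `[[`, "m")),
                valid = simplify2array(lapply(reg, `[[`, "v")),
                period_deg = 180, kind = "orientation")
}
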