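## File formats. All writers use plain-text or standard image containers:
## movies as multi-page 32-bit float TIFF with a JSON sidecar, maps as TSV +
## JSON + PNG preview, cell tables and pose tables as CSV. Image coordinates
## follow the package convention: row 1 is the top of the frame, x runs
## rightward. Anatomical orientation is supplied via configuration, never
## inferred from the data.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an imaging movie as a multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages. The TIFF library clamps
#' values outside `[0, 1]`, so intensities are affinely rescaled into that
#' range; the scale, frame rate and protocol are stored in a JSON sidecar
#' (`<path>.json`) and undone on read. The round trip is exact to 32-bit
#' float precision.
#'
#' @param movie an [oi_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "oi_movie"))
  d <- dim(movie$data)
  lo <- min(movie$data); hi <- max(movie$data)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(d[1]), function(i)
    (movie$data[i, , ] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(offset = lo, scale = scale, frame_rate_hz = movie$frame_rate_hz,
               n_frames = d[1], height = d[2], width = d[3])
  if (!is.null(movie$protocol))
    meta$protocol <- unclass(movie$protocol)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param path TIFF path written by [write_movie()] (the JSON sidecar must
#'   sit next to it).
#' @return for `read_movie`, the reconstructed [oi_movie()].
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such movie file: %s", path))
  if (!file.exists(sidecar_path(path)))
    stop(sprintf("missing movie sidecar: %s", sidecar_path(path)))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop(sprintf("cannot read TIFF '%s': %s", path,
                                    conditionMessage(e))))
  if (length(frames) != meta$n_frames)
    stop("corrupt movie: frame count does not match sidecar")
  arr <- array(0, c(meta$n_frames, meta$height, meta$width))
  for (i in seq_along(frames))
    arr[i, , ] <- frames[[i]] * meta$scale + meta$offset
  protocol <- NULL
  if (!is.null(meta$protocol)) {
    keep <- intersect(names(meta$protocol), names(formals(stim_protocol)))
    protocol <- do.call(stim_protocol, meta$protocol[keep])
  }
  oi_movie(arr, meta$frame_rate_hz, protocol)
}

map_values <- function(map) {
  if (inherits(map, "retinotopic_map"))
    list(value = map$position_deg, period = map$span_deg, what = "position")
  else if (inherits(map, "orientation_map"))
    list(value = map$orientation_deg, period = 180, what = "orientation")
  else if (inherits(map, "phase_map"))
    list(value = map$phase, period = 2 * pi, what = "phase")
  else stop("unsupported map type")
}

#' Write a map as TSV matrices with a PNG preview
#'
#' Writes `<prefix>_<what>.tsv` (map values) and `<prefix>_magnitude.tsv`,
#' a JSON metadata file, and an 8-bit PNG preview in which hue encodes the
#' map value over its angular period and brightness the normalized
#' magnitude. Masked pixels are black.
#'
#' @param map a [retinotopic_map()], [orientation_map()] or [phase_map()].
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_maps <- function(map, prefix) {
  mv <- map_values(map)
  f_val <- sprintf("%s_%s.tsv", prefix, mv$what)
  f_mag <- sprintf("%s_magnitude.tsv", prefix)
  f_meta <- sprintf("%s_meta.json", prefix)
  f_png <- sprintf("%s_preview.png", prefix)
  utils::write.table(mv$value, f_val, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(map$magnitude, f_mag, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(what = mv$what, period = mv$period,
               delay_estimate_s = map$delay_estimate_s,
               class = class(map))
  if (inherits(map, "retinotopic_map")) {
    meta$axis <- map$axis
    meta$span_deg <- map$span_deg
  }
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
  png::writePNG(map_preview_rgb(map), f_png)
  invisible(c(values = f_val, magnitude = f_mag, meta = f_meta,
              preview = f_png))
}

#' HSV colormap preview of a map
#'
#' Hue encodes the map value over its angular period, brightness the
#' magnitude normalized to its maximum; invalid pixels are black.
#'
#' @param map a map object accepted by [write_maps()].
#' @return height x width x 3 RGB array in `[0, 1]`.
#' @export
map_preview_rgb <- function(map) {
  mv <- map_values(map)
  hue <- wrap_period(mv$value, mv$period) / mv$period
  mx <- max(map$magnitude)
  val <- if (mx > 0) map$magnitude / mx else map$magnitude * 0
  val[!map$valid_mask] <- 0
  cols <- grDevices::hsv(pmin(pmax(hue, 0), 1 - 1e-9), 1, val)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(nrow(hue), ncol(hue), 3))
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  out
}

#' Write / read a dye-coupling cell table
#'
#' Single CSV holding typed rows: `type` in `cell`, `injection`, `surface`,
#' `layer_border`; `id` (1-based within type); `x_um`, `y_um` in micrometers
#' with y increasing ventrally (downward from the tissue surface). A
#' `# hemisphere: <left|right>` comment line records the slice orientation.
#'
#' @param network a [coupling_network()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(network, path) {
  stopifnot(inherits(network, "coupling_network"))
  rows <- function(type, m) {
    if (is.null(m)) return(NULL)
    m <- matrix(m, ncol = 2)
    data.frame(type = type, id = seq_len(nrow(m)), x_um = m[, 1],
               y_um = m[, 2])
  }
  df <- rbind(rows("cell", network$cells_xy),
              rows("injection", matrix(network$injection_xy, 1)),
              rows("surface", network$surface_polyline),
              rows("layer_border", network$layer_border_polyline))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hemisphere: %s", network$hemisphere), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @return for `read_cells_csv`, the reconstructed [coupling_network()].
#' @export
read_cells_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such cell table: %s", path))
  first <- readLines(path, n = 1)
  hemisphere <- "left"
  if (startsWith(first, "# hemisphere:"))
    hemisphere <- trimws(sub("# hemisphere:", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("type", "id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("cell table must have columns type, id, x_um, y_um")
  pick <- function(type) {
    m <- df[df$type == type, c("x_um", "y_um")]
    if (!nrow(m)) return(NULL)
    as.matrix(m[order(df$id[df$type == type]), ])
  }
  inj <- pick("injection")
  if (is.null(inj)) stop("cell table has no injection site")
  cells <- pick("cell")
  if (is.null(cells)) stop("cell table has no cells")
  surface <- pick("surface")
  if (is.null(surface)) stop("cell table has no surface polyline")
  coupling_network(inj[1, ], cells, surface, pick("layer_border"),
                   hemisphere = hemisphere)
}

#' Write / read a pose-tracking table
#'
#' Pose-estimation CSV dialect with a three-row header (`scorer`,
#' `bodyparts`, `coords`) and per-body-part `x`, `y`, `likelihood` column
#' triples; the first column is the frame index. Frame rate, flash onsets
#' and the pixel scale live in a JSON sidecar (`<path>.json`).
#'
#' @param track a [pose_track()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  parts <- track_parts(track)
  scorer <- "collimap"
  h1 <- c("scorer", rep(scorer, 3 * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  body <- do.call(cbind, lapply(parts, function(p)
    cbind(track[[paste0(p, "_x")]], track[[paste0(p, "_y")]],
          track[[paste0(p, "_likelihood")]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  utils::write.table(cbind(seq_len(nrow(track)) - 1, body), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(frame_rate_hz = attr(track, "frame_rate_hz"),
               flash_onsets_s = attr(track, "flash_onsets_s"),
               px_per_cm = attr(track, "px_per_cm"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pose_csv
#' @param frame_rate_hz,flash_onsets_s,px_per_cm overrides used when no JSON
#'   sidecar sits next to the CSV.
#' @return for `read_pose_csv`, the reconstructed [pose_track()].
#' @export
read_pose_csv <- function(path, frame_rate_hz = 25,
                          flash_onsets_s = numeric(), px_per_cm = NULL) {
  if (!file.exists(path)) stop(sprintf("no such pose table: %s", path))
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3 || !startsWith(hdr[2], "bodyparts") ||
      !startsWith(hdr[3], "coords"))
    stop("not a pose-tracking CSV (expected scorer/bodyparts/coords header)")
  parts_row <- strsplit(hdr[2], ",")[[1]][-1]
  coords_row <- strsplit(hdr[3], ",")[[1]][-1]
  df <- utils::read.csv(path, skip = 3, header = FALSE)
  if (ncol(df) != length(parts_row) + 1)
    stop("pose CSV header and body disagree on column count")
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    frame_rate_hz <- meta$frame_rate_hz
    flash_onsets_s <- meta$flash_onsets_s
    px_per_cm <- meta$px_per_cm
  }
  out <- data.frame(time_s = df[[1]] / frame_rate_hz)
  for (j in seq_along(parts_row)) {
    suffix <- c(x = "_x", y = "_y", likelihood = "_likelihood")[
      coords_row[j]]
    out[[paste0(parts_row[j], suffix)]] <- df[[j + 1]]
  }
  pose_track(out, frame_rate_hz = frame_rate_hz,
             flash_onsets_s = flash_onsets_s, px_per_cm = px_per_cm)
}
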