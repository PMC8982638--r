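#' Locomotor activity summary
#'
#' Total distance traveled and mean speed from a calibrated track. Distance
#' is the sum of Euclidean steps between consecutive pairs of valid frames;
#' steps longer than `max_step_cm` (physically implausible between adjacent
#' frames, i.e. tracking glitches) are excluded from the sum and counted
#' separately. Mean speed is distance over the time spanned by the steps
#' actually used.
#'
#' @param track A [frame_track()].
#' @param px_per_cm Calibration from [calibrate()].
#' @param fps Frames per second (defaults to the track's).
#' @param max_step_cm Glitch threshold per frame-step (default 10 cm).
#' @return A list of class `activity_summary`: `distance_cm`,
#'   `mean_speed_cm_s`, `frames_used`, `steps_excluded`.
#' @export
compute_activity <- function(track, px_per_cm, fps = NULL, max_step_cm = 10) {
  fps <- fps %||% track_fps(track)
  stopifnot_scalar_pos(px_per_cm, "px_per_cm")
  if (sum(track$valid) < 2) stop("need at least 2 valid frames")
  n <- nrow(track)
  both <- track$valid[-n] & track$valid[-1]
  step_cm <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2) / px_per_cm
  use <- both & !is.na(step_cm) & step_cm <= max_step_cm
  distance <- sum(step_cm[use])
  frames_used <- sum(use)
  structure(list(
    distance_cm = distance,
    mean_speed_cm_s = if (frames_used > 0) distance / (frames_used / fps) else 0,
    frames_used = frames_used,
    steps_excluded = sum(both & !is.na(step_cm) & step_cm > max_step_cm)),
    class = "activity_summary")
}

#' Burying-topography occupancy heatmaps
#'
#' Bins the positions of all valid frames into a 2D grid over the arena,
#' split into two count grids by the per-frame label: one for burying
#' frames, one for every other valid frame. The two grids together conserve
#' the number of valid frames. Counts are stored raw; render on a
#' `log(1 + count)` scale for display.
#'
#' @param track A [frame_track()].
#' @param labels A [label_series()] aligned to the track.
#' @param arena An [arena_geometry()].
#' @param bin_size_px Square bin side in pixels (default 16).
#' @return A list of class `heatmap_pair`: matrices `burying` and
#'   `non_burying` (rows = y bins, cols = x bins), `bin_size_px`, `arena`.
#' @export
occupancy_heatmap <- function(track, labels, arena, bin_size_px = 16) {
  if (nrow(track) != nrow(labels)) stop("track and labels lengths differ")
  b <- arena_bounds_px(arena)
  nx <- max(1L, ceiling((b$x1 - b$x0) / bin_size_px))
  ny <- max(1L, ceiling((b$y1 - b$y0) / bin_size_px))
  bury <- matrix(0L, nrow = ny, ncol = nx)
  non <- matrix(0L, nrow = ny, ncol = nx)
  v <- which(track$valid)
  ix <- clamp(floor((track$x_px[v] - b$x0) / bin_size_px) + 1L, 1L, nx)
  iy <- clamp(floor((track$y_px[v] - b$y0) / bin_size_px) + 1L, 1L, ny)
  pos <- labels$label[v] == "positive"
  for (j in seq_along(v)) {
    if (pos[j]) bury[iy[j], ix[j]] <- bury[iy[j], ix[j]] + 1L
    else non[iy[j], ix[j]] <- non[iy[j], ix[j]] + 1L
  }
  structure(list(burying = bury, non_burying = non,
                 bin_size_px = bin_size_px, arena = arena),
            class = "heatmap_pair")
}

#' Fraction of time spent in the arena corners
#'
#' Corner zones are four squares of side `corner_frac * min(arena width,
#' height)` (in pixels) anchored at the arena corners; the statistic is the
#' fraction of valid frames whose centroid falls inside any of them — a
#' spatial-preference proxy for wall/corner-directed behavior.
#'
#' @param track A [frame_track()].
#' @param arena An [arena_geometry()].
#' @param corner_frac Zone side as a fraction of the smaller arena
#'   dimension (default 0.25).
#' @return Fraction in `[0, 1]`.
#' @export
corner_preference <- function(track, arena, corner_frac = 0.25) {
  if (corner_frac <= 0) return(0)
  b <- arena_bounds_px(arena)
  side <- corner_frac * min(b$x1 - b$x0, b$y1 - b$y0)
  x <- track$x_px[track$valid]; y <- track$y_px[track$valid]
  if (!length(x)) return(0)
  in_x <- (x <= b$x0 + side) | (x >= b$x1 - side)
  in_y <- (y <= b$y0 + side) | (y >= b$y1 - side)
  mean(in_x & in_y)
}

#' Render a heatmap pair to PNG
#'
#' Writes the two grids side by side on a `log(1 + count)` gray scale.
#'
#' @param hm A `heatmap_pair`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(hm, path) {
  render <- function(g) {
    z <- log1p(g)
    if (max(z) > 0) z <- z / max(z)
    z
  }
  img <- cbind(render(hm$non_burying), render(hm$burying))
  png::writePNG(img, path)
  invisible(path)
}
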