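# Shortest axial (mod pi) difference between two orientations.
axial_diff <- function(a, b) ((a - b + pi / 2) %% pi) - pi / 2

#' Per-frame kinematic features for burying classification
#'
#' Computes, for every frame of a track, the quantities whose short-time
#' statistics separate burying from locomotion: speed and acceleration
#' (central differences of the centroid), turn rate (axial derivative of
#' the body-ellipse orientation), ellipse area and aspect ratio, distance
#' to the nearest wall and nearest corner, and — when raw frames are
#' supplied — the mean absolute frame-to-frame intensity change in a disk
#' around the centroid (bedding being displaced moves pixels even when the
#' centroid does not). Invalid track frames yield `NA` rows.
#'
#' @param track A [frame_track()].
#' @param frames Optional `h x w x n` array of raw frames; when `NULL` the
#'   `local_pixel_change` column is omitted.
#' @param arena An [arena_geometry()] for wall/corner distances.
#' @return A data frame with one row per frame; attribute
#'   `has_pixel_change` records whether the video-based column is present.
#' @export
compute_frame_features <- function(track, frames = NULL, arena) {
  n <- nrow(track)
  fps <- track_fps(track)
  if (!any(track$valid)) stop("track has no valid frames")
  dt <- 1 / fps
  x <- track$x_px; y <- track$y_px; th <- track$theta_rad

  cdiff <- function(v) {          # central difference, one-sided at edges
    n <- length(v)
    if (n == 1) return(0 * v)
    d <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
    d / dt
  }
  vx <- cdiff(x); vy <- cdiff(y)
  speed <- sqrt(vx^2 + vy^2)
  ax <- cdiff(vx); ay <- cdiff(vy)
  accel <- sqrt(ax^2 + ay^2)
  if (n > 2) {
    dth <- c(axial_diff(th[2], th[1]),
             axial_diff(th[3:n], th[1:(n - 2)]) / 2,
             axial_diff(th[n], th[n - 1])) / dt
  } else dth <- rep(0, n)

  b <- arena_bounds_px(arena)
  wall <- pmin(x - b$x0, b$x1 - x, y - b$y0, b$y1 - y)
  cx <- c(b$x0, b$x1, b$x1, b$x0); cy <- c(b$y0, b$y0, b$y1, b$y1)
  corner <- do.call(pmin, lapply(1:4, function(k) sqrt((x - cx[k])^2 + (y - cy[k])^2)))

  feats <- data.frame(
    speed_px_s = speed,
    accel_px_s2 = accel,
    turn_rate_rad_s = abs(dth),
    ellipse_area_px2 = pi * (track$major_px / 2) * (track$minor_px / 2),
    ellipse_aspect = track$major_px / pmax(track$minor_px, 1e-9),
    dist_wall_px = wall,
    dist_corner_px = corner
  )
  if (!is.null(frames)) {
    r <- 0.6 * median(track$major_px, na.rm = TRUE)
    lpc <- rep(NA_real_, n)
    h <- dim(frames)[1]; w <- dim(frames)[2]
    for (i in seq_len(n)) {
      if (!track$valid[i]) next
      j <- if (i == 1) 2L else i - 1L
      if (j > n) next
      r0 <- max(1, floor(y[i] - r) + 1); r1 <- min(h, ceiling(y[i] + r) + 1)
      c0 <- max(1, floor(x[i] - r) + 1); c1 <- min(w, ceiling(x[i] + r) + 1)
      dd <- abs(frames[r0:r1, c0:c1, i] - frames[r0:r1, c0:c1, j])
      dx2 <- outer(((r0:r1) - 1 - y[i])^2, ((c0:c1) - 1 - x[i])^2, "+")
      lpc[i] <- mean(dd[dx2 <= r^2])
    }
    feats$local_pixel_change <- lpc
  }
  feats[!track$valid, ] <- NA_real_
  attr(feats, "has_pixel_change") <- !is.null(frames)
  attr(feats, "fps") <- fps
  feats
}

# Windowed mean and sd by cumulative sums with NA-aware counts.
win_mean_sd <- function(x, r) {
  n <- length(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(xz); cs2 <- cumsum(xz^2); cn <- cumsum(ok)
  hi <- pmin(n, seq_len(n) + r); lo <- pmax(1, seq_len(n) - r)
  s <- cs[hi] - c(0, cs)[lo]
  s2 <- cs2[hi] - c(0, cs2)[lo]
  m <- cn[hi] - c(0, cn)[lo]
  mean_ <- ifelse(m > 0, s / m, NA_real_)
  var_ <- ifelse(m > 1, pmax(0, (s2 - s^2 / pmax(m, 1)) / (m - 1)), NA_real_)
  list(mean = mean_, sd = ifelse(m > 1, sqrt(var_), NA_real_))
}

#' Sliding-window statistics of per-frame features
#'
#' Expands each base feature into window features: for every radius in
#' `window_radii` and every statistic in `stats`, the statistic of the
#' feature over the centered window `[i - r, i + r]`, truncated at the
#' series edges (an edge window averages only the frames that exist).
#' `end_minus_start` is the difference between the last and first frame of
#' the (truncated) window. `NA` frames are ignored within a window; an
#' all-`NA` window yields `NA`.
#'
#' @param features Data frame of numeric per-frame features.
#' @param window_radii Integer radii in frames (default `c(2, 6, 12)`).
#' @param stats Statistics to compute, a subset of
#'   `c("mean", "std", "min", "max", "end_minus_start")`.
#' @return A data frame with `ncol(features) * length(window_radii) *
#'   length(stats)` columns named `<feature>_<stat>_r<radius>`.
#' @export
windowize <- function(features, window_radii = c(2, 6, 12),
                      stats = c("mean", "std", "min", "max", "end_minus_start")) {
  if (any(window_radii < 1)) stop("window radii must be >= 1")
  stats <- match.arg(stats, several.ok = TRUE)
  n <- nrow(features)
  out <- list()
  for (fname in names(features)) {
    x <- features[[fname]]
    for (r in window_radii) {
      ms <- if (any(c("mean", "std") %in% stats)) win_mean_sd(x, r) else NULL
      hi <- pmin(n, seq_len(n) + r); lo <- pmax(1, seq_len(n) - r)
      for (st in stats) {
        col <- switch(st,
          mean = ms$mean,
          std = ms$sd,
          min = vapply(seq_len(n), function(i) {
            w <- x[lo[i]:hi[i]]; w <- w[!is.na(w)]
            if (length(w)) min(w) else NA_real_
          }, numeric(1)),
          max = vapply(seq_len(n), function(i) {
            w <- x[lo[i]:hi[i]]; w <- w[!is.na(w)]
            if (length(w)) max(w) else NA_real_
          }, numeric(1)),
          end_minus_start = x[hi] - x[lo])
        out[[paste(fname, st, paste0("r", r), sep = "_")]] <- col
      }
    }
  }
  as.data.frame(out)
}
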