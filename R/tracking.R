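#' Estimate the static background of a frame stack
#'
#' Per-pixel median across a strided sample of frames. With the animal
#' present at any given pixel in fewer than half the sampled frames, the
#' median recovers the empty-arena image.
#'
#' @param frames Numeric array `h x w x n` in `[0, 1]`.
#' @param sample_stride Take every `sample_stride`-th frame; the default
#'   picks a stride so that about 50 frames are sampled.
#' @return A numeric `h x w` background matrix.
#' @export
estimate_background <- function(frames, sample_stride = NULL) {
  n <- dim(frames)[3]
  if (is.null(sample_stride)) sample_stride <- max(1L, floor(n / 50))
  idx <- seq(1, n, by = sample_stride)
  if (length(idx) < 10) stop("need at least 10 sampled frames; lower sample_stride")
  apply(frames[, , idx, drop = FALSE], c(1, 2), median)
}

# Centroid and ellipse parameters from the pixel coordinates of a blob
# (second-order image moments; axes of the equivalent constant-intensity
# ellipse). Coordinates are 0-based pixel centres.
blob_moments <- function(rows, cols) {
  x <- cols - 1; y <- rows - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(cx = cx, cy = cy,
       major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 0)),
       theta = theta %% pi)
}

#' Track the animal across a frame stack
#'
#' For each frame: absolute difference against the background, binarization
#' (Otsu threshold on the difference image by default), largest connected
#' component of at least `min_area_px` pixels, and centroid + body ellipse
#' from second-order image moments. Frames with no qualifying component are
#' marked invalid. Works for either polarity (dark animal on light bedding
#' or the reverse) because the difference image is unsigned.
#'
#' @param frames Numeric array `h x w x n`.
#' @param background Matrix from [estimate_background()], same `h x w`.
#' @param threshold Fixed binarization threshold on the difference image in
#'   `[0, 1]`, or `NULL` (default) for per-frame Otsu.
#' @param min_area_px Minimum blob area to accept, pixels.
#' @param fps Frames per second recorded on the output track.
#' @return A [frame_track()].
#' @export
track_frames <- function(frames, background, threshold = NULL,
                         min_area_px = 50, fps = 25) {
  dm <- dim(frames)
  if (length(dm) != 3 || dm[3] < 1) stop("frames must be a non-empty h x w x n array")
  if (!all(dm[1:2] == dim(background))) {
    stop("frames and background have different shapes")
  }
  n <- dm[3]
  x <- y <- major <- minor <- theta <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- abs(frames[, , i] - background)
    thr <- threshold %||% EBImage::otsu(EBImage::Image(d), range = c(0, 1))
    mask <- d > thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    if (!length(areas) || max(areas) < min_area_px) next
    best <- which.max(areas)   # ties: lowest label = first in scan order
    px <- which(lab == best, arr.ind = TRUE)
    m <- blob_moments(px[, 1], px[, 2])
    x[i] <- m$cx; y[i] <- m$cy
    major[i] <- m$major; minor[i] <- m$minor; theta[i] <- m$theta
    valid[i] <- TRUE
  }
  frame_track(x, y, major, minor, theta, valid = valid, fps = fps)
}

#' Bridge short tracking dropouts by linear interpolation
#'
#' Runs of invalid frames no longer than `max_gap_frames`, flanked by valid
#' frames on both sides, are filled by linear interpolation of position and
#' axis lengths (orientation interpolated along the shorter axial arc) and
#' marked valid. Longer runs, and runs touching the ends of the session,
#' are left untouched.
#'
#' @param track A [frame_track()].
#' @param max_gap_frames Longest gap (frames) that will be bridged.
#' @return A [frame_track()].
#' @export
interpolate_gaps <- function(track, max_gap_frames = 12) {
  runs <- logical_runs(!track$valid)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start_frame[i]; e <- runs$end_frame[i]   # 0-based half-open
    len <- e - s
    if (len > max_gap_frames) next
    if (s == 0 || e >= nrow(track)) next               # no anchor on one side
    i0 <- s; i1 <- e + 1                               # 1-based anchors
    frac <- seq_len(len) / (len + 1)
    idx <- (s + 1):e                                   # 1-based gap rows
    for (col in c("x_px", "y_px", "major_px", "minor_px")) {
      track[[col]][idx] <- track[[col]][i0] + frac * (track[[col]][i1] - track[[col]][i0])
    }
    th0 <- track$theta_rad[i0]; th1 <- track$theta_rad[i1]
    dth <- ((th1 - th0 + pi / 2) %% pi) - pi / 2       # shorter axial arc
    track$theta_rad[idx] <- (th0 + frac * dth) %% pi
    track$valid[idx] <- TRUE
  }
  track
}

#' Pixel-to-centimeter calibration from arena corners
#'
#' Averages the scale implied by the top edge (width) and the left edge
#' (height). If the two estimates disagree by more than 5% — e.g. an
#' uncorrected oblique camera view — a warning is emitted and the mean is
#' still returned.
#'
#' @param arena An [arena_geometry()].
#' @return Scalar pixels per centimeter.
#' @export
calibrate <- function(arena) {
  cp <- arena$corner_px
  top <- sqrt(sum((cp[2, ] - cp[1, ])^2))
  left <- sqrt(sum((cp[4, ] - cp[1, ])^2))
  if (top <= 0 || left <= 0) stop("degenerate arena corners")
  est <- c(top / arena$width_cm, left / arena$height_cm)
  if (abs(diff(est)) / mean(est) > 0.05) {
    warning(sprintf(
      "px/cm estimates from width (%.2f) and height (%.2f) differ by > 5%%",
      est[1], est[2]))
  }
  mean(est)
}
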