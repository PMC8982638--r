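#' Per-frame track of a single animal
#'
#' A `frame_track` is a data frame with one row per video frame holding the
#' animal's body-ellipse state: columns `frame` (0-based index), `t_s`
#' (seconds, `frame / fps`), `x_px`, `y_px` (ellipse centroid in image
#' coordinates: origin top-left, x rightward, y downward, pixel-centered),
#' `major_px`, `minor_px` (full axis lengths), `theta_rad` (major-axis
#' orientation in `[0, pi)`) and `valid` (logical; invalid frames carry `NA`
#' positions). The frame rate is stored as attribute `fps`.
#'
#' @param x_px,y_px Numeric centroid coordinates, one per frame.
#' @param major_px,minor_px Ellipse axis lengths in pixels.
#' @param theta_rad Orientation of the major axis, radians in `[0, pi)`.
#' @param valid Logical vector; `FALSE` rows are treated as tracking failures.
#' @param fps Frames per second.
#' @return A data frame of class `frame_track`.
#' @export
frame_track <- function(x_px, y_px, major_px, minor_px, theta_rad,
                        valid = rep(TRUE, length(x_px)), fps = 25) {
  n <- length(x_px)
  stopifnot(length(y_px) == n, length(valid) == n)
  stopifnot_scalar_pos(fps, "fps")
  major_px <- rep_len(major_px, n)
  minor_px <- rep_len(minor_px, n)
  theta_rad <- rep_len(theta_rad, n)
  tr <- data.frame(
    frame = seq_len(n) - 1L,
    t_s = (seq_len(n) - 1L) / fps,
    x_px = as.numeric(x_px), y_px = as.numeric(y_px),
    major_px = as.numeric(major_px), minor_px = as.numeric(minor_px),
    theta_rad = as.numeric(theta_rad) %% pi,
    valid = as.logical(valid)
  )
  tr[!tr$valid, c("x_px", "y_px", "major_px", "minor_px", "theta_rad")] <- NA_real_
  attr(tr, "fps") <- fps
  class(tr) <- c("frame_track", "data.frame")
  tr
}

#' Frame rate of a track or label series
#' @param x A `frame_track` or `label_series`.
#' @return Frames per second stored on the object.
#' @export
track_fps <- function(x) attr(x, "fps") %||% 25

#' Per-frame burying label series
#'
#' One row per frame: `frame` (0-based), `score` (real-valued classifier
#' margin, `NA` for manual annotations) and `label`, one of `"positive"`,
#' `"negative"`, `"unannotated"`. Frames never shown to an annotator are
#' `"unannotated"` and are excluded from training, cross-validation and
#' agreement tallies.
#'
#' @param label Character/factor vector of labels, or a logical vector
#'   (`TRUE` = positive); `NA` means unannotated.
#' @param score Optional per-frame real score.
#' @param fps Frames per second.
#' @return A data frame of class `label_series`.
#' @export
label_series <- function(label, score = NULL, fps = 25) {
  if (is.logical(label)) {
    label <- ifelse(is.na(label), "unannotated",
                    ifelse(label, "positive", "negative"))
  }
  label <- as.character(label)
  label[is.na(label)] <- "unannotated"
  bad <- setdiff(unique(label), c("positive", "negative", "unannotated"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  n <- length(label)
  ls <- data.frame(
    frame = seq_len(n) - 1L,
    score = if (is.null(score)) NA_real_ else as.numeric(score),
    label = label
  )
  attr(ls, "fps") <- fps
  class(ls) <- c("label_series", "data.frame")
  ls
}

#' Logical view of a label series
#' @param labels A `label_series` (or plain character/logical vector).
#' @return Logical vector: `TRUE` positive, `FALSE` negative, `NA` unannotated.
#' @export
label_mask <- function(labels) {
  lab <- if (is.data.frame(labels)) labels$label else labels
  if (is.logical(lab)) return(lab)
  out <- lab == "positive"
  out[lab == "unannotated"] <- NA
  out
}

#' Arena geometry and pixel calibration
#'
#' Describes the rectangular test cage as seen by the overhead camera: the
#' four corner points in image coordinates (ordered TL, TR, BR, BL) and the
#' physical floor dimensions. Defaults match a type III cage floor of
#' 26.6 x 42.5 cm.
#'
#' @param corner_px 4x2 numeric matrix of corner points (x, y) in pixels,
#'   ordered top-left, top-right, bottom-right, bottom-left.
#' @param width_cm,height_cm Physical dimensions of the arena floor.
#' @return An object of class `arena_geometry` with a `px_per_cm` field
#'   filled in by [calibrate()].
#' @export
arena_geometry <- function(corner_px, width_cm = 26.6, height_cm = 42.5) {
  corner_px <- as.matrix(corner_px)
  if (!all(dim(corner_px) == c(4, 2))) stop("corner_px must be a 4x2 matrix")
  stopifnot_scalar_pos(width_cm, "width_cm")
  stopifnot_scalar_pos(height_cm, "height_cm")
  g <- structure(list(corner_px = corner_px, width_cm = width_cm,
                      height_cm = height_cm, px_per_cm = NA_real_),
                 class = "arena_geometry")
  g$px_per_cm <- calibrate(g)
  g
}

# Axis-aligned pixel bounding box of the arena quadrilateral.
arena_bounds_px <- function(arena) {
  cp <- arena$corner_px
  list(x0 = min(cp[, 1]), x1 = max(cp[, 1]),
       y0 = min(cp[, 2]), y1 = max(cp[, 2]))
}
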