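SCHEMA_VERSION <- "mbury-1"

schema_header <- function(kind) sprintf("# %s %s", SCHEMA_VERSION, kind)

write_csv_schema <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schema_header(kind), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_schema <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write track / label / bout tables as CSV
#'
#' Plain CSV with a one-line schema comment header. Tracks carry columns
#' `frame, t_s, x_px, y_px, major_px, minor_px, theta_rad, valid`; label
#' series `frame, score, label`; bout sets
#' `bout_id, start_frame, end_frame, duration_s`.
#'
#' @param track,labels,bouts Objects to write.
#' @param path CSV file path.
#' @param fps Frame rate to attach when reading.
#' @return Readers return the reconstructed object; writers the path,
#'   invisibly.
#' @name track_io
NULL

#' @rdname track_io
#' @export
write_track_csv <- function(track, path) {
  write_csv_schema(as.data.frame(track), path, "track")
}

#' @rdname track_io
#' @export
read_track_csv <- function(path, fps = 25) {
  df <- read_csv_schema(path)
  tr <- frame_track(df$x_px, df$y_px, df$major_px, df$minor_px, df$theta_rad,
                    valid = df$valid, fps = fps)
  tr
}

#' @rdname track_io
#' @export
write_labels_csv <- function(labels, path) {
  write_csv_schema(as.data.frame(labels), path, "labels")
}

#' @rdname track_io
#' @export
read_labels_csv <- function(path, fps = 25) {
  df <- read_csv_schema(path)
  label_series(df$label, score = df$score, fps = fps)
}

#' @rdname track_io
#' @export
write_bouts_csv <- function(bouts, path) {
  write_csv_schema(as.data.frame(bouts), path, "bouts")
}

#' Read a stack of grayscale PNG frames from a directory
#'
#' Frames are read in lexicographic filename order; color PNGs are
#' averaged to grayscale.
#'
#' @param dir Directory containing `.png` files.
#' @return Numeric array `h x w x n` in `[0, 1]`.
#' @export
read_frames_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir)
  first <- png_gray(png::readPNG(files[1]))
  frames <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- first
  for (i in seq_along(files)[-1]) frames[, , i] <- png_gray(png::readPNG(files[i]))
  frames
}

png_gray <- function(img) {
  if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
}

#' Write a frame stack as numbered PNGs
#'
#' @param frames Array `h x w x n` in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames_dir <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(frames)[3]
  for (i in seq_len(n)) {
    png::writePNG(frames[, , i],
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' Read an RGB still image (PNG)
#'
#' @param path PNG file.
#' @return Array `h x w x 3` in `[0, 1]`.
#' @export
read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3) stop("expected a color image")
  img[, , 1:3, drop = FALSE]
}

#' Session configuration
#'
#' Assembles and validates the parameters of one analysis run. Defaults
#' follow the standard protocol: 25 fps, a 26.6 x 42.5 cm arena, a 1 s
#' minimum bout, 20 marbles with a 2/3 burial threshold.
#'
#' @param fps Frames per second.
#' @param arena An [arena_geometry()].
#' @param model An `mb_classifier` or a path to one saved with
#'   [save_classifier()].
#' @param min_bout_s,max_gap_s Bout segmentation parameters.
#' @param bin_size_px Heatmap bin side.
#' @param max_step_cm Tracking glitch threshold for distance.
#' @param burial_threshold,expected_marbles Marble scoring parameters.
#' @param smooth_radius_frames Label median-filter radius.
#' @param out_dir Optional output directory; when set, [run_session()]
#'   writes CSV/JSON/PNG outputs there.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(fps = 25, arena = NULL, model = NULL,
                           min_bout_s = 1.0, max_gap_s = 0.0,
                           bin_size_px = 16, max_step_cm = 10,
                           burial_threshold = 2 / 3, expected_marbles = 20,
                           smooth_radius_frames = 2, out_dir = NULL) {
  stopifnot_scalar_pos(fps, "fps")
  if (is.null(arena)) stop("config error: arena geometry is required")
  if (is.null(model)) stop("config error: classifier model is required")
  if (is.character(model)) {
    if (!file.exists(model)) stop("config error: model file not found: ", model)
  } else if (!inherits(model, "mb_classifier")) {
    stop("config error: model must be an mb_classifier or a file path")
  }
  structure(list(fps = fps, arena = arena, model = model,
                 min_bout_s = min_bout_s, max_gap_s = max_gap_s,
                 bin_size_px = bin_size_px, max_step_cm = max_step_cm,
                 burial_threshold = burial_threshold,
                 expected_marbles = expected_marbles,
                 smooth_radius_frames = smooth_radius_frames,
                 out_dir = out_dir), class = "session_config")
}

#' Read a session configuration from YAML
#'
#' Recognized keys mirror the arguments of [session_config()]; the arena is
#' given as `arena: {corner_px: [[x,y],...], width_cm: , height_cm: }` and
#' the model as a file path under `model`.
#'
#' @param path YAML file.
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  y <- yaml::read_yaml(path)
  arena <- NULL
  if (!is.null(y$arena)) {
    cp <- do.call(rbind, y$arena$corner_px)
    arena <- arena_geometry(cp, width_cm = y$arena$width_cm %||% 26.6,
                            height_cm = y$arena$height_cm %||% 42.5)
  }
  session_config(
    fps = y$fps %||% 25, arena = arena, model = y$model,
    min_bout_s = y$min_bout_s %||% 1.0, max_gap_s = y$max_gap_s %||% 0.0,
    bin_size_px = y$bin_size_px %||% 16, max_step_cm = y$max_step_cm %||% 10,
    burial_threshold = y$burial_threshold %||% (2 / 3),
    expected_marbles = y$expected_marbles %||% 20,
    smooth_radius_frames = y$smooth_radius_frames %||% 2,
    out_dir = y$out_dir)
}
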