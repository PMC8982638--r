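#' Segment burying bouts from a label series
#'
#' A bout is a maximal run of positive frames. Two post-processing rules
#' are applied in a fixed order: first, runs separated by at most
#' `max_gap_s` seconds of negative frames are merged (bridging brief
#' classifier flicker inside one long bout); then runs shorter than
#' `min_bout_s` seconds are dropped. The default minimum bout length is one
#' second, so at 25 fps a 24-frame run is discarded and a 25-frame run
#' kept. Unannotated frames count as negative for segmentation.
#'
#' @param labels A [label_series()] (or logical vector).
#' @param fps Frames per second.
#' @param min_bout_s Minimum bout duration in seconds (default 1).
#' @param max_gap_s Maximum negative gap merged into a bout (default 0).
#' @return A data frame of class `bout_set` with columns `bout_id`,
#'   `start_frame`, `end_frame` (0-based, half-open), `duration_s`;
#'   attributes `fps` and `n_frames`.
#' @export
segment_bouts <- function(labels, fps = NULL, min_bout_s = 1.0, max_gap_s = 0.0) {
  fps <- fps %||% track_fps(labels)
  stopifnot_scalar_pos(fps, "fps")
  m <- label_mask(labels)
  m[is.na(m)] <- FALSE
  runs <- logical_runs(m)
  # merge runs separated by <= max_gap_s * fps negative frames
  if (nrow(runs) > 1 && max_gap_s > 0) {
    gap_frames <- max_gap_s * fps
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start_frame[i] - merged$end_frame[nrow(merged)] <= gap_frames) {
        merged$end_frame[nrow(merged)] <- runs$end_frame[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  len <- runs$end_frame - runs$start_frame
  runs <- runs[len >= min_bout_s * fps, , drop = FALSE]
  out <- data.frame(
    bout_id = seq_len(nrow(runs)),
    start_frame = as.integer(runs$start_frame),
    end_frame = as.integer(runs$end_frame))
  out$duration_s <- (out$end_frame - out$start_frame) / fps
  attr(out, "fps") <- fps
  attr(out, "n_frames") <- length(m)
  class(out) <- c("bout_set", "data.frame")
  out
}

#' Reconstruct the per-frame burying mask implied by a bout set
#'
#' @param bouts A `bout_set`.
#' @param n_frames Total frames (defaults to the attribute stored at
#'   segmentation time).
#' @return Logical vector, `TRUE` inside bouts.
#' @export
bout_mask <- function(bouts, n_frames = NULL) {
  n_frames <- n_frames %||% attr(bouts, "n_frames")
  m <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(bouts))) {
    m[(bouts$start_frame[i] + 1):bouts$end_frame[i]] <- TRUE
  }
  m
}

#' Headline bout statistics for one session
#'
#' @param bouts A `bout_set` from [segment_bouts()].
#' @param fps Frames per second (defaults to the bout set's).
#' @return A list of class `bout_summary`: `n_bouts`, `mean_bout_s`,
#'   `total_burying_s`, and `empty` (`TRUE` when there were no bouts, in
#'   which case the mean is reported as 0 with this flag set).
#' @export
summarize_bouts <- function(bouts, fps = NULL) {
  fps <- fps %||% attr(bouts, "fps")
  durs <- (bouts$end_frame - bouts$start_frame) / fps
  n <- nrow(bouts)
  structure(list(
    n_bouts = n,
    mean_bout_s = if (n > 0) sum(durs) / n else 0,
    total_burying_s = sum(durs),
    empty = n == 0), class = "bout_summary")
}

#' Histogram of bout durations
#'
#' Right-open bins `[edge_i, edge_{i+1})`; bouts outside the edge coverage
#' are not counted.
#'
#' @param bouts A `bout_set`.
#' @param bin_edges_s Strictly increasing bin edges in seconds.
#' @return Integer counts, one per bin.
#' @export
bout_histogram <- function(bouts, bin_edges_s) {
  if (any(diff(bin_edges_s) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(bin_edges_s) - 1
  counts <- integer(nb)
  for (d in bouts$duration_s) {
    j <- findInterval(d, bin_edges_s, rightmost.closed = FALSE)
    if (j >= 1 && j <= nb && d < bin_edges_s[nb + 1]) counts[j] <- counts[j] + 1L
  }
  counts
}

#' Cumulative burying time in one-minute bins
#'
#' Cumulative seconds of burying at the end of each time bin, computed on
#' the post-segmentation mask (after gap merging and the minimum-bout
#' filter) so that the final value equals
#' `summarize_bouts(...)$total_burying_s`.
#'
#' @param labels A [label_series()].
#' @param fps Frames per second.
#' @param bin_s Bin width in seconds (default 60 = 1 min).
#' @param min_bout_s,max_gap_s Passed to [segment_bouts()].
#' @return Data frame with `bin`, `t_end_s`, `cum_burying_s` (monotone
#'   non-decreasing).
#' @export
cumulative_curve <- function(labels, fps = NULL, bin_s = 60,
                             min_bout_s = 1.0, max_gap_s = 0.0) {
  fps <- fps %||% track_fps(labels)
  stopifnot_scalar_pos(fps, "fps")
  bouts <- segment_bouts(labels, fps, min_bout_s, max_gap_s)
  m <- bout_mask(bouts)
  n <- length(m)
  bin_frames <- bin_s * fps
  nb <- ceiling(n / bin_frames)
  ends <- pmin(n, ceiling(seq_len(nb) * bin_frames))
  cum <- cumsum(m)
  data.frame(bin = seq_len(nb), t_end_s = ends / fps,
             cum_burying_s = cum[ends] / fps)
}
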