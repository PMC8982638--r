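#' Run the full analysis pipeline on one session
#'
#' Orchestrates track -> features -> predict -> bouts -> activity ->
#' heatmap (-> marbles when an end-of-test image is supplied) for one
#' session. Each stage runs inside an error barrier: a failure is recorded
#' under the stage's name and the stages that depend on it are skipped,
#' while independent stages still run. The whole run is deterministic given
#' the inputs, the model and the configuration.
#'
#' @param config A [session_config()].
#' @param frames Numeric array `h x w x n` of video frames, or a path to a
#'   directory of PNG frames.
#' @param marble_image Optional RGB array or PNG path of the end-of-test
#'   marble photograph.
#' @return A list of class `session_report`: `track`, `labels`, `bouts`,
#'   `bout_summary`, `activity`, `corner_preference`, `heatmap`,
#'   `cumulative`, `marbles` (or `NULL`), `errors` (named list of stage
#'   failures) and `summary` (flat named list of the headline numbers).
#'   When `config$out_dir` is set the per-stage outputs and a summary JSON
#'   are written there.
#' @export
run_session <- function(config, frames, marble_image = NULL) {
  stopifnot(inherits(config, "session_config"))
  model <- config$model
  if (is.character(model)) model <- load_classifier(model)
  errors <- list()
  rep <- list(track = NULL, labels = NULL, bouts = NULL, bout_summary = NULL,
              activity = NULL, corner_preference = NULL, heatmap = NULL,
              cumulative = NULL, marbles = NULL)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (is.character(frames)) frames <- stage("read_frames", read_frames_dir(frames))

  rep$track <- stage("tracking", {
    bg <- estimate_background(frames)
    interpolate_gaps(track_frames(frames, bg, fps = config$fps))
  })

  feats <- NULL
  if (!is.null(rep$track)) {
    feats <- stage("features", {
      windowize(compute_frame_features(rep$track, frames, config$arena))
    })
  }
  if (!is.null(feats)) {
    rep$labels <- stage("classify", {
      predict_frames(model, feats,
                     smooth_radius_frames = config$smooth_radius_frames,
                     fps = config$fps)
    })
  }
  if (!is.null(rep$labels)) {
    rep$bouts <- stage("bouts", {
      segment_bouts(rep$labels, config$fps, config$min_bout_s, config$max_gap_s)
    })
    rep$cumulative <- stage("bouts", {
      cumulative_curve(rep$labels, config$fps,
                       min_bout_s = config$min_bout_s,
                       max_gap_s = config$max_gap_s)
    })
  }
  if (!is.null(rep$bouts)) rep$bout_summary <- summarize_bouts(rep$bouts)
  if (!is.null(rep$track)) {
    rep$activity <- stage("activity", {
      compute_activity(rep$track, config$arena$px_per_cm, config$fps,
                       config$max_step_cm)
    })
    rep$corner_preference <- stage("activity", {
      corner_preference(rep$track, config$arena)
    })
  }
  if (!is.null(rep$track) && !is.null(rep$labels)) {
    rep$heatmap <- stage("heatmap", {
      occupancy_heatmap(rep$track, rep$labels, config$arena, config$bin_size_px)
    })
  }
  if (!is.null(marble_image)) {
    rep$marbles <- stage("marbles", {
      img <- if (is.character(marble_image)) read_image_rgb(marble_image) else marble_image
      measure_coverage(segment_marbles(img),
                       burial_threshold = config$burial_threshold,
                       expected_n = config$expected_marbles)
    })
  }

  rep$errors <- errors
  rep$summary <- session_summary(rep)
  class(rep) <- "session_report"
  if (!is.null(config$out_dir)) write_session_outputs(rep, config)
  rep
}

session_summary <- function(rep) {
  s <- list(schema = SCHEMA_VERSION)
  if (!is.null(rep$bout_summary)) {
    s$n_bouts <- rep$bout_summary$n_bouts
    s$mean_bout_s <- rep$bout_summary$mean_bout_s
    s$total_burying_s <- rep$bout_summary$total_burying_s
  }
  if (!is.null(rep$activity)) {
    s$distance_cm <- rep$activity$distance_cm
    s$mean_speed_cm_s <- rep$activity$mean_speed_cm_s
  }
  if (!is.null(rep$corner_preference)) s$corner_preference <- rep$corner_preference
  if (!is.null(rep$marbles)) {
    s$n_buried <- rep$marbles$n_buried
    s$total_uncovered_area_px2 <- rep$marbles$total_uncovered_area_px2
  }
  if (length(rep$errors)) s$failed_stages <- names(rep$errors)
  s
}

write_session_outputs <- function(rep, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(rep$track)) write_track_csv(rep$track, p("track.csv"))
  if (!is.null(rep$labels)) write_labels_csv(rep$labels, p("labels.csv"))
  if (!is.null(rep$bouts)) write_bouts_csv(rep$bouts, p("bouts.csv"))
  if (!is.null(rep$cumulative)) {
    write_csv_schema(rep$cumulative, p("cumulative.csv"), "cumulative")
  }
  if (!is.null(rep$heatmap)) write_heatmap_png(rep$heatmap, p("heatmap.png"))
  jsonlite::write_json(rep$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Run a batch of sessions and collect a cohort table
#'
#' Each element of `sessions` is a list with elements `config`, `frames`
#' and optionally `marble_image` and `id`. Sessions are isolated: one
#' failure does not abort the rest.
#'
#' @param sessions List of session descriptors.
#' @return A list of class `batch_report`: `reports` (per-session
#'   `session_report` or error message), `cohort` (long-format data frame
#'   with columns `session_id`, `metric`, `value`, ready for
#'   [group_compare()]) and `n_failed`.
#' @export
run_batch <- function(sessions) {
  if (!length(sessions)) stop("empty batch")
  reports <- vector("list", length(sessions))
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    id <- s$id %||% sprintf("session_%03d", i)
    res <- tryCatch(
      run_session(s$config, s$frames, s$marble_image),
      error = function(e) conditionMessage(e))
    reports[[i]] <- res
    if (is.character(res) || length(res$errors)) n_failed <- n_failed + 1L
    if (!is.character(res)) {
      met <- res$summary[setdiff(names(res$summary), c("schema", "failed_stages"))]
      for (m in names(met)) {
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = id, metric = m, value = as.numeric(met[[m]]))
      }
    }
  }
  names(reports) <- vapply(seq_along(sessions),
                           function(i) sessions[[i]]$id %||% sprintf("session_%03d", i),
                           character(1))
  cohort <- if (length(rows)) do.call(rbind, rows) else
    data.frame(session_id = character(0), metric = character(0),
               value = numeric(0))
  structure(list(reports = reports, cohort = cohort, n_failed = n_failed),
            class = "batch_report")
}
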