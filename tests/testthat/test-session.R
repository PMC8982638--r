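# Shared fixture: a classifier trained on one short rendered session.
local_model_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- quick_spec(seed = 91, duration_s = 60, n_bouts = 5,
                       bout_duration_s_mean = 3, bout_duration_s_sd = 1)
    gt <- make_trajectory(spec)
    fr <- render_frames(gt$track, spec, noise_sd = 0.01)
    tr <- interpolate_gaps(track_frames(fr, estimate_background(fr)))
    wf <- windowize(compute_frame_features(tr, fr, spec_arena(spec)))
    model <- train_classifier(wf, gt$labels, seed = 1)
    cache <<- list(model = model, spec = spec)
    cache
  }
})

test_that("a session runs end to end and recovers the ground truth", {
  fx <- local_model_fixture()
  spec <- quick_spec(seed = 92, duration_s = 60, n_bouts = 4,
                     bout_duration_s_mean = 3, bout_duration_s_sd = 1)
  gt <- make_trajectory(spec)
  fr <- render_frames(gt$track, spec, noise_sd = 0.01)
  out <- tempfile()
  cfg <- session_config(arena = spec_arena(spec), model = fx$model,
                        out_dir = out)
  rep <- run_session(cfg, fr)

  expect_length(rep$errors, 0)
  expect_equal(rep$summary$n_bouts, nrow(gt$bouts))
  expect_lt(abs(rep$summary$total_burying_s - sum(gt$bouts$duration_s)), 2)
  expect_true(all(c("track.csv", "labels.csv", "bouts.csv", "summary.json",
                    "cumulative.csv", "heatmap.png") %in% list.files(out)))

  # round-trip read-back of the CSV outputs is lossless
  tr2 <- read_track_csv(file.path(out, "track.csv"), fps = 25)
  expect_equal(tr2$x_px, rep$track$x_px)
  lab2 <- read_labels_csv(file.path(out, "labels.csv"), fps = 25)
  expect_equal(lab2$label, rep$labels$label)

  # determinism: identical rerun
  rep2 <- run_session(session_config(arena = spec_arena(spec),
                                     model = fx$model), fr)
  expect_equal(rep$summary, rep2$summary)
  unlink(out, recursive = TRUE)
})

test_that("marble images are scored within a session when supplied", {
  fx <- local_model_fixture()
  spec <- quick_spec(seed = 93, duration_s = 20, n_bouts = 1)
  gt <- make_trajectory(spec)
  fr <- render_frames(gt$track, spec, noise_sd = 0.01)
  mi <- make_marble_image(20, coverage = rep(c(0, 0.9), 10), seed = 9)
  cfg <- session_config(arena = spec_arena(spec), model = fx$model)
  rep <- run_session(cfg, fr, marble_image = mi$image)
  expect_false(is.null(rep$marbles))
  expect_equal(rep$summary$n_buried, 10)
})

test_that("configuration errors surface before any tracking", {
  rect <- arena_geometry(rbind(c(0, 0), c(266, 0), c(266, 425), c(0, 425)))
  expect_error(session_config(arena = NULL, model = "x"), "arena")
  expect_error(session_config(arena = rect, model = NULL), "model")
  expect_error(session_config(arena = rect, model = "/nonexistent/model.rds"),
               "not found")
})

test_that("stage failures are reported and downstream stages skipped", {
  fx <- local_model_fixture()
  cfg <- session_config(arena = spec_arena(fx$spec), model = fx$model)
  blank <- array(0.7, dim = c(100, 80, 30))   # no animal: tracking yields
  rep <- run_session(cfg, blank)               # no valid frames
  expect_true(length(rep$errors) > 0)
  expect_true(any(c("features", "tracking") %in% names(rep$errors)))
  expect_null(rep$bout_summary)
  expect_true("failed_stages" %in% names(rep$summary))
})

test_that("batches isolate failures and build a cohort table", {
  fx <- local_model_fixture()
  mk <- function(seed) {
    spec <- quick_spec(seed = seed, duration_s = 20, n_bouts = 1)
    gt <- make_trajectory(spec)
    list(config = session_config(arena = spec_arena(spec), model = fx$model),
         frames = render_frames(gt$track, spec, noise_sd = 0.01),
         id = paste0("s", seed))
  }
  good1 <- mk(94); good2 <- mk(95)
  bad <- list(config = good1$config,
              frames = array(0.7, dim = c(100, 80, 30)), id = "bad")
  batch <- run_batch(list(good1, bad, good2))
  expect_equal(batch$n_failed, 1)
  expect_true(all(c("s94", "s95") %in% batch$cohort$session_id))
  expect_true(all(c("session_id", "metric", "value") %in%
                    names(batch$cohort)))
  expect_gt(nrow(batch$cohort), 6)
  expect_error(run_batch(list()), "empty")

  # two identical sessions give identical rows
  s1 <- mk(96); s2 <- mk(96); s2$id <- "s96b"
  batch2 <- run_batch(list(s1, s2))
  w <- split(batch2$cohort$value, batch2$cohort$session_id)
  expect_equal(w[[1]], w[[2]])
})

test_that("YAML configs round-trip into session configs", {
  fx <- local_model_fixture()
  mp <- tempfile(fileext = ".rds")
  save_classifier(fx$model, mp)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "fps: 25",
    "arena:",
    "  corner_px: [[0, 0], [160, 0], [160, 255], [0, 255]]",
    "  width_cm: 26.6",
    "  height_cm: 42.5",
    sprintf("model: %s", mp),
    "min_bout_s: 1.0",
    "burial_threshold: 0.5"), yml)
  cfg <- read_session_config(yml)
  expect_s3_class(cfg, "session_config")
  expect_equal(cfg$burial_threshold, 0.5)
  expect_equal(cfg$arena$width_cm, 26.6)
  unlink(c(mp, yml))
})
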