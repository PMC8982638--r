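test_that("trajectory generator honours the session spec", {
  spec <- quick_spec(seed = 7, duration_s = 60, n_bouts = 4)
  gt <- make_trajectory(spec)

  expect_equal(nrow(gt$track), 60 * 25)
  expect_equal(nrow(gt$labels), nrow(gt$track))
  expect_equal(nrow(gt$bouts), 4)

  d <- mbury:::spec_arena_px(spec)
  expect_true(all(gt$track$x_px >= 0 & gt$track$x_px <= d[["w"]]))
  expect_true(all(gt$track$y_px >= 0 & gt$track$y_px <= d[["h"]]))

  # labels are exactly the scheduled bouts
  m <- label_mask(gt$labels)
  for (i in seq_len(nrow(gt$bouts))) {
    idx <- (gt$bouts$start_frame[i] + 1):gt$bouts$end_frame[i]
    expect_true(all(m[idx]))
  }
  expect_equal(sum(m), sum(gt$bouts$end_frame - gt$bouts$start_frame))
})

test_that("trajectories are deterministic in the seed and reject bad specs", {
  spec <- quick_spec(seed = 7)
  expect_identical(make_trajectory(spec), make_trajectory(spec))
  spec2 <- quick_spec(seed = 8)
  expect_false(identical(make_trajectory(spec)$track$x_px,
                         make_trajectory(spec2)$track$x_px))
  expect_error(session_spec(duration_s = -1), "duration_s")
  expect_error(session_spec(fps = 0), "fps")
  expect_error(session_spec(corner_bias = 1.5), "corner_bias")
})

test_that("a session with no bouts has all-negative labels", {
  gt <- make_trajectory(quick_spec(seed = 3, n_bouts = 0))
  expect_true(all(label_mask(gt$labels) == FALSE))
  expect_equal(nrow(gt$bouts), 0)
})

test_that("burying epochs are slower than locomotion epochs", {
  gt <- make_trajectory(quick_spec(seed = 5, duration_s = 120, n_bouts = 6))
  v <- sqrt(diff(gt$track$x_px)^2 + diff(gt$track$y_px)^2)
  m <- label_mask(gt$labels)[-1]
  expect_lt(median(v[m]), 0.5 * median(v[!m]))
})

test_that("rendered frames are deterministic and put mass at the centroid", {
  spec <- quick_spec(seed = 2, duration_s = 1, n_bouts = 0)
  gt <- make_trajectory(spec)
  tr <- gt$track[1:3, ]
  f1 <- render_frames(tr, spec, noise_sd = 0.02, seed = 9)
  f2 <- render_frames(tr, spec, noise_sd = 0.02, seed = 9)
  expect_identical(f1, f2)

  # noise-free: one dark connected region whose pixel-mass centroid sits on
  # the ground truth pose (pixel-mass oracle, independent of the tracker)
  f <- render_frames(tr, spec, noise_sd = 0)
  dark <- f[, , 1] < 0.5
  lab <- EBImage::bwlabel(dark)
  expect_equal(max(lab), 1)
  px <- which(dark, arr.ind = TRUE)
  expect_lt(abs(mean(px[, 2] - 1) - tr$x_px[1]), 0.5)
  expect_lt(abs(mean(px[, 1] - 1) - tr$y_px[1]), 0.5)
})

test_that("observer-label noise flips frames at the requested rates", {
  gt <- make_trajectory(quick_spec(seed = 11, duration_s = 400, n_bouts = 20))
  truth <- label_mask(gt$labels)

  expect_identical(label_mask(make_observer_labels(gt$labels, 0, 0, seed = 1)),
                   truth)
  expect_identical(label_mask(make_observer_labels(gt$labels, 1, 1, seed = 1)),
                   !truth)

  obs <- label_mask(make_observer_labels(gt$labels, 0.1, 0.05, seed = 4))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  miss <- sum(truth & !obs) / n_pos
  fa <- sum(!truth & obs) / n_neg
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / n_pos))
  expect_lt(abs(fa - 0.05), 3 * sqrt(0.05 * 0.95 / n_neg))
  expect_error(make_observer_labels(gt$labels, -0.1, 0), "rates")
})

test_that("feature tables separate classes by the requested amount", {
  gt <- make_trajectory(quick_spec(seed = 13, duration_s = 400, n_bouts = 20))
  m <- label_mask(gt$labels)

  ft0 <- make_feature_table(gt$labels, class_separation = 0, seed = 1)
  d0 <- mean(ft0$f1[m]) - mean(ft0$f1[!m])
  expect_lt(abs(d0), 4 * sqrt(1 / sum(m) + 1 / sum(!m)))

  ft <- make_feature_table(gt$labels, class_separation = 10, seed = 1)
  expect_gt(min(ft$f1[m]), max(ft$f1[!m]))  # linearly separable

  # separation 1: threshold at the midpoint on one axis achieves about
  # pnorm(0.5) accuracy (closed-form Gaussian overlap)
  ft1 <- make_feature_table(gt$labels, class_separation = 1, seed = 2)
  acc <- mean((ft1$f1 > 0) == m)
  expect_lt(abs(acc - pnorm(0.5)), 0.03)
})

test_that("annotation subsampling balances classes without touching positives", {
  gt <- make_trajectory(quick_spec(seed = 17, duration_s = 240, n_bouts = 10))
  lab <- subsample_annotations(gt$labels, seed = 2)
  m <- label_mask(lab)
  expect_equal(sum(m, na.rm = TRUE), sum(label_mask(gt$labels)))
  expect_lt(abs(sum(!m, na.rm = TRUE) - sum(m, na.rm = TRUE)),
            0.05 * sum(m, na.rm = TRUE))
})

test_that("synthetic marble images carry exact per-marble ground truth", {
  mi <- make_marble_image(9, coverage = c(0, 0, 0, 0.5, 0.5, 0.5, 1, 1, 1),
                          radius_px = 20, seed = 3)
  tr <- mi$truth
  full <- tr$full_px[tr$coverage == 0]
  expect_true(all(abs(tr$visible_px[tr$coverage == 0] - pi * 20^2) <
                    2 * pi * 20))        # full disk within a 1 px ring
  expect_true(all(tr$visible_px[tr$coverage == 1] == 0))
  half <- tr$visible_px[tr$coverage == 0.5] / tr$full_px[tr$coverage == 0.5]
  expect_true(all(abs(half - 0.5) < 0.02))
  expect_identical(make_marble_image(4, 0.3, seed = 5),
                   make_marble_image(4, 0.3, seed = 5))
  expect_error(make_marble_image(4, coverage = 1.2), "coverage")
})
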