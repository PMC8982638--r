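make_cv_fixture <- function(seed, separation = 3, duration_s = 240,
                            n_bouts = 12) {
  gt <- make_trajectory(quick_spec(seed = seed, duration_s = duration_s,
                                   n_bouts = n_bouts))
  labels <- subsample_annotations(gt$labels, seed = seed + 1)
  feats <- make_feature_table(labels, class_separation = separation,
                              seed = seed + 2)
  list(feats = feats, labels = labels)
}

test_that("training is deterministic and fits separable data perfectly", {
  fx <- make_cv_fixture(31, separation = 10)
  m1 <- train_classifier(fx$feats, fx$labels, seed = 5)
  m2 <- train_classifier(fx$feats, fx$labels, seed = 5)
  expect_identical(classifier_margin(m1, fx$feats),
                   classifier_margin(m2, fx$feats))

  pred <- predict_frames(m1, fx$feats, smooth_radius_frames = 0)
  truth <- label_mask(fx$labels)
  ann <- !is.na(truth)
  expect_equal(mean(label_mask(pred)[ann] == truth[ann]), 1)

  expect_error(train_classifier(fx$feats,
                                label_series(rep(TRUE, nrow(fx$feats)))),
               "both classes")
})

test_that("prediction aligns feature columns and applies the median filter", {
  fx <- make_cv_fixture(33)
  model <- train_classifier(fx$feats, fx$labels, seed = 1)

  # shuffled column order gives identical scores
  shuffled <- fx$feats[, rev(names(fx$feats))]
  expect_equal(classifier_margin(model, fx$feats),
               classifier_margin(model, shuffled))
  expect_error(classifier_margin(model, fx$feats[, 1:3]), "missing")

  # radius 0: labels are exactly the sign of the score
  p0 <- predict_frames(model, fx$feats, smooth_radius_frames = 0)
  expect_identical(label_mask(p0), p0$score >= 0)

  # an isolated 1-frame positive is removed by a radius-2 median
  v <- rep(FALSE, 11); v[6] <- TRUE
  expect_false(any(mbury:::median_smooth_logical(v, 2)))
  # and an isolated 1-frame hole in a long positive run is filled
  w <- rep(TRUE, 11); w[6] <- FALSE
  expect_true(all(mbury:::median_smooth_logical(w, 2)))

  # random labels: sliding-median brute force oracle
  set.seed(2)
  z <- runif(200) > 0.5
  sm <- mbury:::median_smooth_logical(z, 3)
  for (i in seq_along(z)) {
    w <- z[max(1, i - 3):min(200, i + 3)]
    expected <- if (sum(w) * 2 == length(w)) z[i] else sum(w) * 2 > length(w)
    expect_identical(sm[i], expected)
  }
})

test_that("model serialization round-trips bit-identically", {
  fx <- make_cv_fixture(35)
  model <- train_classifier(fx$feats, fx$labels, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_classifier(model, path)
  loaded <- load_classifier(path)
  expect_identical(classifier_margin(model, fx$feats),
                   classifier_margin(loaded, fx$feats))
  unlink(path)
})

test_that("cross-validation is segment-stratified and conserves counts", {
  fx <- make_cv_fixture(37)
  cv <- cross_validate(fx$feats, fx$labels, k = 5, seed = 2)
  expect_true(cv$acc_burying >= 0 && cv$acc_burying <= 1)
  expect_true(cv$acc_nonburying >= 0 && cv$acc_nonburying <= 1)
  expect_equal(sum(cv$confusion), cv$n_frames_annotated)
  expect_equal(cv$n_frames_annotated, sum(!is.na(label_mask(fx$labels))))
  expect_error(cross_validate(fx$feats, fx$labels, k = 1), "k must be")
})

test_that("cross-validation accuracy is high with clear class separation", {
  fx <- make_cv_fixture(39, separation = 10)
  cv <- cross_validate(fx$feats, fx$labels, k = 5, seed = 1)
  expect_gt(cv$acc_burying, 0.95)
  expect_gt(cv$acc_nonburying, 0.95)
})

test_that("increasing separation never hurts accuracy (3-seed medians)", {
  med_acc <- function(sep) {
    accs <- vapply(1:3, function(s) {
      fx <- make_cv_fixture(50 + s, separation = sep, duration_s = 120,
                            n_bouts = 6)
      cv <- cross_validate(fx$feats, fx$labels, k = 4, seed = s,
                           n_rounds = 50)
      (cv$acc_burying + cv$acc_nonburying) / 2
    }, numeric(1))
    median(accs)
  }
  accs <- vapply(c(0.5, 2, 6), med_acc, numeric(1))
  expect_true(all(diff(accs) >= -0.01))
})

test_that("annotation import handles frame tables and event exports", {
  # frame table
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(frame = c(0, 1, 2, 5),
                       label = c("positive", "positive", "negative",
                                 "negative")),
            f, row.names = FALSE)
  lab <- read_annotations(f, fps = 25, n_frames = 8)
  expect_equal(lab$label[1:3], c("positive", "positive", "negative"))
  expect_equal(lab$label[4], "unannotated")
  unlink(f)

  # event export expanded at the stated fps
  g <- tempfile(fileext = ".csv")
  write.csv(data.frame(behavior = "burying", start_s = 1, stop_s = 2), g,
            row.names = FALSE)
  lab2 <- read_annotations(g, fps = 25, n_frames = 100)
  m <- label_mask(lab2)
  expect_equal(sum(m), 25)
  expect_true(all(which(m) %in% 26:50))
  unlink(g)
})
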