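#' Train the frame-level burying classifier
#'
#' Fits a boosted ensemble of shallow trees (gradient boosting with
#' depth-limited trees, logistic loss) on window features of annotated
#' frames. Unannotated frames are excluded; `NA` feature values are handled
#' natively by the trees. The model records its feature column names so
#' that prediction can realign columns.
#'
#' @param features Data frame of numeric (window) features, one row per frame.
#' @param labels A [label_series()] aligned to `features`.
#' @param n_rounds Boosting rounds (default 100).
#' @param max_depth Tree depth (default 2).
#' @param eta Learning rate.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `mb_classifier`.
#' @export
train_classifier <- function(features, labels, n_rounds = 100, max_depth = 2,
                             eta = 0.1, seed = 0L) {
  m <- label_mask(labels)
  if (length(m) != nrow(features)) stop("features and labels length mismatch")
  ann <- which(!is.na(m))
  if (length(unique(m[ann])) < 2) {
    stop("need both classes among annotated frames")
  }
  x <- as.matrix(features[ann, , drop = FALSE])
  storage.mode(x) <- "double"
  y <- as.integer(m[ann])
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = dtrain, nrounds = n_rounds, verbose = 0)
  })
  structure(list(raw = xgboost::xgb.save.raw(booster),
                 feature_names = colnames(features),
                 n_rounds = n_rounds, max_depth = max_depth, eta = eta,
                 threshold = 0, version = 1L),
            class = "mb_classifier")
}

classifier_booster <- function(model) xgboost::xgb.load.raw(model$raw)

#' Classifier scores for a feature table
#'
#' @param model An `mb_classifier`.
#' @param features Data frame containing at least the model's feature columns.
#' @return Numeric ensemble margins (log-odds scale), one per row.
#' @export
classifier_margin <- function(model, features) {
  missing_cols <- setdiff(model$feature_names, colnames(features))
  if (length(missing_cols)) {
    stop("feature columns missing: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  predict(classifier_booster(model),
          xgboost::xgb.DMatrix(x, nthread = 1, missing = NA),
          outputmargin = TRUE)
}

# Sliding majority (median) filter on a logical vector, centered window of
# radius r, truncated at the edges. Ties (even truncated windows) keep the
# original value.
median_smooth_logical <- function(v, r) {
  if (r < 1) return(v)
  n <- length(v)
  cs <- cumsum(as.integer(v))
  hi <- pmin(n, seq_len(n) + r); lo <- pmax(1, seq_len(n) - r)
  ones <- cs[hi] - c(0, cs)[lo]
  m <- hi - lo + 1
  out <- v
  out[ones * 2 > m] <- TRUE
  out[ones * 2 < m] <- FALSE
  out
}

#' Predict per-frame burying labels
#'
#' Scores every frame with the ensemble margin, thresholds the score, then
#' optionally applies a sliding median (majority) filter to the binary
#' labels to remove isolated flickers. The scores themselves are never
#' smoothed.
#'
#' @param model An `mb_classifier` from [train_classifier()].
#' @param features Window-feature data frame.
#' @param threshold Decision threshold on the margin (default 0).
#' @param smooth_radius_frames Median filter radius in frames (default 2;
#'   0 disables smoothing so labels are exactly the sign of the score).
#' @param fps Frame rate recorded on the returned series.
#' @return A [label_series()] with `score` = margin.
#' @export
predict_frames <- function(model, features, threshold = 0,
                           smooth_radius_frames = 2, fps = 25) {
  score <- classifier_margin(model, features)
  lab <- score >= threshold
  lab <- median_smooth_logical(lab, smooth_radius_frames)
  label_series(lab, score = score, fps = fps)
}

#' Save / load a trained classifier
#'
#' The model is stored as a single RDS archive holding the serialized
#' booster bytes, the feature schema and a format version; a
#' save-load-predict round trip is bit-identical.
#'
#' @param model An `mb_classifier`.
#' @param path File path.
#' @return `load_classifier` returns the `mb_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "mb_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mb_classifier")) stop("not a classifier archive")
  model
}

# Contiguous annotated segments with constant label: the unit of
# cross-validation fold assignment (adjacent frames are near-duplicates, so
# folds must not split a segment).
annotation_segments <- function(mask) {
  n <- length(mask)
  ann <- !is.na(mask)
  if (!any(ann)) return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  brk <- c(TRUE, (ann[-1] != ann[-n]) | (ann[-1] & ann[-n] & mask[-1] != mask[-n]))
  brk[is.na(brk)] <- TRUE
  seg_id <- cumsum(brk)
  keep <- tapply(ann, seg_id, any)
  starts <- tapply(seq_len(n) - 1L, seg_id, min)
  ends <- tapply(seq_len(n) - 1L, seg_id, max) + 1L
  data.frame(start_frame = as.integer(starts[keep]),
             end_frame = as.integer(ends[keep]))
}

#' Segment-stratified k-fold cross-validation of the classifier
#'
#' Contiguous annotated segments (runs of identically-labeled annotated
#' frames) are dealt whole into folds — never split — because adjacent
#' frames are nearly identical and frame-level shuffling would leak the
#' test set into training. Segments are shuffled with the given seed and
#' assigned greedily to the currently smallest fold. Reports per-class
#' accuracies over the pooled held-out predictions:
#' `acc_burying = TP / (TP + FN)` and `acc_nonburying = TN / (TN + FP)`.
#'
#' @param features Window-feature data frame.
#' @param labels A [label_series()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and training.
#' @param ... Passed to [train_classifier()] (e.g. `n_rounds`).
#' @return A list of class `cv_report`: `acc_burying`, `acc_nonburying`,
#'   `n_frames_annotated`, `confusion` (tp, fn, tn, fp), `k`, `n_segments`.
#' @export
cross_validate <- function(features, labels, k = 5, seed = 0L, ...) {
  if (k < 2) stop("k must be >= 2")
  m <- label_mask(labels)
  segs <- annotation_segments(m)
  if (nrow(segs) < k) stop("fewer annotated segments than folds")
  segs$fold <- NA_integer_
  with_seed(seed, {
    ord <- sample.int(nrow(segs))
    sizes <- numeric(k)
    for (s in ord) {
      f <- which.min(sizes)
      segs$fold[s] <- f
      sizes[f] <- sizes[f] + (segs$end_frame[s] - segs$start_frame[s])
    }
  })
  tp <- fn <- tn <- fp <- 0L
  for (f in seq_len(k)) {
    test_rows <- unlist(lapply(which(segs$fold == f), function(s) {
      (segs$start_frame[s] + 1):segs$end_frame[s]
    }))
    train_mask <- m
    train_mask[test_rows] <- NA
    if (length(unique(train_mask[!is.na(train_mask)])) < 2) {
      warning(sprintf("fold %d skipped: training labels single-class", f))
      next
    }
    model <- train_classifier(features, label_series(train_mask),
                              seed = seed, ...)
    pred <- classifier_margin(model, features[test_rows, , drop = FALSE]) >= 0
    truth <- m[test_rows]
    use <- !is.na(truth)
    tp <- tp + sum(pred[use] & truth[use])
    fn <- fn + sum(!pred[use] & truth[use])
    tn <- tn + sum(!pred[use] & !truth[use])
    fp <- fp + sum(pred[use] & !truth[use])
  }
  structure(list(
    acc_burying = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    acc_nonburying = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_frames_annotated = sum(!is.na(m)),
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    k = k, n_segments = nrow(segs)), class = "cv_report")
}

#' Import manual annotations
#'
#' Reads either a per-frame CSV with columns `frame` and `label`
#' (positive/negative/unannotated), or an event-style export with columns
#' `behavior`, `start_s`, `stop_s` (one row per scored bout) which is
#' expanded to frames at the stated rate; frames outside every event are
#' negative.
#'
#' @param path CSV file.
#' @param fps Frames per second used to convert event times to frames.
#' @param n_frames Total frames in the session (required for event format).
#' @return A [label_series()].
#' @export
read_annotations <- function(path, fps = 25, n_frames = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("frame", "label") %in% names(df))) {
    n <- if (is.null(n_frames)) max(df$frame) + 1L else n_frames
    lab <- rep("unannotated", n)
    lab[df$frame + 1L] <- df$label
    return(label_series(lab, fps = fps))
  }
  if (all(c("behavior", "start_s", "stop_s") %in% names(df))) {
    if (is.null(n_frames)) stop("n_frames required for event-format annotations")
    m <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(df))) {
      s <- max(0L, as.integer(floor(df$start_s[i] * fps)))
      e <- min(n_frames, as.integer(ceiling(df$stop_s[i] * fps)))
      if (e > s) m[(s + 1):e] <- TRUE
    }
    return(label_series(m, fps = fps))
  }
  stop("unrecognized annotation format: need (frame,label) or (behavior,start_s,stop_s)")
}
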