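#' Specification of a synthetic marble-burying session
#'
#' Bundles the parameters of the simulated assay. Defaults mirror the
#' standard protocol this package targets: a 26.6 x 42.5 cm cage filmed
#' top-down at 25 frames per second for 30 minutes. The animal is simulated
#' as a confined random walk (Ornstein-Uhlenbeck velocity with reflecting
#' walls) into which `n_bouts` contiguous low-speed "burying" epochs are
#' embedded, placed near a corner of the arena with probability
#' `corner_bias` each.
#'
#' @param duration_s Session length in seconds (default 1800 = 30 min).
#' @param fps Frames per second (default 25).
#' @param arena_w_cm,arena_h_cm Arena floor dimensions in cm.
#' @param px_per_cm Rendering resolution; the default 10 px/cm gives a
#'   266 x 425 px arena crop.
#' @param n_bouts Number of burying bouts to embed.
#' @param bout_duration_s_mean,bout_duration_s_sd Bout-length distribution
#'   (Gaussian, truncated to be positive), seconds.
#' @param corner_bias Probability in `[0, 1]` that a bout is anchored in a
#'   corner zone rather than at the animal's current position.
#' @param speed_cm_s_mean Mean locomotion speed outside bouts, cm/s. During
#'   a bout the speed scale drops to 20% of this value, which is what gives
#'   kinematic features their class signal.
#' @param body_major_cm,body_minor_cm Body-ellipse axes, cm.
#' @param seed Integer RNG seed; all generators are pure in `(spec, seed)`.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(duration_s = 1800, fps = 25,
                         arena_w_cm = 26.6, arena_h_cm = 42.5,
                         px_per_cm = 10,
                         n_bouts = 30,
                         bout_duration_s_mean = 4, bout_duration_s_sd = 2,
                         corner_bias = 0.75,
                         speed_cm_s_mean = 5,
                         body_major_cm = 6, body_minor_cm = 2.6,
                         seed = 1L) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(fps, "fps")
  stopifnot_scalar_pos(arena_w_cm, "arena_w_cm")
  stopifnot_scalar_pos(arena_h_cm, "arena_h_cm")
  if (n_bouts < 0) stop("n_bouts must be >= 0")
  if (corner_bias < 0 || corner_bias > 1) stop("corner_bias must be in [0, 1]")
  structure(list(
    duration_s = duration_s, fps = fps,
    arena_w_cm = arena_w_cm, arena_h_cm = arena_h_cm, px_per_cm = px_per_cm,
    n_bouts = as.integer(n_bouts),
    bout_duration_s_mean = bout_duration_s_mean,
    bout_duration_s_sd = bout_duration_s_sd,
    corner_bias = corner_bias, speed_cm_s_mean = speed_cm_s_mean,
    body_major_cm = body_major_cm, body_minor_cm = body_minor_cm,
    seed = as.integer(seed)
  ), class = "session_spec")
}

# Arena pixel dimensions (width, height) for a spec.
spec_arena_px <- function(spec) {
  c(w = round(spec$arena_w_cm * spec$px_per_cm),
    h = round(spec$arena_h_cm * spec$px_per_cm))
}

#' Arena geometry implied by a session spec
#' @param spec A [session_spec()].
#' @return An [arena_geometry()] whose corners are the rendered image corners.
#' @export
spec_arena <- function(spec) {
  d <- spec_arena_px(spec)
  arena_geometry(rbind(c(0, 0), c(d[["w"]], 0),
                       c(d[["w"]], d[["h"]]), c(0, d[["h"]])),
                 width_cm = spec$arena_w_cm, height_cm = spec$arena_h_cm)
}

# Schedule n non-overlapping bout intervals (frames, half-open) inside
# [0, n_frames), separated by >= 2 negative frames so that each bout is
# exactly one run of positive labels.
schedule_bouts <- function(n_frames, n_bouts, dur_mean_s, dur_sd_s, fps) {
  if (n_bouts == 0) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  dur_s <- numeric(n_bouts)
  for (i in seq_len(n_bouts)) {
    d <- rnorm(1, dur_mean_s, dur_sd_s)
    while (d <= 0) d <- rnorm(1, dur_mean_s, dur_sd_s)
    dur_s[i] <- d
  }
  len <- pmax(1L, as.integer(round(dur_s * fps)))
  gap <- 2L
  free <- n_frames - sum(len) - gap * (n_bouts + 1L)
  if (free < 0) stop("bouts do not fit in the session at the requested rate")
  # split the free frames into n_bouts + 1 random gaps
  cuts <- sort(runif(n_bouts))
  parts <- diff(c(0, cuts, 1))
  extra <- floor(parts * free)
  starts <- integer(n_bouts)
  pos <- 0L
  for (i in seq_len(n_bouts)) {
    pos <- pos + gap + extra[i]
    starts[i] <- pos
    pos <- pos + len[i]
  }
  data.frame(start_frame = starts, end_frame = starts + len)
}

#' Simulate a confined trajectory with embedded burying bouts
#'
#' Generates an Ornstein-Uhlenbeck velocity random walk reflected at the
#' arena walls (inset by half the body length so the rendered ellipse stays
#' inside the image). Scheduled bouts suppress the velocity scale to 20% of
#' the baseline and, for corner-anchored bouts, steer the animal into a
#' corner zone beforehand, emulating the corner-focused burying topography
#' seen in real sessions.
#'
#' @param spec A [session_spec()].
#' @return A list of class `ground_truth` with elements `track`
#'   ([frame_track()]), `labels` ([label_series()]; `positive` during true
#'   bouts), `bouts` (data frame of half-open frame intervals) and `spec`.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  n <- as.integer(round(spec$duration_s * spec$fps))
  d <- spec_arena_px(spec)
  ppc <- spec$px_per_cm
  major <- spec$body_major_cm * ppc
  minor <- spec$body_minor_cm * ppc
  if (major >= min(d)) stop("body ellipse does not fit in the arena")
  margin <- major / 2 + 2
  lo <- c(margin, margin)
  hi <- c(d[["w"]] - 1 - margin, d[["h"]] - 1 - margin)

  with_seed(spec$seed, {
    bouts <- schedule_bouts(n, spec$n_bouts, spec$bout_duration_s_mean,
                            spec$bout_duration_s_sd, spec$fps)
    nb <- nrow(bouts)
    in_bout <- rep(FALSE, n)
    for (i in seq_len(nb)) {
      in_bout[(bouts$start_frame[i] + 1):bouts$end_frame[i]] <- TRUE
    }
    # corner anchors: squares of side min(dim)/4 at each corner
    side <- min(d) / 4
    anchors <- rbind(
      c(lo[1] + side / 2, lo[2] + side / 2),
      c(hi[1] - side / 2, lo[2] + side / 2),
      c(hi[1] - side / 2, hi[2] - side / 2),
      c(lo[1] + side / 2, hi[2] - side / 2))
    corner_bout <- runif(nb) < spec$corner_bias
    bout_anchor <- anchors[sample.int(4, nb, replace = TRUE), , drop = FALSE]

    dt <- 1 / spec$fps
    tau <- 1.0                      # velocity relaxation time, seconds
    sd_stat <- spec$speed_cm_s_mean * ppc / sqrt(pi / 2)  # per-axis px/s
    a <- exp(-dt / tau)
    b <- sd_stat * sqrt(1 - a^2)
    slow <- 0.2                      # bout speed scale

    # per-frame attraction target (corner approach and corner dwell)
    approach <- as.integer(round(2 * spec$fps))
    target_x <- rep(NA_real_, n); target_y <- rep(NA_real_, n)
    for (i in seq_len(nb)) {
      if (!corner_bout[i]) next
      s <- max(0L, bouts$start_frame[i] - approach)
      idx <- (s + 1):bouts$end_frame[i]
      target_x[idx] <- bout_anchor[i, 1]
      target_y[idx] <- bout_anchor[i, 2]
    }

    x <- numeric(n); y <- numeric(n)
    pos <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    vel <- rnorm(2, 0, sd_stat)
    noise <- matrix(rnorm(2 * n), ncol = 2)
    for (i in seq_len(n)) {
      s <- if (in_bout[i]) slow else 1
      vel <- a * vel + s * b * noise[i, ]
      if (!is.na(target_x[i])) {
        pull <- (c(target_x[i], target_y[i]) - pos)
        vel <- 0.7 * vel + 1.5 * pull   # px/s toward the anchor
      }
      pos <- pos + vel * dt
      # reflect at the inset walls
      for (k in 1:2) {
        if (pos[k] < lo[k]) { pos[k] <- 2 * lo[k] - pos[k]; vel[k] <- -vel[k] }
        if (pos[k] > hi[k]) { pos[k] <- 2 * hi[k] - pos[k]; vel[k] <- -vel[k] }
        pos[k] <- clamp(pos[k], lo[k], hi[k])
      }
      x[i] <- pos[1]; y[i] <- pos[2]
    }

    # heading from displacement; carry forward when nearly stationary
    dx <- c(diff(x), 0); dy <- c(diff(y), 0)
    theta <- atan2(dy, dx) %% pi
    still <- sqrt(dx^2 + dy^2) < 1e-6
    for (i in seq_len(n)) if (still[i] && i > 1) theta[i] <- theta[i - 1]

    track <- frame_track(x, y, major, minor, theta, fps = spec$fps)
    labels <- label_series(in_bout, fps = spec$fps)
    bouts$duration_s <- (bouts$end_frame - bouts$start_frame) / spec$fps
    structure(list(track = track, labels = labels, bouts = bouts,
                   spec = spec), class = "ground_truth")
  })
}

# Fill a rotated ellipse into an image matrix (rows = y, cols = x, 0-based
# pixel-centred coordinates). Returns the modified matrix.
fill_ellipse <- function(img, cx, cy, major, minor, theta, value) {
  a <- major / 2; b <- minor / 2
  r0 <- max(1L, floor(cy - a) + 1L); r1 <- min(nrow(img), ceiling(cy + a) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(ncol(img), ceiling(cx + a) + 1L)
  xs <- (c0:c1) - 1 - cx
  ys <- (r0:r1) - 1 - cy
  ct <- cos(theta); st <- sin(theta)
  u <- outer(ys * st, xs * ct, "+")       # rotated coords per pixel
  v <- outer(ys * ct, xs * -st, "+")
  mask <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[mask] <- value
  img[r0:r1, c0:c1] <- sub
  img
}

#' Render a tracked session as a grayscale frame stack
#'
#' Draws a dark filled body ellipse at each track pose over a bright
#' textured bedding background, with optional i.i.d. Gaussian pixel noise;
#' a stand-in for the overhead camera video that the tracker consumes.
#'
#' @param track A [frame_track()] (all frames must be valid and in-bounds).
#' @param spec The [session_spec()] that produced the track (supplies arena
#'   pixel dimensions and texture).
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units,
#'   images are in `[0, 1]`).
#' @param seed RNG seed for texture and noise (defaults to `spec$seed`).
#' @return A numeric array `height x width x n_frames` in `[0, 1]`.
#' @export
render_frames <- function(track, spec, noise_sd = 0, seed = spec$seed) {
  d <- spec_arena_px(spec)
  w <- d[["w"]]; h <- d[["h"]]
  if (any(track$major_px >= min(w, h), na.rm = TRUE)) {
    stop("body ellipse larger than the arena")
  }
  n <- nrow(track)
  with_seed(seed, {
    coarse <- matrix(runif(ceiling(h / 8 + 2) * ceiling(w / 8 + 2), 0.68, 0.85),
                     nrow = ceiling(h / 8 + 2))
    bg <- bilinear_upsample(coarse, h, w)
    frames <- array(0, dim = c(h, w, n))
    for (i in seq_len(n)) {
      f <- bg
      if (isTRUE(track$valid[i])) {
        f <- fill_ellipse(f, track$x_px[i], track$y_px[i],
                          track$major_px[i], track$minor_px[i],
                          track$theta_rad[i], 0.15)
      }
      if (noise_sd > 0) f <- f + rnorm(h * w, 0, noise_sd)
      frames[, , i] <- clamp(f, 0, 1)
    }
    frames
  })
}

#' Degrade a ground-truth label series into noisy observer annotations
#'
#' Emulates an imperfect human annotator: each true positive frame is
#' flipped to negative with probability `miss_rate` and each true negative
#' to positive with probability `false_alarm_rate`, independently.
#' Unannotated frames are untouched.
#'
#' @param truth A [label_series()].
#' @param miss_rate,false_alarm_rate Flip probabilities in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A new [label_series()].
#' @export
make_observer_labels <- function(truth, miss_rate, false_alarm_rate, seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1 || false_alarm_rate < 0 ||
      false_alarm_rate > 1) stop("rates must be in [0, 1]")
  m <- label_mask(truth)
  with_seed(seed, {
    u <- runif(length(m))
    out <- m
    out[which(m)] <- u[which(m)] >= miss_rate
    out[which(!m)] <- u[which(!m)] < false_alarm_rate
    label_series(out, fps = track_fps(truth))
  })
}

#' Gaussian per-frame feature table with known class separation
#'
#' Draws one feature vector per frame from class-conditional Gaussians:
#' the first `n_informative` axes differ in mean by `class_separation`
#' between burying and non-burying frames (so a single informative axis has
#' Bayes accuracy `pnorm(class_separation / 2)` at `noise_sd = 1`), the
#' remaining axes are pure noise. This is the classifier's
#' parameter-recovery surface.
#'
#' @param labels A [label_series()] giving the per-frame classes.
#' @param class_separation Mean difference per informative axis (>= 0).
#' @param noise_sd Within-class standard deviation on every axis.
#' @param n_features Total number of feature columns.
#' @param n_informative Number of informative axes (default 2).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `f1 ... f<n_features>`.
#' @export
make_feature_table <- function(labels, class_separation, noise_sd = 1,
                               n_features = 8, n_informative = 2, seed = 1L) {
  if (class_separation < 0) stop("class_separation must be >= 0")
  m <- label_mask(labels)
  n <- length(m)
  with_seed(seed, {
    x <- matrix(rnorm(n * n_features, 0, noise_sd), nrow = n)
    shift <- ifelse(is.na(m), 0, ifelse(m, 0.5, -0.5)) * class_separation
    for (j in seq_len(n_informative)) x[, j] <- x[, j] + shift
    colnames(x) <- paste0("f", seq_len(n_features))
    as.data.frame(x)
  })
}

#' Balance annotations by subsampling negative frames
#'
#' Emulates the annotation workflow used to train the classifier: not every
#' frame of a session is labeled — instead annotators label all burying
#' bouts plus enough surrounding non-burying footage to obtain a roughly
#' equal class distribution. Positive frames stay annotated; each negative
#' run keeps a random contiguous chunk, sized so that total negatives
#' approximately equal `ratio` times the positives; the rest becomes
#' `unannotated`.
#'
#' @param labels A fully annotated [label_series()].
#' @param ratio Target negatives : positives ratio (default 1).
#' @param seed Integer RNG seed.
#' @return A [label_series()] with some frames set to `unannotated`.
#' @export
subsample_annotations <- function(labels, ratio = 1, seed = 1L) {
  m <- label_mask(labels)
  n_pos <- sum(m, na.rm = TRUE)
  runs <- logical_runs(!m & !is.na(m))
  target <- ratio * n_pos
  total_neg <- sum(runs$end_frame - runs$start_frame)
  if (total_neg <= target || n_pos == 0) return(labels)
  with_seed(seed, {
    out <- m
    keep_frac <- target / total_neg
    for (i in seq_len(nrow(runs))) {
      s <- runs$start_frame[i]; e <- runs$end_frame[i]
      len <- e - s
      keep <- round(len * keep_frac)
      if (keep >= len) next
      drop_from <- s + sample.int(keep + 1, 1) - 1L
      idx <- (drop_from + 1):(drop_from + (len - keep))
      out[idx] <- NA
    }
    label_series(out, fps = track_fps(labels))
  })
}

# Solve for the circular-segment geometry that occludes fraction f of a
# disk: returns the signed distance from the centre to the chord (positive
# when less than half the disk is covered).
chord_offset <- function(f, radius) {
  if (f <= 0) return(radius + 1)
  if (f >= 1) return(-radius - 1)
  g <- function(th) (th - sin(th)) / (2 * pi) - f
  th <- stats::uniroot(g, c(0, 2 * pi), tol = 1e-12)$root
  radius * cos(th / 2)
}

#' Synthetic end-of-test marble image with known per-marble coverage
#'
#' Renders blue disks laid out on a grid over a bedding-colored textured
#' background; marble `i` is occluded by a bedding-colored circular-segment
#' mask covering fraction `coverage[i]` of its area (the chord offset is
#' computed analytically from the requested area fraction, at a random
#' occlusion direction per marble).
#'
#' @param n_marbles Number of marbles (default 20, laid out in 4 rows of 5
#'   when square-ish).
#' @param coverage Numeric vector of requested occlusion fractions in
#'   `[0, 1]`, recycled to `n_marbles`.
#' @param radius_px Marble radius in pixels.
#' @param seed Integer RNG seed.
#' @return A list: `image` (h x w x 3 RGB array in `[0, 1]`) and `truth`, a
#'   data frame with per-marble `cx_px`, `cy_px`, requested `coverage`,
#'   rasterized `visible_px` and `full_px` pixel counts.
#' @export
make_marble_image <- function(n_marbles = 20, coverage = 0, radius_px = 20,
                              seed = 1L) {
  coverage <- rep_len(coverage, n_marbles)
  if (any(coverage < 0 | coverage > 1)) stop("coverage must be in [0, 1]")
  ncol_g <- ceiling(sqrt(n_marbles))
  nrow_g <- ceiling(n_marbles / ncol_g)
  pitch <- 4 * radius_px
  w <- ncol_g * pitch; h <- nrow_g * pitch
  bedding <- c(0.79, 0.64, 0.45)
  blue <- c(0.12, 0.30, 0.78)
  with_seed(seed, {
    img <- array(0, dim = c(h, w, 3))
    coarse_n <- ceiling(h / 6 + 2) * ceiling(w / 6 + 2)
    for (k in 1:3) {
      coarse <- matrix(bedding[k] + runif(coarse_n, -0.05, 0.05),
                       nrow = ceiling(h / 6 + 2))
      img[, , k] <- bilinear_upsample(coarse, h, w)
    }
    truth <- data.frame(id = seq_len(n_marbles), cx_px = NA_real_,
                        cy_px = NA_real_, coverage = coverage,
                        visible_px = NA_integer_, full_px = NA_integer_)
    for (i in seq_len(n_marbles)) {
      gr <- (i - 1) %/% ncol_g; gc <- (i - 1) %% ncol_g
      cx <- gc * pitch + pitch / 2; cy <- gr * pitch + pitch / 2
      phi <- runif(1, 0, 2 * pi)
      doff <- chord_offset(coverage[i], radius_px)
      xs <- (max(1, floor(cx - radius_px)):min(w, ceiling(cx + radius_px) + 1)) - 1
      ys <- (max(1, floor(cy - radius_px)):min(h, ceiling(cy + radius_px) + 1)) - 1
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      disk <- dx^2 + dy^2 <= radius_px^2
      u <- dx * cos(phi) + dy * sin(phi)
      visible <- disk & (u < doff)
      for (k in 1:3) {
        sub <- img[ys + 1, xs + 1, k]
        sub[visible] <- blue[k] + runif(sum(visible), -0.03, 0.03)
        img[ys + 1, xs + 1, k] <- sub
      }
      truth$cx_px[i] <- cx; truth$cy_px[i] <- cy
      truth$visible_px[i] <- sum(visible)
      truth$full_px[i] <- sum(disk)
    }
    img <- clamp(img, 0, 1)
    list(image = img, truth = truth)
  })
}
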