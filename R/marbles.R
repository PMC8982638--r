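#' Default HSV range for blue glass marbles
#'
#' Hue/saturation/value window (each in `[0, 1]`) that isolates blue marbles
#' from light bedding; tune per setup since marble and bedding colors vary.
#'
#' @return Named list with `h_min`, `h_max`, `s_min`, `v_min`, `v_max`.
#' @export
blue_marble_range <- function() {
  list(h_min = 0.50, h_max = 0.75, s_min = 0.30, v_min = 0.15, v_max = 1.0)
}

#' Segment marbles in a color image by HSV thresholding
#'
#' Converts the image to hue/saturation/value, keeps pixels inside
#' `color_range`, labels connected components, discards components outside
#' the `[min_area_px, max_area_px]` window, and assigns stable ids in
#' row-major order of the component centroids (top row of marbles first,
#' left to right).
#'
#' @param image RGB array `h x w x 3` in `[0, 1]`.
#' @param color_range List as returned by [blue_marble_range()].
#' @param min_area_px,max_area_px Component area limits in pixels.
#' @return A list of class `marble_masks`: `labels` (integer matrix, 0 =
#'   background, ids in reading order) and `areas_px2`, `cx_px`, `cy_px`
#'   per component. Zero components yields an empty result with a warning.
#' @export
segment_marbles <- function(image, color_range = blue_marble_range(),
                            min_area_px = 30, max_area_px = Inf) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) stop("need an RGB image")
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  keep <- hsv[1, ] >= color_range$h_min & hsv[1, ] <= color_range$h_max &
    hsv[2, ] >= color_range$s_min &
    hsv[3, ] >= color_range$v_min & hsv[3, ] <= color_range$v_max
  mask <- matrix(keep, nrow = h, ncol = w)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  ok <- which(areas >= min_area_px & areas <= max_area_px)
  if (!length(ok)) {
    warning("no marble-sized components found")
    return(structure(list(labels = matrix(0L, h, w), areas_px2 = numeric(0),
                          cx_px = numeric(0), cy_px = numeric(0)),
                     class = "marble_masks"))
  }
  cx <- cy <- numeric(length(ok))
  for (j in seq_along(ok)) {
    px <- which(lab == ok[j], arr.ind = TRUE)
    cx[j] <- mean(px[, 2] - 1); cy[j] <- mean(px[, 1] - 1)
  }
  # row-major ordering: cluster centroids into rows, then sort by x
  typical_r <- sqrt(median(areas[ok]) / pi)
  o <- order(cy)
  row_id <- integer(length(ok))
  rid <- 1L; row_id[o[1]] <- 1L
  if (length(o) > 1) {
    for (j in 2:length(o)) {
      if (cy[o[j]] - cy[o[j - 1]] > typical_r) rid <- rid + 1L
      row_id[o[j]] <- rid
    }
  }
  ord <- order(row_id, cx)
  relab <- matrix(0L, h, w)
  for (j in seq_along(ord)) relab[lab == ok[ord[j]]] <- j
  structure(list(labels = relab, areas_px2 = areas[ok][ord],
                 cx_px = cx[ord], cy_px = cy[ord]),
            class = "marble_masks")
}

#' Per-marble coverage from segmented masks
#'
#' Coverage is `clamp(1 - visible / baseline, 0, 1)` per marble; a marble
#' is `buried` when coverage reaches `burial_threshold`. When
#' `expected_n` exceeds the number of detected components, the missing
#' marbles are assumed fully covered (coverage 1); a mismatch is flagged,
#' not fatal.
#'
#' @param masks A `marble_masks` from [segment_marbles()].
#' @param baseline_area_px2 Full (uncovered) marble area: a scalar, or one
#'   value per detected marble, typically from a pre-test image; by default
#'   the median detected area.
#' @param burial_threshold Coverage at which a marble counts as buried.
#'   Default 2/3; 0.5 is the other common convention.
#' @param expected_n Expected number of marbles (e.g. 20), or `NULL`.
#' @return A list of class `marble_report`: data frame `marbles` (id,
#'   visible_area_px2, baseline_area_px2, coverage, buried, detected) and
#'   totals `n_marbles_detected`, `n_buried`, `total_uncovered_area_px2`,
#'   `count_mismatch`.
#' @export
measure_coverage <- function(masks, baseline_area_px2 = NULL,
                             burial_threshold = 2 / 3, expected_n = NULL) {
  vis <- masks$areas_px2
  nd <- length(vis)
  baseline <- baseline_area_px2 %||% if (nd) median(vis) else NA_real_
  if (any(baseline <= 0, na.rm = TRUE)) stop("baseline area must be positive")
  baseline <- rep_len(baseline, nd)
  n_total <- max(nd, expected_n %||% nd)
  df <- data.frame(
    id = seq_len(n_total),
    visible_area_px2 = c(vis, rep(0, n_total - nd)),
    baseline_area_px2 = c(baseline, rep(mean(baseline), n_total - nd)),
    detected = c(rep(TRUE, nd), rep(FALSE, n_total - nd)))
  df$coverage <- clamp(1 - df$visible_area_px2 / df$baseline_area_px2, 0, 1)
  df$buried <- df$coverage >= burial_threshold
  mismatch <- !is.null(expected_n) && nd != expected_n
  if (mismatch) {
    warning(sprintf("detected %d marbles but expected %d", nd, expected_n))
  }
  structure(list(marbles = df,
                 n_marbles_detected = nd,
                 n_buried = sum(df$buried),
                 total_uncovered_area_px2 = sum(df$visible_area_px2),
                 burial_threshold = burial_threshold,
                 count_mismatch = mismatch),
            class = "marble_report")
}

# Spearman rank correlation with a permutation p-value: exhaustive over all
# n! orderings when n <= 7, Monte Carlo otherwise.
spearman_perm <- function(x, y, n_mc = 10000, seed = 1L) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7) {
    perms <- permutations_all(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    p <- with_seed(seed, {
      rhos <- replicate(n_mc, cor(rx, sample(ry)))
      (sum(abs(rhos) >= abs(rho) - 1e-12) + 1) / (n_mc + 1)
    })
  }
  list(rho = rho, p_value = p)
}

# All permutations of 1..n (n small).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Compare image-based, visual and classifier scorings across animals
#'
#' Pairs per-animal burial scores obtained by different methods (e.g.
#' image-measured uncovered area, visually counted buried marbles, total
#' classifier burying time) and quantifies their agreement with Spearman
#' rank correlations; p-values come from an exact permutation null for
#' small cohorts (n <= 7; exhaustive over all orderings), Monte Carlo
#' permutation otherwise.
#'
#' @param image_scores,visual_counts Numeric vectors, one value per animal.
#' @param classifier_totals Optional third method, same length.
#' @return A list of class `scoring_comparison`: `table` (per-animal
#'   values) and one `rho`/`p_value` pair per method pairing.
#' @export
compare_scorings <- function(image_scores, visual_counts,
                             classifier_totals = NULL) {
  n <- length(image_scores)
  if (n < 3) stop("need at least 3 paired records")
  if (length(visual_counts) != n) stop("unequal lengths")
  out <- list(table = data.frame(animal = seq_len(n),
                                 image = image_scores, visual = visual_counts))
  out$image_vs_visual <- spearman_perm(image_scores, visual_counts)
  if (!is.null(classifier_totals)) {
    if (length(classifier_totals) != n) stop("unequal lengths")
    out$table$classifier <- classifier_totals
    out$classifier_vs_visual <- spearman_perm(classifier_totals, visual_counts)
  }
  structure(out, class = "scoring_comparison")
}
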