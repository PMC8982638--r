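#' Frame-level agreement between two label series
#'
#' Cross-tabulates two per-frame annotations (e.g. a human observer against
#' the classifier) over the frames annotated in both. Reports the four
#' quadrant counts, their fractions of the compared total, and the
#' positive-rate ratio of the first series relative to the second
#' (`normalized_positive_ratio`, observer positives / reference positives).
#'
#' @param a,b [label_series()] of equal length; `a` is the observer, `b`
#'   the reference (classifier).
#' @return A list of class `agreement_report`: counts `n_match_pos`,
#'   `n_match_neg`, `n_a_pos_b_neg`, `n_a_neg_b_pos`, `n_compared`,
#'   `fractions` (same order, summing to 1), `normalized_positive_ratio`.
#' @export
frame_agreement <- function(a, b) {
  ma <- label_mask(a); mb <- label_mask(b)
  if (length(ma) != length(mb)) stop("series lengths differ")
  use <- !is.na(ma) & !is.na(mb)
  if (!any(use)) stop("no frames annotated in both series")
  ma <- ma[use]; mb <- mb[use]
  counts <- c(
    n_match_pos = sum(ma & mb),
    n_match_neg = sum(!ma & !mb),
    n_a_pos_b_neg = sum(ma & !mb),
    n_a_neg_b_pos = sum(!ma & mb))
  structure(list(
    n_match_pos = counts[["n_match_pos"]],
    n_match_neg = counts[["n_match_neg"]],
    n_a_pos_b_neg = counts[["n_a_pos_b_neg"]],
    n_a_neg_b_pos = counts[["n_a_neg_b_pos"]],
    n_compared = sum(counts),
    fractions = counts / sum(counts),
    normalized_positive_ratio = if (sum(mb) > 0) sum(ma) / sum(mb) else NA_real_),
    class = "agreement_report")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared distribution with
#' 2 degrees of freedom. Requires n >= 8 for the kurtosis approximation.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (K2) and `p_value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (sd(x) == 0) return(list(statistic = Inf, p_value = 0))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino's transformed Z
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn transformed Z
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  t1 <- 1 - 2 / (9 * a)
  denom <- 1 + xx * sqrt(2 / (a - 4))
  t2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (t1 - t2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

normality_p <- function(x, test) {
  if (length(unique(x)) == 1) return(0)   # constant data: treat as non-normal
  if (test == "dagostino_pearson") {
    if (length(x) < 8) {
      warning("n < 8: falling back to Shapiro-Wilk for the normality gate")
      return(shapiro.test(x)$p.value)
    }
    dagostino_pearson(x)$p_value
  } else {
    shapiro.test(x)$p.value
  }
}

#' Normality-gated two-group comparison
#'
#' Implements the analysis policy of the assay: test each group for
#' normality first (D'Agostino-Pearson by default; Shapiro-Wilk as used for
#' paired pharmacology designs), then compare with a parametric test when
#' the gate passes at `alpha_normality` and a rank test otherwise.
#' Unpaired data: Student's t test vs Mann-Whitney (exact null when
#' combined n <= 12 and there are no ties, normal approximation with
#' continuity correction otherwise). Paired data: paired t vs Wilcoxon
#' signed-rank, gated on the normality of the paired differences. The
#' direction of a one-tailed test is always the caller's choice, via
#' `alternative`.
#'
#' @param x,y Numeric vectors (paired tests require equal lengths).
#' @param paired Logical.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (x vs y).
#' @param normality_test `"dagostino_pearson"` (default) or
#'   `"shapiro_wilk"`.
#' @param alpha_normality Gate level (default 0.05).
#' @param test `"auto"` (default) applies the normality gate; naming a test
#'   (`"t"`, `"mann_whitney"`, `"paired_t"`, `"wilcoxon"`) runs it directly
#'   (normality p-values are still reported).
#' @return A list of class `comparison_result`: `test_name` (one of `"t"`,
#'   `"mann_whitney"`, `"paired_t"`, `"wilcoxon"`), `statistic`, `p_value`,
#'   `tails`, `alternative`, `normality_p` (per group, or for the paired
#'   differences), `normality_test`, `parametric`.
#' @export
group_compare <- function(x, y, paired = FALSE,
                          alternative = c("two.sided", "greater", "less"),
                          normality_test = c("dagostino_pearson", "shapiro_wilk"),
                          alpha_normality = 0.05,
                          test = c("auto", "t", "mann_whitney", "paired_t",
                                   "wilcoxon")) {
  alternative <- match.arg(alternative)
  normality_test <- match.arg(normality_test)
  test <- match.arg(test)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per group")
  if (test %in% c("paired_t", "wilcoxon")) paired <- TRUE
  if (test %in% c("t", "mann_whitney")) paired <- FALSE
  if (paired && length(x) != length(y)) stop("paired groups must have equal lengths")

  np <- function(v) {
    if (test == "auto") normality_p(v, normality_test) else
      suppressWarnings(tryCatch(normality_p(v, normality_test),
                                error = function(e) NA_real_))
  }
  if (paired) {
    d <- x - y
    norm_p <- c(differences = np(d))
  } else {
    norm_p <- c(x = np(x), y = np(y))
  }
  parametric <- if (test == "auto") all(norm_p >= alpha_normality) else
    test %in% c("t", "paired_t")

  if (paired && all(x == y)) {
    # no effect whatsoever; rank tests are undefined on all-zero differences
    res <- list(statistic = 0, p.value = 1)
    test_name <- if (parametric) "paired_t" else "wilcoxon"
  } else if (parametric) {
    res <- t.test(x, y, paired = paired, var.equal = !paired,
                  alternative = alternative)
    test_name <- if (paired) "paired_t" else "t"
  } else if (paired) {
    res <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, alternative = alternative,
                  exact = length(x) <= 12, correct = TRUE))
    test_name <- "wilcoxon"
  } else {
    res <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative,
                  exact = (length(x) + length(y)) <= 12, correct = TRUE))
    test_name <- "mann_whitney"
  }
  structure(list(
    test_name = test_name,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    tails = if (alternative == "two.sided") "two" else "one",
    alternative = alternative,
    normality_p = norm_p,
    normality_test = normality_test,
    parametric = parametric), class = "comparison_result")
}
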