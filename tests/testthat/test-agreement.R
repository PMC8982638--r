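test_that("frame agreement tallies the four quadrants exactly", {
  gt <- make_trajectory(quick_spec(seed = 81, duration_s = 400, n_bouts = 20))
  obs <- make_observer_labels(gt$labels, 0.15, 0.08, seed = 2)

  agr <- frame_agreement(obs, gt$labels)
  a <- label_mask(obs); b <- label_mask(gt$labels)
  expect_equal(agr$n_match_pos, sum(a & b))
  expect_equal(agr$n_match_neg, sum(!a & !b))
  expect_equal(agr$n_a_pos_b_neg, sum(a & !b))
  expect_equal(agr$n_a_neg_b_pos, sum(!a & b))
  expect_equal(agr$n_match_pos + agr$n_match_neg + agr$n_a_pos_b_neg +
                 agr$n_a_neg_b_pos, agr$n_compared)
  expect_equal(sum(agr$fractions), 1)
  expect_equal(agr$normalized_positive_ratio, sum(a) / sum(b))
})

test_that("agreement handles identical, complemented and partial series", {
  lab <- label_series(c(TRUE, TRUE, FALSE, FALSE, TRUE))
  same <- frame_agreement(lab, lab)
  expect_equal(same$n_a_pos_b_neg, 0)
  expect_equal(same$n_a_neg_b_pos, 0)
  expect_equal(same$normalized_positive_ratio, 1)

  comp <- frame_agreement(lab, label_series(!label_mask(lab)))
  expect_equal(comp$n_match_pos, 0)
  expect_equal(comp$n_match_neg, 0)

  # unannotated frames in either series are excluded
  a <- label_series(c("positive", "unannotated", "negative", "positive"))
  b <- label_series(c("positive", "positive", "unannotated", "negative"))
  part <- frame_agreement(a, b)
  expect_equal(part$n_compared, 2)

  expect_error(frame_agreement(lab, label_series(TRUE)), "lengths")
  expect_error(frame_agreement(label_series("unannotated"),
                               label_series("positive")), "no frames")
})

test_that("swapping the series transposes the off-diagonal quadrants", {
  gt <- make_trajectory(quick_spec(seed = 82, duration_s = 100, n_bouts = 6))
  obs <- make_observer_labels(gt$labels, 0.2, 0.1, seed = 3)
  ab <- frame_agreement(obs, gt$labels)
  ba <- frame_agreement(gt$labels, obs)
  expect_equal(ab$n_a_pos_b_neg, ba$n_a_neg_b_pos)
  expect_equal(ab$n_a_neg_b_pos, ba$n_a_pos_b_neg)
  expect_equal(ab$n_match_pos, ba$n_match_pos)
  expect_equal(ab$normalized_positive_ratio,
               1 / ba$normalized_positive_ratio)
})

test_that("the omnibus normality test reproduces reference values", {
  # frozen reference values computed independently with the standard
  # skewness/kurtosis Z transformations
  x1 <- sin(1:20) * 3 + (1:20) / 10
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 3.9949299617, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.1356787960, tolerance = 1e-9)

  x2 <- c(0.5, 1.2, -0.3, 2.4, 0.9, -1.1, 0.2, 0.7, 1.5, -0.6, 3.2, 0.1)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 1.1438748435, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.5644308381, tolerance = 1e-9)

  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  # strongly non-normal data is rejected
  set.seed(1)
  expect_lt(dagostino_pearson(rexp(100))$p_value, 0.001)
})

test_that("the normality gate selects the right branch", {
  set.seed(31)
  xn <- rnorm(15); yn <- rnorm(15)
  gn <- group_compare(xn, yn)
  expect_equal(gn$test_name, "t")
  expect_true(gn$parametric)

  xs <- rlnorm(15, sdlog = 2); ys <- rlnorm(15, sdlog = 2)
  gs <- group_compare(xs, ys)
  expect_equal(gs$test_name, "mann_whitney")
  expect_false(gs$parametric)

  gp <- group_compare(xn, xn + rnorm(15, 0, 0.5), paired = TRUE)
  expect_equal(gp$test_name, "paired_t")
  expect_length(gp$normality_p, 1)   # paired gate acts on the differences

  expect_error(group_compare(1:2, 1:5), "n >= 3")
  expect_error(group_compare(1:4, 1:5, paired = TRUE), "equal lengths")
})

test_that("identical paired samples give p = 1", {
  x <- c(3.2, 4.1, 5.0, 2.8, 3.9, 4.4, 5.1, 3.3)
  g <- group_compare(x, x, paired = TRUE)
  expect_gte(g$p_value, 0.99)
})

test_that("exact Mann-Whitney matches exhaustive rank enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0; all C(6,3) = 20 rank assignments enumerated
  g <- group_compare(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                     test = "mann_whitney")
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1 / 20)

  # independent enumeration oracle for a second example
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(4.0, 6.2, 5.9)
  g2 <- group_compare(x, y, alternative = "less", test = "mann_whitney")
  pooled <- c(x, y)
  combs <- combn(7, 4)
  r <- rank(pooled)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - 4 * 5 / 2)
  expect_equal(g2$p_value, mean(u_all <= u_obs))
})

test_that("shifted Gaussians are detected with high power", {
  set.seed(77)
  rej <- mean(replicate(200, {
    group_compare(rnorm(20), rnorm(20) + 3)$p_value < 0.05
  }))
  expect_gt(rej, 0.99)
})

test_that("the gated procedure keeps its nominal size under the null", {
  set.seed(55)
  rej_norm <- mean(replicate(400, group_compare(rnorm(12),
                                                rnorm(12))$p_value < 0.05))
  rej_skew <- mean(replicate(400, group_compare(rlnorm(12, sdlog = 1.5),
                                                rlnorm(12, sdlog = 1.5))$p_value < 0.05))
  expect_lt(abs(rej_norm - 0.05), 0.03)
  expect_lt(abs(rej_skew - 0.05), 0.03)
})
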