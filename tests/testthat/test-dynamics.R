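test_that("feature change is after minus before, componentwise", {
  before <- list(gpar = 0.95, tbr = 0.30, par = 0.30, tcr = 0.45)
  after <- list(gpar = 0.60, tbr = 0.25, par = 0.45, tcr = 0.40)
  d <- feature_change(before, after)
  expect_equal(d[["par"]], 0.15)
  expect_equal(d[["gpar"]], -0.35)
  expect_equal(feature_change(before, before),
               c(gpar = 0, tbr = 0, par = 0, tcr = 0))
  # a missing side yields a missing delta
  d2 <- feature_change(list(gpar = 0.9), after)
  expect_true(is.na(d2[["par"]]))
  expect_equal(d2[["gpar"]], -0.3)
})

test_that("first derivative is the pairwise difference sequence", {
  expect_equal(first_derivative(c(1, 1, 2, 4)), c(0, 1, 2))
  expect_equal(first_derivative(rep(3, 6)), rep(0, 5))
  expect_length(first_derivative(5), 0)
  set.seed(73)
  x <- rnorm(30)
  loop <- vapply(2:30, function(i) x[i] - x[i - 1], numeric(1))
  expect_equal(first_derivative(x), loop)
  # differencing a cumulative sum recovers the increments exactly
  inc <- rnorm(20)
  expect_equal(first_derivative(cumsum(inc)), inc[-1])
})

test_that("series derivatives are indexed by the later timepoint and respect gaps", {
  s <- feature_series("p", c(1, 2, 3, 5, 6), par = c(0.3, 0.32, 0.31, 0.5, 0.52))
  d <- first_derivative(s, "par")
  expect_equal(d$timepoint, c(2, 3, 5, 6))
  expect_equal(d$delta, c(0.02, -0.01, NA, 0.02))
  # a missing value propagates, never interpolated
  s2 <- feature_series("p", 1:4, par = c(0.3, NA, 0.4, 0.45))
  expect_equal(first_derivative(s2, "par")$delta, c(NA, NA, 0.05))
})

test_that("onset detection finds a constructed rolling jump and abstains on flat series", {
  par_v <- c(0.30, 0.30, 0.31, 0.30, 0.31, 0.45, 0.50)
  s <- feature_series("p", 1:7, par = par_v,
                      tbr = 0.6 - par_v, tcr = 0.8 - par_v)
  rep_ <- detect_rolling_onset(s)
  expect_equal(rep_$onset_index, 6)
  expect_equal(rep_$magnitude, 0.14)
  expect_equal(unname(rep_$per_descriptor_votes), c(6L, 6L, 6L))

  flat <- feature_series("p", 1:5, par = rep(0.3, 5), tbr = rep(0.5, 5),
                         tcr = rep(0.6, 5))
  expect_true(is.na(detect_rolling_onset(flat)$onset_index))

  # PAR alone decides when the other descriptors abstain
  s3 <- feature_series("p", 1:7, par = par_v, tbr = rep(0.5, 7),
                       tcr = rep(0.6, 7))
  expect_equal(detect_rolling_onset(s3)$onset_index, 6)

  # disagreement with no majority falls back to the PAR candidate
  s4 <- feature_series("p", 1:6, par = c(0.3, 0.5, 0.3, 0.3, 0.3, 0.3),
                       tbr = c(0.5, 0.5, 0.3, 0.5, 0.5, 0.5),
                       tcr = c(0.6, 0.6, 0.6, 0.6, 0.3, 0.6))
  expect_equal(detect_rolling_onset(s4)$onset_index, 2)
})

test_that("onset detection is invariant to adding a constant to the series", {
  set.seed(79)
  par_v <- cumsum(c(0.3, rnorm(9, 0.01, 0.02)))
  s <- feature_series("p", 1:10, par = par_v, tbr = 1 - par_v, tcr = 1.2 - par_v)
  s_shift <- feature_series("p", 1:10, par = par_v + 5, tbr = 6 - par_v,
                            tcr = 7 - par_v)
  expect_equal(detect_rolling_onset(s)$onset_index,
               detect_rolling_onset(s_shift)$onset_index)
})

test_that("one-way ANOVA reproduces the hand-computed F and agrees with stats::oneway.test", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  expect_equal(a$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  set.seed(83)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, -0.5))
  mine <- anova_oneway(g)
  ref <- stats::oneway.test(
    y ~ grp, var.equal = TRUE,
    data = data.frame(y = unlist(g),
                      grp = rep(letters[1:3], c(8, 6, 7)))
  )
  expect_equal(mine$F, unname(ref$statistic))
  expect_equal(mine$p, unname(ref$p.value))
})

test_that("ANOVA F is invariant to shifting and scaling the observations", {
  set.seed(89)
  g <- list(rnorm(10), rnorm(10, 0.5), rnorm(12, 1))
  a <- anova_oneway(g)
  shifted <- anova_oneway(lapply(g, function(v) v + 7))
  scaled <- anova_oneway(lapply(g, function(v) v * -3.2))
  expect_equal(shifted$F, a$F)
  expect_equal(scaled$F, a$F)
})

test_that("degenerate ANOVA inputs follow the stated contract", {
  z <- anova_oneway(list(c(1, 1, 1), c(2, 2)))
  expect_true(z$degenerate)
  expect_equal(z$F, Inf)
  expect_equal(z$p, 0)
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(anova_oneway(list(1, c(2, 3))), "at least 2 values")
})

test_that("ANOVA type-I error is calibrated near the nominal 5% level", {
  set.seed(97)
  rejections <- 0L
  for (i in 1:1000) {
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    if (anova_oneway(g)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})

test_that("Pearson correlation matches hand computation and its symmetries", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_equal(pearson_r(x, c(6, 5, 1)), -5 / sqrt(28))
  set.seed(101)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_r(a, -b), -pearson_r(a, b))
  # pairwise deletion of missing values
  a2 <- a; a2[3] <- NA
  expect_equal(pearson_r(a2, b), stats::cor(a[-3], b[-3]))
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("feature series require strictly increasing timepoints", {
  expect_error(feature_series("p", c(1, 1, 2)))
  expect_error(feature_series("p", c(3, 2, 1)))
})
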