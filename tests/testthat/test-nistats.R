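# Noninferiority statistics: CIs, classification, panel margins, fun scores.

test_that("z-based CIs reproduce published bounds from summary statistics", {
  ci1 <- round_half_up(ci_from_summary(3.77, 5.69, 20))
  expect_equal(ci1, c(1.28, 6.26))
  ci2 <- round_half_up(ci_from_summary(-1.75, 7.22, 20))
  expect_equal(ci2, c(-4.91, 1.41))
  ci3 <- round_half_up(ci_from_summary(1.05, 1.93, 20))
  expect_equal(ci3, c(0.20, 1.90))
})

test_that("difference_stats matches the summary formula and degenerates sanely", {
  set.seed(71)
  x <- rnorm(20, 3, 5)
  ds <- difference_stats(x)
  expect_equal(c(ds$ci_low, ds$ci_high),
               ci_from_summary(mean(x), sd(x), 20))
  expect_true(ds$ci_low <= ds$mean_diff && ds$mean_diff <= ds$ci_high)

  dt <- difference_stats(x, method = "t")
  expect_lt(dt$ci_low, ds$ci_low)   # t interval is wider
  expect_gt(dt$ci_high, ds$ci_high)

  const <- difference_stats(c(2, 2, 2, 2))
  expect_equal(const$ci_low, 2)
  expect_equal(const$ci_high, 2)

  expect_error(difference_stats(1), "at least 2")
})

test_that("the three-way decision matches the published verdicts", {
  expect_identical(classify_noninferiority(list(ci_low = 1.28, ci_high = 6.26), -2)$decision,
                   "noninferior")
  # trailing foot: CI derived from the difference column at n = 20
  ci <- ci_from_summary(-1.75, 7.07, 20)
  expect_identical(classify_noninferiority(list(ci_low = ci[1], ci_high = ci[2]), -2)$decision,
                   "inconclusive")
  expect_identical(classify_noninferiority(list(ci_low = 0.20, ci_high = 1.90), 3)$decision,
                   "noninferior")
  expect_identical(classify_noninferiority(list(ci_low = -5, ci_high = -3), -2)$decision,
                   "inferior")
  expect_error(classify_noninferiority(list(ci_low = -1, ci_high = 1), 0), "nonzero")
})

test_that("touching the margin is not noninferior", {
  expect_identical(classify_noninferiority(list(ci_low = -2, ci_high = 1), -2)$decision,
                   "inconclusive")
  expect_identical(classify_noninferiority(list(ci_low = -1, ci_high = 3), 3)$decision,
                   "inconclusive")
})

test_that("exactly one decision fires over random CI/margin configurations", {
  set.seed(72)
  for (i in 1:2000) {
    a <- rnorm(1, 0, 3); b <- rnorm(1, 0, 3)
    ci <- list(ci_low = min(a, b), ci_high = max(a, b))
    m <- rnorm(1, 0, 2); if (m == 0) m <- 1
    dec <- classify_noninferiority(ci, m)$decision
    expect_true(dec %in% c("noninferior", "inconclusive", "inferior"))
    # antisymmetry: negating CI and margin together preserves the decision
    neg <- classify_noninferiority(list(ci_low = -ci$ci_high,
                                        ci_high = -ci$ci_low), -m)$decision
    expect_identical(neg, dec)
    # simultaneous rescaling (cm -> m) preserves the decision
    sc <- classify_noninferiority(list(ci_low = ci$ci_low / 100,
                                       ci_high = ci$ci_high / 100), m / 100)$decision
    expect_identical(sc, dec)
  }
})

test_that("normality screening behaves like Shapiro-Wilk should", {
  set.seed(73)
  passes <- replicate(100, normality_check(rnorm(20))$normal)
  expect_gte(mean(passes), 0.9)

  bimodal <- c(rnorm(10, -10, 0.5), rnorm(10, 10, 0.5))
  expect_false(normality_check(bimodal)$normal)

  expect_error(normality_check(c(1, 2)), "3 <= n")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("panel margins are medians with IQR", {
  m <- summarize_margin_panel(c(-1, -2, -2, -3, -2, -1, -2, -2, -4, -2, -2,
                                -1, -3, -2, -2),
                              "overstepping", "max_step_height_L")
  expect_equal(m$margin, -2)
  expect_equal(m$panel_n, 15)

  same <- summarize_margin_panel(rep(3, 7))
  expect_equal(same$panel_iqr, 0)
  one <- summarize_margin_panel(-5)
  expect_equal(one$margin, -5)
  expect_error(summarize_margin_panel(numeric(0)), "empty")

  # a margin object feeds straight into classification
  dec <- classify_noninferiority(list(ci_low = 1.28, ci_high = 6.26), m)
  expect_identical(dec$decision, "noninferior")
})

test_that("fun-score comparison detects uniformly higher VR enjoyment", {
  set.seed(74)
  phys <- sample(3:7, 20, replace = TRUE)
  vr <- phys + sample(1:3, 20, replace = TRUE)
  w <- wilcoxon_fun_scores(phys, vr)
  expect_lt(w$p_value, 0.001)
  expect_identical(w$direction, "vr_higher")

  w2 <- wilcoxon_fun_scores(vr, phys)
  expect_equal(w2$p_value, w$p_value, tolerance = 1e-12)
  expect_identical(w2$direction, "physical_higher")

  expect_error(wilcoxon_fun_scores(phys, phys), "all paired differences are zero")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(6.2639), 6.26)
  expect_equal(round_half_up(0.205), 0.21)
  expect_equal(round_half_up(-0.205), -0.21)
  expect_equal(round_half_up(-4.914), -4.91)
  expect_equal(round_half_up(2.5, 0), 3)
})
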