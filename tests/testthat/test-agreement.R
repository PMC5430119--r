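test_that("agreement of a series with itself is exact", {
  x <- c(2.1, 2.8, 1.4, 3.3, 0.9)
  rep <- agreement_report(x, x)
  expect_equal(rep$bias, 0)
  expect_equal(rep$precision, 0)
  expect_equal(rep$p10, 100)
  expect_equal(rep$p15, 100)
  expect_equal(rep$loa_high - rep$loa_low, 4 * rep$precision)
})

test_that("single-pair arithmetic is forced", {
  rep <- agreement_report(2.0, 1.8)
  expect_equal(rep$bias, 0.2)
  expect_equal(rep$pct_bias, 100 * 0.2 / 1.9, tolerance = 1e-12)
  expect_equal(rep$pct_bias, 10.526, tolerance = 1e-4)
  expect_equal(rep$p10, 0)   # |%bias| = 10.53 is not under 10
  expect_equal(rep$p15, 100)
})

test_that("agreement statistics match a brute-force recomputation", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:48, 1)
    ref <- runif(n, 0.5, 4)
    comp <- ref * exp(rnorm(n, 0, 0.1))
    rep <- agreement_report(ref, comp)
    oracle <- brute_agreement(ref, comp)
    for (f in names(oracle)) expect_equal(rep[[f]], oracle[[f]])
    expect_equal(rep$r2,
                 brute_weighted_r2(ref, comp, 1 / comp^2),
                 tolerance = 1e-10)
  }
})

test_that("swapping reference and comparative negates bias, keeps accuracy", {
  set.seed(31)
  ref <- runif(30, 0.5, 4); comp <- ref * exp(rnorm(30, 0, 0.15))
  a <- agreement_report(ref, comp)
  b <- agreement_report(comp, ref)
  expect_equal(a$bias, -b$bias)
  expect_equal(a$pct_bias, -b$pct_bias)
  expect_equal(a$precision, b$precision)
  expect_equal(a$p10, b$p10)
  expect_equal(a$p15, b$p15)
  expect_lte(a$p10, a$p15)
})

test_that("weighted regression R2 follows the stated conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(weighted_regression_r2(x, 2 * x), 1)
  expect_error(weighted_regression_r2(rep(2, 5), c(1, 2, 3, 4, 5)),
               "constant")
  expect_warning(r2 <- weighted_regression_r2(c(1, 2, 3, 4), c(0, 2, 3, 4)),
                 "zero weight")
  expect_error(weighted_regression_r2(c(1, 2), c(1, 2)), "at least 3")

  set.seed(7)
  for (i in 1:10) {
    x <- runif(20, 1, 5)
    y <- 0.5 + 0.8 * x + rnorm(20, 0, 0.3 * x)
    expect_equal(weighted_regression_r2(x, y),
                 brute_weighted_r2(x, y, 1 / y^2), tolerance = 1e-10)
    expect_equal(weighted_regression_r2(x, y, weighting = "reference"),
                 brute_weighted_r2(x, y, 1 / x^2), tolerance = 1e-10)
  }
})

test_that("line-vs-polynomial selection behaves on known shapes", {
  set.seed(3)
  x <- seq(20, 110, length.out = 40)
  lin <- select_line_vs_poly6(x, 5 + 0.9 * x + rnorm(40, 0, 1e-6))
  expect_equal(lin$chosen, "line")

  sig <- 100 / (1 + exp(-(x - 60) / 6)) + rnorm(40, 0, 2)
  curved <- select_line_vs_poly6(x, sig)
  expect_equal(curved$chosen, "polynomial6")
  expect_gt(curved$f_statistic, 0)

  oracle <- brute_f_poly(x, sig)
  expect_equal(curved$f_statistic, oracle$f, tolerance = 1e-8)
  expect_equal(curved$p_value, oracle$p, tolerance = 1e-8)

  expect_error(select_line_vs_poly6(x[1:8], sig[1:8]), "more than 8")

  # nesting: the polynomial can never fit worse than the line
  for (i in 1:10) {
    y <- rnorm(20)
    xx <- runif(20)
    sel <- select_line_vs_poly6(xx, y)
    expect_gte(sel$f_statistic, -1e-10)
  }
})

test_that("percent-of-function normalization anchors week 0 at 100%", {
  week <- rep(0:2, each = 4)
  ref_pc <- c(rnorm(4, 2.5, 0.1), rnorm(4, 1.5, 0.1), rnorm(4, 0.8, 0.05))
  ref_pct <- percent_of_baseline(ref_pc, week)
  expect_equal(mean(ref_pct[week == 0]), 100)

  # a marker value equal to its week-0 mean maps to 100%
  marker <- c(rnorm(4, 1, 0.05), rnorm(4, 2, 0.1), rnorm(4, 4, 0.2))
  ns <- normalize_to_function_scale(marker, week, ref_pct,
                                    direction = "increases")
  m0 <- mean(marker[week == 0])
  at_m0 <- normalize_to_function_scale(c(marker, m0), c(week, 0),
                                       c(ref_pct, 100), "increases")
  expect_equal(at_m0$marker_pct[length(marker) + 1], 100)
  # the cohort-worst (highest) marker value maps to the reference floor
  expect_equal(ns$marker_pct[which.max(marker)], min(ref_pct))

  # reference normalized against itself is the identity line
  self <- normalize_to_function_scale(ref_pc, week, ref_pct, "decreases")
  expect_equal(self$marker_pct, ref_pct, tolerance = 1e-10)

  expect_error(normalize_to_function_scale(marker[week > 0], week[week > 0],
                                           ref_pct[week > 0], "increases"),
               "week-0")
})

test_that("first significant week screens weekly change from baseline", {
  # flat series: ANOVA is not significant, no week flagged
  d <- grid_values(rep(10, 6), n_subjects = 5, noise_sd = 0.5, seed = 2)
  expect_true(is.na(first_significant_week(d$value, d$week, d$subject_id)))

  # a clean 40% drop from week 1 onward is flagged at week 1
  d2 <- grid_values(c(10, 6, 6, 6, 6, 6), n_subjects = 6, noise_sd = 0.2,
                    seed = 3)
  expect_equal(as.integer(first_significant_week(d2$value, d2$week,
                                                 d2$subject_id)), 1L)
  expect_equal(as.integer(first_significant_week(d2$value, d2$week,
                                                 d2$subject_id,
                                                 adjust = "tukey")), 1L)

  # a late change is not attributed to early weeks
  d3 <- grid_values(c(10, 10, 10, 10, 5, 4), n_subjects = 6, noise_sd = 0.3,
                    seed = 4)
  expect_gte(as.integer(first_significant_week(d3$value, d3$week,
                                               d3$subject_id)), 4L)

  one <- grid_values(c(10, 6), n_subjects = 1)
  expect_error(first_significant_week(one$value, one$week, one$subject_id),
               "at least 3 subjects")
})
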