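test_that("trapezoid AUC matches hand-computable cases", {
  expect_equal(trapezoid_auc(c(0, 10), c(100, 50)), 750)
  expect_equal(trapezoid_auc(c(0, 10), c(100, 100)), 1000)
  expect_error(trapezoid_auc(c(10, 0), c(1, 2)), "strictly increasing")
  expect_error(trapezoid_auc(c(10, 10), c(1, 2)), "strictly increasing")
  expect_error(trapezoid_auc(5, 1), "at least 2")
})

test_that("trapezoid on a convex decreasing curve bounds the integral above", {
  # 12-point sampling of 100 exp(-0.01 t): compare with the analytic
  # integral over the sampled interval and an independent numeric oracle
  tt <- paper_schedule
  cc <- 100 * exp(-0.01 * tt)
  analytic <- (100 / 0.01) * (exp(-0.01 * min(tt)) - exp(-0.01 * max(tt)))
  oracle <- stats::integrate(function(t) 100 * exp(-0.01 * t),
                             min(tt), max(tt))$value
  auc <- trapezoid_auc(tt, cc)
  expect_equal(oracle, analytic, tolerance = 1e-8)
  expect_gt(auc, analytic)
  expect_lt((auc - analytic) / analytic, 0.05)

  # convexity bound holds across random exponentials and refines monotonically
  set.seed(11)
  for (i in 1:50) {
    b <- runif(1, 10, 200); beta <- runif(1, 0.002, 0.05)
    t_end <- runif(1, 100, 400)
    coarse <- seq(0, t_end, length.out = 8)
    fine <- seq(0, t_end, length.out = 15)
    exact <- (b / beta) * (1 - exp(-beta * t_end))
    auc_coarse <- trapezoid_auc(coarse, b * exp(-beta * coarse))
    auc_fine <- trapezoid_auc(fine, b * exp(-beta * fine))
    expect_gte(auc_coarse, exact)
    expect_gte(auc_fine, exact)
    expect_lte(auc_fine, auc_coarse)
  }
})

test_that("log-linear tail integrates the fitted exponential to the threshold", {
  # exact points on 100 exp(-0.01 t): analytic oracle (C_last - 0.5)/0.01
  tt <- c(180, 240, 300)
  tail <- log_linear_tail(tt, 100 * exp(-0.01 * tt))
  expect_equal(tail$terminal_rate, 0.01, tolerance = 1e-10)
  expect_equal(tail$tail_auc, (100 * exp(-3) - 0.5) / 0.01, tolerance = 1e-8)
  expect_equal(tail$tail_auc, 447.871, tolerance = 1e-5)

  # last concentration at or below the threshold: nothing to extrapolate
  expect_equal(log_linear_tail(c(240, 300), c(0.8, 0.4))$tail_auc, 0)
  tt2 <- c(240, 300)
  expect_equal(log_linear_tail(tt2, 50 * exp(-0.02 * tt2))$tail_auc, 0)

  # rising terminal phase cannot be extrapolated
  expect_error(log_linear_tail(c(200, 250, 300), c(2, 2.5, 3)),
               "non-declining")
})

test_that("trapezoidal clearance approaches dose/(B/beta) on a dense grid", {
  tt <- seq(0, 600, by = 1)
  s <- subject_session("s1", 0, "m", 10000, tt, 100 * exp(-0.01 * tt),
                       background_conc = 0, lloq = 0)
  est <- clearance_trapezoidal(s, threshold = 0)
  expect_equal(est$method, "trapezoidal")
  expect_equal(est$clearance_ml_min, 1.0, tolerance = 0.005)
  expect_equal(est$auc, est$auc_observed + est$auc_extrapolated)
  expect_equal(est$clearance_ml_min * est$auc, 10000, tolerance = 1e-9)

  # 12-point schedule within 5% of the dense-grid oracle at threshold 0.5
  s12 <- session_on_curve(function(t) 100 * exp(-0.01 * t))
  est12 <- clearance_trapezoidal(s12, threshold = 0.5)
  dense <- subject_session("s1", 0, "m", 10000, tt, 100 * exp(-0.01 * tt),
                           background_conc = 0, lloq = 0)
  oracle <- clearance_trapezoidal(dense, threshold = 0.5)$clearance_ml_min
  expect_equal(est12$clearance_ml_min, oracle, tolerance = 0.05)

  # clearance is linear in dose for an identical curve
  s_double <- session_on_curve(function(t) 100 * exp(-0.01 * t), dose = 20000)
  expect_equal(clearance_trapezoidal(s_double)$clearance_ml_min,
               2 * clearance_trapezoidal(s12)$clearance_ml_min)
})

test_that("one-compartment fit recovers an exact monoexponential", {
  tt <- c(30, 60, 90, 120, 180, 240, 300)
  s <- subject_session("s1", 0, "m", 5000, tt, 50 * exp(-0.02 * tt), lloq = 0)
  est <- fit_one_compartment(s)
  expect_equal(est$terms[[1]]$coefficient, 50, tolerance = 1e-9)
  expect_equal(est$terms[[1]]$rate, 0.02, tolerance = 1e-9)
  expect_equal(est$clearance_ml_min, 2.0, tolerance = 1e-9)
  expect_equal(est$auc, 50 / 0.02, tolerance = 1e-6)

  # t_min = 30 drops the five distribution-phase points of the 12-point
  # schedule, leaving 7
  s12 <- session_on_curve(function(t) 50 * exp(-0.02 * t), dose = 5000)
  expect_equal(fit_one_compartment(s12, t_min = 30)$diagnostics$n_points, 7)

  expect_error(fit_one_compartment(s, t_min = 290), "fewer than 2")
  rising <- subject_session("s1", 0, "m", 5000, c(30, 60, 90), c(1, 2, 3),
                            lloq = 0)
  expect_error(fit_one_compartment(rising), "non-declining")
})

test_that("one-compartment median estimate is unbiased under 5% noise", {
  set.seed(202)
  tt <- c(30, 60, 90, 120, 180, 240, 300)
  sdlog <- sqrt(log(1 + 0.05^2))
  cl <- replicate(200, {
    cc <- 50 * exp(-0.02 * tt) * exp(rnorm(7, -sdlog^2 / 2, sdlog))
    fit_one_compartment(subject_session("s", 0, "m", 5000, tt, cc,
                                        lloq = 0))$clearance_ml_min
  })
  expect_equal(median(cl), 2.0, tolerance = 0.02)
})

test_that("two-compartment fit reproduces an exact biexponential", {
  curve <- function(t) biexp(t, 80, 0.15, 40, 0.01)
  s <- session_on_curve(curve, dose = 10000)
  est <- fit_two_compartment(s)
  expect_equal(est$auc, 80 / 0.15 + 40 / 0.01, tolerance = 1e-6)
  expect_equal(est$clearance_ml_min, 10000 / (80 / 0.15 + 40 / 0.01),
               tolerance = 1e-6)
  expect_equal(est$terms[[1]]$rate, 0.15, tolerance = 1e-4)
  expect_equal(est$terms[[2]]$rate, 0.01, tolerance = 1e-4)
  expect_gt(est$terms[[1]]$rate, est$terms[[2]]$rate)  # fast first
  expect_false(est$diagnostics$fallback)
  expect_equal(est$clearance_ml_min * est$auc, 10000, tolerance = 1e-8)
})

test_that("two-compartment recovery holds across generating clearances", {
  cfg <- cohort_config()
  for (mk in c("iohexol", "inulin")) {
    pk <- cfg$markers[[mk]]
    for (cl in c(0.6, 1.2, 2.5)) {
      tm <- compartmental_to_exponential(cl, pk$v_central, pk$v_peripheral,
                                         pk$q_intercompartmental,
                                         cfg$dose_ug[[mk]])
      s <- session_on_curve(function(t) {
        biexp(t, tm$fast$coefficient, tm$fast$rate,
              tm$slow$coefficient, tm$slow$rate)
      }, dose = cfg$dose_ug[[mk]], lloq = pk$lloq)
      est <- fit_two_compartment(s)
      expect_equal(est$clearance_ml_min, cl, tolerance = 1e-6)
    }
  }
})

test_that("degenerate single-exponential input falls back gracefully", {
  s <- session_on_curve(function(t) 50 * exp(-0.02 * t), dose = 5000)
  expect_warning(est <- fit_two_compartment(s), "fell back")
  expect_equal(est$method, "two_compartment")
  expect_true(est$diagnostics$fallback)
  expect_equal(est$clearance_ml_min, 2.0, tolerance = 1e-6)
})

test_that("two-sample formula matches the monoexponential through the points", {
  est <- clearance_two_sample(10000, 30, 90,
                              100 * exp(-0.01 * 30), 100 * exp(-0.01 * 90))
  expect_equal(est$terms[[1]]$rate, 0.01, tolerance = 1e-12)
  expect_equal(est$terms[[1]]$coefficient, 100, tolerance = 1e-9)
  expect_equal(est$clearance_ml_min, 1.0, tolerance = 1e-12)

  # any two points on B exp(-beta t) give dose*beta/B
  set.seed(5)
  for (i in 1:25) {
    b <- runif(1, 20, 300); beta <- runif(1, 0.005, 0.05)
    t1 <- runif(1, 10, 100); t2 <- t1 + runif(1, 10, 200)
    est <- clearance_two_sample(1000, t1, t2,
                                b * exp(-beta * t1), b * exp(-beta * t2))
    expect_equal(est$clearance_ml_min, 1000 * beta / b, tolerance = 1e-9)
  }

  expect_error(clearance_two_sample(1000, 30, 90, 10, 12), "non-declining")
  expect_error(clearance_two_sample(1000, 90, 30, 12, 10), "t1 < t2")
  expect_error(clearance_two_sample(1000, 30, 90, 12, -1), "positive")
})

test_that("two-sample estimate equals a two-point one-compartment fit", {
  set.seed(17)
  for (i in 1:50) {
    t1 <- runif(1, 5, 150); t2 <- t1 + runif(1, 5, 150)
    c1 <- runif(1, 5, 400); c2 <- c1 * runif(1, 0.05, 0.95)
    dose <- runif(1, 1000, 50000)
    two <- clearance_two_sample(dose, t1, t2, c1, c2)
    ses <- subject_session("s", 0, "m", dose, c(t1, t2), c(c1, c2), lloq = 0)
    one <- fit_one_compartment(ses, t_min = 0)
    expect_equal(two$clearance_ml_min, one$clearance_ml_min,
                 tolerance = 1e-12)
    expect_equal(two$auc, one$auc, tolerance = 1e-12)
  }
})

test_that("dose/AUC identity holds for every estimator", {
  curve <- function(t) biexp(t, 80, 0.15, 40, 0.01)
  s <- session_on_curve(curve, dose = 10000)
  ests <- list(clearance_trapezoidal(s),
               fit_two_compartment(s),
               fit_one_compartment(s),
               clearance_two_sample(10000, 30, 90, curve(30), curve(90)))
  for (est in ests) {
    expect_equal(est$clearance_ml_min * est$auc, 10000,
                 tolerance = 1e-9 * 10000)
    if (length(est$terms)) {
      expect_equal(est$auc,
                   sum(vapply(est$terms,
                              function(tm) tm$coefficient / tm$rate,
                              numeric(1))),
                   tolerance = 1e-9)
    }
  }
})

test_that("one-compartment overestimates clearance when the fast phase matters", {
  # inulin-like curve: a large distribution-phase AUC share means
  # dose/(B/beta) > dose/(A/alpha + B/beta); with the trapezoidal value as
  # reference the bias (reference - comparative) is negative
  cfg <- cohort_config()
  pk <- cfg$markers$inulin
  tm <- compartmental_to_exponential(2.5, pk$v_central, pk$v_peripheral,
                                     pk$q_intercompartmental, 20000)
  curve <- function(t) biexp(t, tm$fast$coefficient, tm$fast$rate,
                             tm$slow$coefficient, tm$slow$rate)
  s <- session_on_curve(curve, dose = 20000, lloq = pk$lloq)
  one <- fit_one_compartment(s)
  trap <- clearance_trapezoidal(s)
  expect_gt(one$clearance_ml_min, 2.5)
  expect_lt(trap$clearance_ml_min - one$clearance_ml_min, 0)
})
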