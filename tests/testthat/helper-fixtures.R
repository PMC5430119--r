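# shared fixtures and independent oracles used across the test files

paper_schedule <- c(0, 2, 5, 10, 20, 30, 60, 90, 120, 180, 240, 300)

# exact (bi)exponential concentrations
biexp <- function(t, a, alpha, b, beta) a * exp(-alpha * t) + b * exp(-beta * t)

# build a session whose post-dose samples lie exactly on a curve
session_on_curve <- function(curve, dose = 10000, times = paper_schedule,
                             lloq = 0, ...) {
  t_post <- times[times > 0]
  subject_session("s1", 0, "m", dose_ug = dose,
                  time_min = c(0, t_post),
                  concentration = c(0, curve(t_post)),
                  lloq = lloq, ...)
}

# brute-force recomputation of every agreement statistic, coded
# independently of agreement_report (explicit loops, no shared helpers)
brute_agreement <- function(ref, comp) {
  n <- length(ref)
  bias <- numeric(n); pct <- numeric(n)
  for (i in seq_len(n)) {
    bias[i] <- ref[i] - comp[i]
    pct[i] <- 100 * (ref[i] - comp[i]) / ((ref[i] + comp[i]) / 2)
  }
  m <- sum(bias) / n
  s <- sqrt(sum((bias - m)^2) / (n - 1))
  mp <- sum(pct) / n
  sp <- sqrt(sum((pct - mp)^2) / (n - 1))
  list(bias = m, precision = s, pct_bias = mp, pct_precision = sp,
       p10 = 100 * sum(abs(pct) < 10) / n,
       p15 = 100 * sum(abs(pct) < 15) / n,
       loa_low = m - 2 * s, loa_high = m + 2 * s)
}

# weighted least squares R^2 by explicit normal equations
brute_weighted_r2 <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  fitted <- X %*% beta
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
}

# extra-sum-of-squares F-test via explicit polynomial design matrices
brute_f_poly <- function(x, y) {
  n <- length(x)
  rss <- function(deg) {
    X <- outer(x, 0:deg, "^")
    b <- qr.solve(X, y)
    sum((y - X %*% b)^2)
  }
  ss1 <- rss(1); ss6 <- rss(6)
  f <- ((ss1 - ss6) / 5) / (ss6 / (n - 7))
  list(f = f, p = pf(f, 5, n - 7, lower.tail = FALSE))
}

# small complete subject-by-week data frame for sensitivity tests
grid_values <- function(values_by_week, n_subjects = 4, noise_sd = 0,
                        seed = 1) {
  set.seed(seed)
  weeks <- seq_along(values_by_week) - 1L
  d <- expand.grid(subject_id = sprintf("s%d", seq_len(n_subjects)),
                   week = weeks, stringsAsFactors = FALSE)
  d$value <- values_by_week[d$week + 1L] + rnorm(nrow(d), 0, noise_sd)
  d
}
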