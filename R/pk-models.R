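#' @title Clearance estimate container
#' @description Internal constructor for a `clearance_estimate`: an AUC and
#'   the dose/AUC plasma clearance, tagged by the method that produced it.
#'   The defining identity `clearance = dose / auc` is enforced here.
#' @noRd
clearance_estimate <- function(method, dose_ug, auc,
                               terms = list(),
                               auc_observed = NA_real_,
                               auc_extrapolated = NA_real_,
                               diagnostics = list()) {
  stopifnot(auc > 0)
  structure(list(method = method,
                 dose_ug = dose_ug,
                 auc = auc,
                 clearance_ml_min = dose_ug / auc,
                 terms = terms,
                 auc_observed = auc_observed,
                 auc_extrapolated = auc_extrapolated,
                 diagnostics = diagnostics),
            class = "clearance_estimate")
}

#' @export
print.clearance_estimate <- function(x, ...) {
  cat(sprintf("<clearance_estimate> method: %s\n", x$method))
  cat(sprintf("  clearance: %.4f mL/min   AUC: %.2f ug*min/mL   dose: %g ug\n",
              x$clearance_ml_min, x$auc, x$dose_ug))
  if (length(x$terms)) {
    for (tm in x$terms) {
      cat(sprintf("  term: %.4g * exp(-%.4g t)\n", tm$coefficient, tm$rate))
    }
  }
  if (!is.na(x$auc_observed)) {
    cat(sprintf("  AUC observed: %.2f   extrapolated: %.2f\n",
                x$auc_observed, x$auc_extrapolated))
  }
  if (isTRUE(x$diagnostics$fallback)) {
    cat("  note: biexponential fit fell back to a single exponential\n")
  }
  invisible(x)
}

exp_term <- function(coefficient, rate) {
  stopifnot(coefficient > 0, rate > 0)
  list(coefficient = coefficient, rate = rate)
}

#' Trapezoidal area under a concentration-time series
#'
#' Model-free AUC by linear interpolation between sampled concentrations:
#' the sum over adjacent sample pairs of
#' `(t[i+1] - t[i]) * (C[i] + C[i+1]) / 2`.
#'
#' @param time_min sample times in minutes, strictly increasing.
#' @param concentration concentrations in micrograms/mL.
#' @return AUC in micrograms*min/mL.
#' @examples
#' trapezoid_auc(c(0, 10), c(100, 50))  # 750
#' @export
trapezoid_auc <- function(time_min, concentration) {
  n <- length(time_min)
  if (n < 2L || length(concentration) != n) {
    stop("need at least 2 samples with matching times and concentrations",
         call. = FALSE)
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  dt <- diff(time_min)
  sum(dt * (concentration[-n] + concentration[-1L]) / 2)
}

#' Log-linear tail extrapolation of the AUC
#'
#' When the last measured concentration is still above a residual threshold,
#' the remaining area is estimated by fitting a terminal exponential
#' (ordinary least squares of log concentration on time over the last `k`
#' samples above the threshold) and integrating it analytically from the
#' last sample time down to the concentration threshold:
#' `tail_auc = (C_last - threshold) / lambda`.
#'
#' @param time_min,concentration terminal samples (strictly increasing
#'   times).
#' @param threshold residual concentration in micrograms/mL down to which
#'   the curve is extrapolated; default 0.5.
#' @param k number of terminal samples used for the log-linear slope;
#'   default 3.
#' @return A list with `tail_auc` (micrograms*min/mL) and `terminal_rate`
#'   (1/min; `NA` when no extrapolation was needed).
#' @export
log_linear_tail <- function(time_min, concentration, threshold = 0.5, k = 3) {
  stopifnot(length(time_min) == length(concentration))
  c_last <- concentration[length(concentration)]
  if (c_last <= threshold) {
    return(list(tail_auc = 0, terminal_rate = NA_real_))
  }
  use <- concentration > threshold
  t_use <- time_min[use]
  c_use <- concentration[use]
  n <- length(t_use)
  if (n < 2L) {
    stop("need at least 2 terminal samples above the threshold to extrapolate",
         call. = FALSE)
  }
  idx <- seq.int(max(1L, n - k + 1L), n)
  fit <- stats::lm.fit(cbind(1, t_use[idx]), log(c_use[idx]))
  lambda <- -unname(fit$coefficients[2L])
  if (!is.finite(lambda) || lambda <= 0) {
    stop("non-declining terminal phase: cannot extrapolate the tail",
         call. = FALSE)
  }
  list(tail_auc = (c_last - threshold) / lambda,
       terminal_rate = unname(lambda))
}

#' Trapezoidal plasma clearance
#'
#' Background-subtracts the session, sums the trapezoids across the sampled
#' time points, adds the log-linear tail extrapolation down to `threshold`,
#' and returns clearance = dose / AUC.
#'
#' @param session a [subject_session].
#' @param threshold residual concentration for the tail extrapolation
#'   (micrograms/mL); default 0.5.
#' @param k terminal points used for the tail slope; default 3.
#' @return A `clearance_estimate` with the observed/extrapolated AUC split.
#' @export
clearance_trapezoidal <- function(session, threshold = 0.5, k = 3) {
  session <- subtract_background(session)
  s <- session$samples
  auc_obs <- trapezoid_auc(s$time_min, s$concentration)
  tail <- log_linear_tail(s$time_min, s$concentration,
                          threshold = threshold, k = k)
  clearance_estimate("trapezoidal", session$dose_ug,
                     auc = auc_obs + tail$tail_auc,
                     auc_observed = auc_obs,
                     auc_extrapolated = tail$tail_auc,
                     diagnostics = list(terminal_rate = tail$terminal_rate,
                                        threshold = threshold, k = k))
}

#' One-compartment (monoexponential) plasma clearance
#'
#' Fits `C(t) = B exp(-beta t)` to the beta phase by ordinary least squares
#' on log-transformed concentrations, using only samples from `t_min`
#' onward (the distribution phase is assumed complete by then). Clearance
#' is `dose * beta / B` since the monoexponential AUC is `B / beta`.
#'
#' @param session a [subject_session].
#' @param t_min earliest sample time (minutes) included in the fit;
#'   default 30.
#' @param nonlinear if `TRUE`, refine the log-linear estimates by
#'   unweighted nonlinear least squares on the raw concentrations
#'   (sensitivity check); default `FALSE`.
#' @return A `clearance_estimate` with a single exponential term.
#' @export
fit_one_compartment <- function(session, t_min = 30, nonlinear = FALSE) {
  session <- subtract_background(session)
  s <- .fit_samples(session)
  s <- s[s$time_min >= t_min, , drop = FALSE]
  if (nrow(s) < 2L) {
    stop("fewer than 2 usable samples at or after t_min", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, s$time_min), log(s$concentration))
  beta <- -unname(fit$coefficients[2L])
  b <- exp(unname(fit$coefficients[1L]))
  if (!is.finite(beta) || beta <= 0) {
    stop("non-declining curve: fitted elimination rate is not positive",
         call. = FALSE)
  }
  if (nonlinear) {
    nls_fit <- try(minpack.lm::nlsLM(
      concentration ~ B * exp(-beta * time_min),
      data = s, start = list(B = b, beta = beta),
      lower = c(B = .Machine$double.eps, beta = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      cf <- stats::coef(nls_fit)
      b <- unname(cf["B"]); beta <- unname(cf["beta"])
    }
  }
  resid <- log(s$concentration) - (log(b) - beta * s$time_min)
  clearance_estimate("one_compartment", session$dose_ug,
                     auc = b / beta,
                     terms = list(exp_term(b, beta)),
                     diagnostics = list(n_points = nrow(s),
                                        log_resid_sd = stats::sd(resid),
                                        t_min = t_min))
}

# curve-stripping starting values for the biexponential fit
.strip_start <- function(time_min, concentration, k_terminal = 3) {
  n <- length(time_min)
  idx_b <- seq.int(max(1L, n - k_terminal + 1L), n)
  fit_b <- stats::lm.fit(cbind(1, time_min[idx_b]), log(concentration[idx_b]))
  beta <- -unname(fit_b$coefficients[2L])
  b <- exp(unname(fit_b$coefficients[1L]))
  if (!is.finite(beta) || beta <= 0) return(NULL)
  early <- setdiff(seq_len(n), idx_b)
  resid <- concentration[early] - b * exp(-beta * time_min[early])
  keep <- early[resid > 0]
  if (length(keep) < 2L) return(NULL)
  fit_a <- stats::lm.fit(cbind(1, time_min[keep]),
                         log(concentration[keep] - b * exp(-beta * time_min[keep])))
  alpha <- -unname(fit_a$coefficients[2L])
  a <- exp(unname(fit_a$coefficients[1L]))
  if (!is.finite(alpha) || alpha <= beta || !is.finite(a)) return(NULL)
  list(A = a, alpha = alpha, B = b, beta = beta)
}

#' Two-compartment (biexponential) plasma clearance
#'
#' Fits `C(t) = A exp(-alpha t) + B exp(-beta t)` (plateau fixed at zero) by
#' unweighted nonlinear least squares on the raw concentrations,
#' initialized by curve stripping (terminal log-linear fit for `(B, beta)`,
#' log-linear fit of the early-phase residuals for `(A, alpha)`).
#' Clearance is `dose / (A/alpha + B/beta)`.
#'
#' When the two rates are not separable (fitted `alpha/beta < rate_ratio_min`,
#' stripping fails, or the optimizer does not converge) the estimate falls
#' back to the one-compartment fit with a warning; the returned object keeps
#' `method = "two_compartment"` and records `diagnostics$fallback = TRUE`.
#'
#' @param session a [subject_session].
#' @param rate_ratio_min identifiability guard: minimum admissible
#'   `alpha/beta` ratio; default 1.5.
#' @param t_min_fallback `t_min` passed to the one-compartment fall-back;
#'   default 30.
#' @return A `clearance_estimate` with terms ordered fast-then-slow.
#' @export
fit_two_compartment <- function(session, rate_ratio_min = 1.5,
                                t_min_fallback = 30) {
  session <- subtract_background(session)
  s <- .fit_samples(session)
  if (nrow(s) < 5L) {
    stop("need at least 5 usable post-dose samples for a biexponential fit",
         call. = FALSE)
  }
  fallback <- function(reason) {
    warning("biexponential fit fell back to one-compartment: ", reason,
            call. = FALSE)
    est <- fit_one_compartment(session, t_min = t_min_fallback)
    est$method <- "two_compartment"
    est$diagnostics$fallback <- TRUE
    est$diagnostics$fallback_reason <- reason
    est
  }
  start <- .strip_start(s$time_min, s$concentration)
  if (is.null(start)) return(fallback("curve stripping found no distribution phase"))
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    concentration ~ A * exp(-alpha * time_min) + B * exp(-beta * time_min),
    data = s, start = start,
    lower = rep(.Machine$double.eps, 4L),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-10,
                                         ptol = 1e-12))), silent = TRUE)
  if (inherits(fit, "try-error")) return(fallback("optimizer failed to converge"))
  cf <- stats::coef(fit)
  a <- unname(cf["A"]); alpha <- unname(cf["alpha"])
  b <- unname(cf["B"]); beta <- unname(cf["beta"])
  if (alpha < beta) {  # reorder fast-then-slow
    tmp <- c(a, alpha); a <- b; alpha <- beta; b <- tmp[1L]; beta <- tmp[2L]
  }
  if (!all(is.finite(c(a, alpha, b, beta))) || beta <= 0 ||
      alpha / beta < rate_ratio_min) {
    return(fallback(sprintf("rates not separable (alpha/beta = %.3g)",
                            alpha / beta)))
  }
  resid <- stats::resid(fit)
  clearance_estimate("two_compartment", session$dose_ug,
                     auc = a / alpha + b / beta,
                     terms = list(exp_term(a, alpha), exp_term(b, beta)),
                     diagnostics = list(n_points = nrow(s),
                                        rss = sum(resid^2),
                                        resid_sd = stats::sd(resid),
                                        fallback = FALSE))
}

#' Two-sample one-compartment plasma clearance
#'
#' The slope-intercept simplification: the monoexponential through two
#' timed samples gives `beta = ln(C1/C2)/(t2 - t1)` and back-extrapolated
#' intercept `B = exp((t2 ln C1 - t1 ln C2)/(t2 - t1))`, so clearance is
#' `dose * beta / B`. Algebraically identical to [fit_one_compartment]
#' restricted to exactly those two points.
#'
#' @param dose_ug injected dose in micrograms.
#' @param t1,t2 sample times in minutes, `0 < t1 < t2`.
#' @param c1,c2 concentrations in micrograms/mL, `c1 > c2 > 0`.
#' @return A `clearance_estimate` with a single exponential term.
#' @examples
#' clearance_two_sample(10000, 30, 90, 100 * exp(-0.3), 100 * exp(-0.9))
#' @export
clearance_two_sample <- function(dose_ug, t1, t2, c1, c2) {
  if (!(t1 > 0 && t2 > t1)) stop("need 0 < t1 < t2", call. = FALSE)
  if (!(c2 > 0)) stop("concentrations must be positive", call. = FALSE)
  if (!(c1 > c2)) {
    stop("non-declining pair: c1 must exceed c2", call. = FALSE)
  }
  beta <- log(c1 / c2) / (t2 - t1)
  b <- exp((t2 * log(c1) - t1 * log(c2)) / (t2 - t1))
  clearance_estimate("two_sample", dose_ug,
                     auc = b / beta,
                     terms = list(exp_term(b, beta)),
                     diagnostics = list(t1 = t1, t2 = t2))
}
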