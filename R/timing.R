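#' Candidate two-sample schedule pairs
#'
#' The five post-distribution permutations evaluated by default: both times
#' at or after the 30-min distribution boundary, drawn from the 12-point
#' schedule between 30 and 120 min.
#' @return A data.frame with columns `t1`, `t2`.
#' @export
default_schedule_pairs <- function() {
  data.frame(t1 = c(30, 60, 90, 30, 60),
             t2 = c(60, 90, 120, 90, 120))
}

#' Evaluate two-sample schedule permutations against full-curve references
#'
#' For each candidate `(t1, t2)` pair, computes the two-sample clearance in
#' every session from the measured concentrations at those times, then
#' summarizes its agreement with each full-curve reference method
#' (1/C^2-weighted R^2, bias, precision, P10 accuracy). Sessions lacking a
#' sample at a pair time, with a below-LLOQ or non-declining concentration
#' at either time, or where a reference fit fails, are excluded from that
#' cell; the exclusion count is reported.
#'
#' @param sessions list of [subject_session] objects (typically one marker).
#' @param pairs data.frame with columns `t1`, `t2` (minutes); default
#'   [default_schedule_pairs()]. Pairs with `t1` before `t_boundary` are
#'   rejected unless `enforce_boundary = FALSE`.
#' @param references character vector of reference methods, a subset of
#'   `c("trapezoidal", "one_compartment", "two_compartment")`.
#' @param t_boundary post-distribution boundary in minutes; default 30.
#' @param enforce_boundary reject pairs starting before `t_boundary`?
#'   Default `TRUE`.
#' @param ... passed to the reference estimators
#'   (e.g. `threshold`, `t_min`).
#' @return A data.frame with one row per (pair, reference): `t1`, `t2`,
#'   `reference`, `n`, `n_excluded`, `r2`, `bias`, `precision`, `pct_bias`,
#'   `p10`, `p15`.
#' @export
evaluate_schedules <- function(sessions,
                               pairs = default_schedule_pairs(),
                               references = c("trapezoidal",
                                              "one_compartment",
                                              "two_compartment"),
                               t_boundary = 30,
                               enforce_boundary = TRUE, ...) {
  references <- match.arg(references, several.ok = TRUE)
  stopifnot(all(c("t1", "t2") %in% names(pairs)), all(pairs$t1 < pairs$t2))
  if (enforce_boundary && any(pairs$t1 < t_boundary)) {
    stop("pair(s) start before the ", t_boundary,
         "-min distribution boundary; set enforce_boundary = FALSE to allow",
         call. = FALSE)
  }

  ref_fit <- function(method, ses) {
    est <- switch(method,
                  trapezoidal = clearance_trapezoidal(ses, ...),
                  one_compartment = fit_one_compartment(ses, ...),
                  two_compartment = suppressWarnings(fit_two_compartment(ses, ...)))
    est$clearance_ml_min
  }
  ref_values <- lapply(references, function(m) {
    vapply(sessions, function(ses) {
      tryCatch(ref_fit(m, ses), error = function(e) NA_real_)
    }, numeric(1))
  })
  names(ref_values) <- references

  two_sample_at <- function(ses, t1, t2) {
    s <- subtract_background(ses)$samples
    i1 <- match(t1, s$time_min); i2 <- match(t2, s$time_min)
    if (is.na(i1) || is.na(i2)) return(NA_real_)
    if (s$below_lloq[i1] || s$below_lloq[i2]) return(NA_real_)
    if (s$concentration[i1] <= s$concentration[i2]) return(NA_real_)
    clearance_two_sample(ses$dose_ug, t1, t2,
                         s$concentration[i1], s$concentration[i2])$clearance_ml_min
  }

  out <- list()
  for (i in seq_len(nrow(pairs))) {
    t1 <- pairs$t1[i]; t2 <- pairs$t2[i]
    ts_cl <- vapply(sessions, two_sample_at, numeric(1), t1 = t1, t2 = t2)
    for (m in references) {
      ok <- is.finite(ts_cl) & is.finite(ref_values[[m]])
      rep <- agreement_report(ref_values[[m]][ok], ts_cl[ok],
                              labels = c(m, sprintf("two_sample_%g_%g", t1, t2)))
      out[[length(out) + 1L]] <-
        data.frame(t1 = t1, t2 = t2, reference = m,
                   n = rep$n, n_excluded = sum(!ok),
                   r2 = rep$r2, bias = rep$bias, precision = rep$precision,
                   pct_bias = rep$pct_bias, p10 = rep$p10, p15 = rep$p15)
    }
  }
  do.call(rbind, out)
}
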