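#' Paired method-agreement statistics
#'
#' Computes the agreement summary used to compare two clearance methods (or
#' a biomarker against a reference) from paired values: per-pair bias
#' `reference - comparative`, percent bias relative to the pair mean,
#' their means and standard deviations, P10/P15 accuracy (the percentage of
#' pairs whose absolute percent bias is below 10 or 15), the
#' 1/C^2-weighted regression coefficient, and Bland-Altman limits of
#' agreement (`bias +/- 2 SD`).
#'
#' "Bias" is the signed difference throughout; only P10/P15 use the
#' magnitude of the percent bias. Pairs whose mean is zero have an
#' undefined percent bias and are excluded with a warning.
#'
#' @param reference reference-method values (numeric).
#' @param comparative comparative-method values, same length and pairing.
#' @param labels optional character vector of length 2 naming the methods.
#' @param r2_weighting weighting convention passed to
#'   [weighted_regression_r2]; default `"comparative"` (weights
#'   `1/comparative^2`).
#' @return An object of class `agreement_report`: a list with `n`, `bias`,
#'   `precision`, `pct_bias`, `pct_precision`, `p10`, `p15`, `r2`,
#'   `loa_low`, `loa_high`, `labels`, and `pairs` (a data.frame with the
#'   per-pair `reference`, `comparative`, `mean`, `bias`, `pct_bias` for
#'   Bland-Altman plotting).
#' @examples
#' agreement_report(c(2, 2.5, 3), c(1.8, 2.6, 2.9))
#' @export
agreement_report <- function(reference, comparative, labels = NULL,
                             r2_weighting = c("comparative", "reference")) {
  r2_weighting <- match.arg(r2_weighting)
  stopifnot(length(reference) == length(comparative))
  ok <- is.finite(reference) & is.finite(comparative)
  reference <- reference[ok]; comparative <- comparative[ok]
  if (length(reference) < 1L) {
    stop("need at least 1 complete pair", call. = FALSE)
  }
  pair_mean <- (reference + comparative) / 2
  if (any(pair_mean == 0)) {
    warning(sum(pair_mean == 0),
            " pair(s) with zero mean excluded (percent bias undefined)")
    keep <- pair_mean != 0
    reference <- reference[keep]; comparative <- comparative[keep]
    pair_mean <- pair_mean[keep]
  }
  bias_i <- reference - comparative
  pct_i <- 100 * bias_i / pair_mean
  r2 <- tryCatch(
    weighted_regression_r2(reference, comparative, weighting = r2_weighting),
    error = function(e) NA_real_)
  bias <- mean(bias_i)
  precision <- stats::sd(bias_i)
  structure(list(n = length(bias_i),
                 bias = bias,
                 precision = precision,
                 pct_bias = mean(pct_i),
                 pct_precision = stats::sd(pct_i),
                 p10 = 100 * mean(abs(pct_i) < 10),
                 p15 = 100 * mean(abs(pct_i) < 15),
                 r2 = r2,
                 loa_low = bias - 2 * precision,
                 loa_high = bias + 2 * precision,
                 labels = labels,
                 pairs = data.frame(reference = reference,
                                    comparative = comparative,
                                    mean = pair_mean,
                                    bias = bias_i,
                                    pct_bias = pct_i)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  hdr <- if (!is.null(x$labels)) {
    sprintf(" %s vs %s", x$labels[1L], x$labels[2L])
  } else ""
  cat(sprintf("<agreement_report>%s  n = %d\n", hdr, x$n))
  cat(sprintf("  bias %+0.3f +/- %0.3f   %%bias %+0.2f +/- %0.2f\n",
              x$bias, x$precision, x$pct_bias, x$pct_precision))
  cat(sprintf("  P10 %0.1f%%   P15 %0.1f%%   R2 %s\n", x$p10, x$p15,
              ifelse(is.na(x$r2), "NA", sprintf("%0.3f", x$r2))))
  cat(sprintf("  limits of agreement [%0.3f, %0.3f]\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' Coerce an agreement report to a one-row data frame
#' @param x an `agreement_report`.
#' @param ... unused.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(reference = if (is.null(x$labels)) NA_character_ else x$labels[1L],
             comparative = if (is.null(x$labels)) NA_character_ else x$labels[2L],
             n = x$n, r2 = x$r2, bias = x$bias, precision = x$precision,
             pct_bias = x$pct_bias, pct_precision = x$pct_precision,
             p10 = x$p10, p15 = x$p15,
             loa_low = x$loa_low, loa_high = x$loa_high)
}

#' Weighted linear-regression coefficient of determination
#'
#' Regresses the comparative measure on the reference by weighted least
#' squares with weights `1/C^2`, where `C` is the comparative measure by
#' default (the convention of common graphing software; switch to
#' `weighting = "reference"` for `1/x^2`). Returns the weighted R^2.
#'
#' @param reference,comparative paired values; `n >= 3`.
#' @param weighting which measure supplies the `1/C^2` weights.
#' @return Weighted R^2 in `[0, 1]`.
#' @export
weighted_regression_r2 <- function(reference, comparative,
                                   weighting = c("comparative", "reference")) {
  weighting <- match.arg(weighting)
  stopifnot(length(reference) == length(comparative))
  wsrc <- if (weighting == "comparative") comparative else reference
  if (any(wsrc == 0)) {
    warning(sum(wsrc == 0), " pair(s) with zero weight source excluded")
    keep <- wsrc != 0
    reference <- reference[keep]; comparative <- comparative[keep]
    wsrc <- wsrc[keep]
  }
  if (length(reference) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(reference) == 0) {
    stop("reference values are constant: R^2 undefined", call. = FALSE)
  }
  fit <- stats::lm(comparative ~ reference, weights = 1 / wsrc^2)
  # summary.lm warns on an essentially perfect fit; R^2 = 1 is still right
  suppressWarnings(summary(fit)$r.squared)
}

#' Straight line versus sixth-order polynomial
#'
#' Fits nested least-squares models of degree 1 and degree 6 and compares
#' them with the extra-sum-of-squares F-test
#' `F = ((SS1 - SS6)/5) / (SS6/(n - 7))`; the polynomial is chosen when
#' `p < alpha`.
#'
#' @param x,y paired observations; `n > 8` so the sixth-order model leaves
#'   residual degrees of freedom.
#' @param alpha significance level; default 0.05.
#' @return A list with `f_statistic`, `p_value`, `chosen`
#'   (`"line"` or `"polynomial6"`), and `fitted_coefficients` of the chosen
#'   model.
#' @export
select_line_vs_poly6 <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 8L) {
    stop("need more than 8 points to compare a line with a sixth-order polynomial",
         call. = FALSE)
  }
  fit1 <- stats::lm(y ~ x)
  fit6 <- stats::lm(y ~ stats::poly(x, 6))
  ss1 <- sum(stats::resid(fit1)^2)
  ss6 <- sum(stats::resid(fit6)^2)
  f <- ((ss1 - ss6) / 5) / (ss6 / (n - 7))
  p <- stats::pf(f, 5, n - 7, lower.tail = FALSE)
  chosen <- if (p < alpha) "polynomial6" else "line"
  list(f_statistic = f, p_value = p, chosen = chosen,
       fitted_coefficients = stats::coef(if (chosen == "line") fit1 else fit6))
}

#' Express a biomarker on the percent-of-kidney-function scale
#'
#' The reference scale is the reference clearance expressed as a percent of
#' its cohort week-0 mean. Each biomarker is mapped linearly onto the same
#' scale: its week-0 cohort mean maps to 100% and its cohort-worst value
#' maps to the scale floor (the minimum of the reference percent series).
#' For markers that rise as function falls (`direction = "increases"`,
#' e.g. creatinine) the worst value is the maximum, which flips the
#' orientation automatically.
#'
#' @param marker_value biomarker values by subject-week.
#' @param week study week of each value (week 0 = baseline).
#' @param reference_pct reference percent-of-function values aligned with
#'   `marker_value`.
#' @param direction `"increases"` if the marker rises as kidney function
#'   declines, `"decreases"` if it falls with function (e.g. a clearance).
#' @return A data.frame with columns `reference_pct` and `marker_pct`.
#' @seealso [percent_of_baseline] for building the reference percent
#'   series.
#' @export
normalize_to_function_scale <- function(marker_value, week, reference_pct,
                                        direction = c("increases",
                                                      "decreases")) {
  direction <- match.arg(direction)
  stopifnot(length(marker_value) == length(week),
            length(marker_value) == length(reference_pct))
  if (!any(week == 0)) {
    stop("missing week-0 baseline for the marker", call. = FALSE)
  }
  m0 <- mean(marker_value[week == 0])
  worst <- if (direction == "increases") max(marker_value) else min(marker_value)
  floor_pct <- min(reference_pct)
  if (worst == m0) {
    stop("marker shows no spread between baseline and worst value",
         call. = FALSE)
  }
  marker_pct <- 100 + (marker_value - m0) * (floor_pct - 100) / (worst - m0)
  data.frame(reference_pct = reference_pct, marker_pct = marker_pct)
}

#' Percent of cohort week-0 mean
#'
#' @param value values by subject-week.
#' @param week study week of each value.
#' @return `100 * value / mean(value at week 0)`.
#' @export
percent_of_baseline <- function(value, week) {
  stopifnot(length(value) == length(week))
  if (!any(week == 0)) stop("no week-0 values present", call. = FALSE)
  100 * value / mean(value[week == 0])
}

#' First week a marker departs significantly from baseline
#'
#' Runs a repeated-measures one-way ANOVA of the marker across weeks
#' (subject as the error stratum); if significant, compares each later week
#' to week 0 by paired t-tests with multiplicity-adjusted p-values and
#' returns the earliest week whose adjusted p-value is below `alpha`.
#'
#' @param value marker values.
#' @param week study week per value (0 = baseline).
#' @param subject_id subject per value; at least 3 subjects with complete
#'   week series (subjects with incomplete series are dropped with a
#'   warning).
#' @param alpha significance level; default 0.05.
#' @param adjust `"holm"` (default) applies a Holm correction to the paired
#'   t-tests; `"tukey"` instead takes the week-versus-0 contrasts from a
#'   Tukey HSD on the within-subject ANOVA.
#' @return The earliest significant week (integer), or `NA` when the ANOVA
#'   or none of the weekly contrasts is significant. The adjusted per-week
#'   p-values and the ANOVA p-value are attached as attributes
#'   `week_p` and `anova_p`.
#' @export
first_significant_week <- function(value, week, subject_id, alpha = 0.05,
                                   adjust = c("holm", "tukey")) {
  adjust <- match.arg(adjust)
  d <- data.frame(value = value, week = as.integer(week),
                  subject = as.character(subject_id))
  weeks <- sort(unique(d$week))
  if (!0 %in% weeks) stop("week 0 must be present", call. = FALSE)
  # listwise handling: keep subjects observed at every week
  counts <- table(d$subject)
  complete <- names(counts)[counts == length(weeks)]
  if (length(complete) < length(counts)) {
    warning(length(counts) - length(complete),
            " subject(s) with incomplete week series dropped")
  }
  d <- d[d$subject %in% complete, , drop = FALSE]
  if (length(complete) < 3L) {
    stop("need at least 3 subjects with complete series", call. = FALSE)
  }
  d$fweek <- factor(d$week)
  d$fsubj <- factor(d$subject)
  fit <- stats::aov(value ~ fweek + Error(fsubj), data = d)
  anova_tab <- summary(fit)[["Error: Within"]][[1L]]
  anova_p <- anova_tab[["Pr(>F)"]][1L]
  later <- setdiff(weeks, 0)
  if (is.na(anova_p) || anova_p >= alpha) {
    res <- NA_integer_
    attr(res, "anova_p") <- anova_p
    attr(res, "week_p") <- stats::setNames(rep(NA_real_, length(later)), later)
    return(res)
  }
  if (adjust == "holm") {
    base <- d$value[d$week == 0][order(d$subject[d$week == 0])]
    praw <- vapply(later, function(w) {
      cur <- d$value[d$week == w][order(d$subject[d$week == w])]
      stats::t.test(cur, base, paired = TRUE)$p.value
    }, numeric(1))
    padj <- stats::p.adjust(praw, method = "holm")
  } else {
    fit2 <- stats::aov(value ~ fweek + fsubj, data = d)
    tk <- stats::TukeyHSD(fit2, "fweek")$fweek
    want <- paste0(later, "-0")
    padj <- tk[want, "p adj"]
  }
  names(padj) <- later
  sig <- later[padj < alpha]
  res <- if (length(sig)) min(sig) else NA_integer_
  attr(res, "anova_p") <- anova_p
  attr(res, "week_p") <- padj
  res
}
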