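#' Construct a subject session
#'
#' A `subject_session` holds one animal-week disappearance curve after a
#' single IV bolus of a filtration marker: the injected dose, the timed
#' plasma samples, and the pre-dose background concentration.
#'
#' When `background_conc` is not supplied, a sample at `t = 0` is
#' interpreted as the pre-dose background draw (the curve cannot be sampled
#' at the instant of injection): its concentration becomes
#' `background_conc` and the row is removed from the working series. When
#' `background_conc` is supplied explicitly, a `t = 0` row is kept as an
#' ordinary sample (useful for synthetic curves evaluated at the moment of
#' injection).
#'
#' @param subject_id subject identifier (coerced to character).
#' @param week integer study week.
#' @param marker marker name, e.g. `"iohexol"` or `"inulin"`.
#' @param dose_ug injected dose in micrograms; must be positive.
#' @param time_min numeric vector of sample times in minutes since
#'   injection, strictly increasing, non-negative.
#' @param concentration numeric vector of plasma concentrations in
#'   micrograms/mL, non-negative, same length as `time_min`.
#' @param background_conc pre-dose concentration in micrograms/mL. Defaults
#'   to the `t = 0` sample when present, else 0.
#' @param lloq lower limit of quantification in micrograms/mL; samples at or
#'   below it are flagged `below_lloq` and excluded from model fits.
#'   Default 0.2.
#' @return An object of class `subject_session`: a list with elements
#'   `subject_id`, `week`, `marker`, `dose_ug`, `background_conc`, `lloq`
#'   and `samples` (a data.frame with columns `time_min`, `concentration`,
#'   `below_lloq`).
#' @examples
#' s <- subject_session("r1", 0, "iohexol", dose_ug = 10000,
#'                      time_min = c(0, 30, 60, 120),
#'                      concentration = c(0, 80, 55, 30))
#' s
#' @export
subject_session <- function(subject_id, week, marker, dose_ug,
                            time_min, concentration,
                            background_conc = NULL, lloq = 0.2) {
  stopifnot(length(time_min) == length(concentration))
  if (!is.numeric(dose_ug) || length(dose_ug) != 1L || is.na(dose_ug) ||
      dose_ug <= 0) {
    stop("dose_ug must be a single positive number", call. = FALSE)
  }
  if (any(is.na(time_min)) || any(time_min < 0)) {
    stop("sample times must be non-negative and non-missing", call. = FALSE)
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("sample times must be strictly increasing (duplicate or unsorted times)",
         call. = FALSE)
  }
  if (any(is.na(concentration)) || any(concentration < 0)) {
    stop("concentrations must be non-negative and non-missing", call. = FALSE)
  }

  samples <- data.frame(time_min = as.numeric(time_min),
                        concentration = as.numeric(concentration))
  # with no explicit background, a t = 0 row is the pre-dose draw
  has_t0 <- samples$time_min[1L] == 0
  if (is.null(background_conc)) {
    background_conc <- if (has_t0) samples$concentration[1L] else 0
    if (has_t0) samples <- samples[-1L, , drop = FALSE]
  }
  if (background_conc < 0) {
    stop("background_conc must be non-negative", call. = FALSE)
  }
  if (nrow(samples) < 2L) {
    stop("a session needs at least 2 post-dose samples", call. = FALSE)
  }
  samples$below_lloq <- samples$concentration <= lloq
  rownames(samples) <- NULL

  structure(list(subject_id = as.character(subject_id),
                 week = as.integer(week),
                 marker = as.character(marker),
                 dose_ug = as.numeric(dose_ug),
                 background_conc = as.numeric(background_conc),
                 lloq = as.numeric(lloq),
                 samples = samples),
            class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf("<subject_session> %s week %d, %s\n",
              x$subject_id, x$week, x$marker))
  cat(sprintf("  dose: %g ug   background: %g ug/mL   samples: %d (%d below LLOQ)\n",
              x$dose_ug, x$background_conc, nrow(x$samples),
              sum(x$samples$below_lloq)))
  tr <- range(x$samples$time_min)
  cat(sprintf("  times: %g-%g min\n", tr[1L], tr[2L]))
  invisible(x)
}

#' Subtract the pre-dose background from a session
#'
#' Reduces every post-dose concentration by `background_conc`, clamping the
#' result at zero. Clamped samples are flagged in a logical `clamped`
#' column. The returned session has `background_conc = 0`, so the
#' subtraction is idempotent.
#'
#' @param session a [subject_session].
#' @return The background-corrected `subject_session`.
#' @export
subtract_background <- function(session) {
  stopifnot(inherits(session, "subject_session"))
  bg <- session$background_conc
  s <- session$samples
  corrected <- pmax(s$concentration - bg, 0)
  if (all(corrected <= 0)) {
    stop("non-informative curve: all post-dose samples at or below background",
         call. = FALSE)
  }
  s$clamped <- bg > 0 & s$concentration - bg < 0
  s$concentration <- corrected
  s$below_lloq <- s$concentration <= session$lloq
  session$samples <- s
  session$background_conc <- 0
  session
}

# samples usable for model fitting: positive and quantifiable
.fit_samples <- function(session) {
  s <- session$samples
  s[!s$below_lloq & s$concentration > 0, , drop = FALSE]
}
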