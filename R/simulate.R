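#' Exponential terms of a two-compartment IV-bolus model
#'
#' Converts mechanistic two-compartment parameters (central volume `v_central`,
#' peripheral volume `v_peripheral`, intercompartmental flow
#' `q_intercompartmental`, renal clearance) into the macro parameters of the
#' biexponential disappearance curve `C(t) = A exp(-alpha t) + B exp(-beta t)`.
#'
#' With `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, the rates `alpha > beta`
#' are the roots of `s^2 - (k10 + k12 + k21) s + k10 k21 = 0`, and
#' `A = (dose/V1)(alpha - k21)/(alpha - beta)`,
#' `B = (dose/V1)(k21 - beta)/(alpha - beta)`. The construction guarantees
#' `dose / (A/alpha + B/beta) = clearance` exactly.
#'
#' @param clearance renal clearance in mL/min, positive.
#' @param v_central,v_peripheral compartment volumes in mL.
#' @param q_intercompartmental intercompartmental flow in mL/min.
#' @param dose_ug injected dose in micrograms.
#' @return A list of two exponential terms, fast then slow, each with
#'   `coefficient` (micrograms/mL) and `rate` (1/min).
#' @examples
#' tm <- compartmental_to_exponential(2, 20, 30, 1, 10000)
#' auc <- tm$fast$coefficient / tm$fast$rate + tm$slow$coefficient / tm$slow$rate
#' 10000 / auc  # recovers clearance = 2
#' @export
compartmental_to_exponential <- function(clearance, v_central, v_peripheral,
                                         q_intercompartmental, dose_ug) {
  stopifnot(clearance > 0, v_central > 0, v_peripheral > 0,
            q_intercompartmental > 0, dose_ug > 0)
  k10 <- clearance / v_central
  k12 <- q_intercompartmental / v_central
  k21 <- q_intercompartmental / v_peripheral
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(s^2 - 4 * p)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- dose_ug / v_central
  a <- c0 * (alpha - k21) / (alpha - beta)
  b <- c0 * (k21 - beta) / (alpha - beta)
  list(fast = exp_term(a, alpha), slow = exp_term(b, beta))
}

#' Exogenous-marker pharmacokinetic description
#'
#' Generative counterpart of the fitted biexponential: compartment volumes
#' and intercompartmental flow determine the distribution (alpha) phase,
#' while clearance sets the elimination (beta) phase. The defaults for the
#' two bundled profiles differ in equilibration speed: the iohexol-like
#' marker (small molecule) equilibrates with extracellular fluid quickly,
#' so its distribution phase carries little area; the inulin-like marker
#' (large polysaccharide) equilibrates slowly, so a one-compartment
#' simplification misses a substantial share of its AUC.
#'
#' @param v_central central (plasma) volume, mL.
#' @param v_peripheral peripheral (extracellular) volume, mL.
#' @param q_intercompartmental distribution flow, mL/min.
#' @param lloq assay lower limit of quantification, micrograms/mL.
#' @param noise_cv multiplicative assay noise at high concentrations,
#'   coefficient of variation (fraction in `[0, 1)`).
#' @param error_c50 concentration (micrograms/mL) at which the relative
#'   assay error has doubled: the effective CV is
#'   `noise_cv * (1 + error_c50 / C)`, the usual inflation of relative
#'   error as an assay approaches its quantification limit. `0` (the
#'   default) keeps the CV constant.
#' @return A `marker_pk` list.
#' @export
marker_pk <- function(v_central, v_peripheral, q_intercompartmental,
                      lloq = 0.2, noise_cv = 0.05, error_c50 = 0) {
  stopifnot(v_central > 0, v_peripheral > 0, q_intercompartmental > 0,
            lloq >= 0, noise_cv >= 0, noise_cv < 1, error_c50 >= 0)
  list(v_central = v_central, v_peripheral = v_peripheral,
       q_intercompartmental = q_intercompartmental,
       lloq = lloq, noise_cv = noise_cv, error_c50 = error_c50)
}

#' Endogenous-marker steady-state model
#'
#' A constantly produced marker eliminated by filtration reaches the
#' steady state `concentration = production_rate / (GFR + nonrenal_clearance)`.
#' The hyperbola makes the clinically familiar delayed rise structural:
#' a 20% GFR loss raises the marker only 1.25-fold while a 50% loss
#' doubles it.
#'
#' @param production_rate production in amount/min (arbitrary marker units
#'   times mL/min, so that concentrations come out in marker units).
#' @param nonrenal_clearance extrarenal elimination, mL/min.
#' @param noise_cv multiplicative assay noise CV (fraction).
#' @param biological_cv within-animal week-to-week biological variability
#'   of the steady state (production and diet fluctuations), as a
#'   multiplicative CV; acts on top of the assay noise.
#' @return An `endogenous_marker_model` list.
#' @export
endogenous_marker_model <- function(production_rate, nonrenal_clearance = 0,
                                    noise_cv = 0.12, biological_cv = 0.15) {
  stopifnot(production_rate > 0, nonrenal_clearance >= 0,
            noise_cv >= 0, noise_cv < 1,
            biological_cv >= 0, biological_cv < 1)
  list(production_rate = production_rate,
       nonrenal_clearance = nonrenal_clearance,
       noise_cv = noise_cv,
       biological_cv = biological_cv)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the package targets: 8 rats followed
#' over 6 weekly GFR evaluations on a 12-point sampling schedule
#' (0, 2, 5, 10, 20, 30, 60, 90, 120, 180, 240, 300 min), with kidney
#' function declining progressively to about a quarter of baseline. Two
#' exogenous markers are injected per session; endogenous markers are
#' observed at weekly steady state.
#'
#' @param n_subjects number of animals; default 8.
#' @param weeks number of weekly evaluations (week 0 = baseline);
#'   default 6.
#' @param gfr_baseline healthy clearance, mL/min; default 2.5.
#' @param gfr_trajectory per-week multipliers in `(0, 1]` applied to the
#'   baseline; default `c(1, 0.72, 0.55, 0.45, 0.33, 0.24)`.
#' @param subject_cv between-animal lognormal CV of baseline GFR;
#'   default 0.1.
#' @param markers named list of [marker_pk] profiles; defaults bundle an
#'   iohexol-like and an inulin-like marker.
#' @param endogenous named list of [endogenous_marker_model]s; defaults
#'   bundle creatinine-, urea- and cystatin-C-like markers.
#' @param dose_ug named dose per exogenous marker, micrograms.
#' @param schedule_min sampling times in minutes, strictly increasing
#'   from 0.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 8,
                          weeks = 6,
                          gfr_baseline = 2.5,
                          gfr_trajectory = c(1, 0.72, 0.55, 0.45, 0.33, 0.24),
                          subject_cv = 0.1,
                          markers = default_markers(),
                          endogenous = default_endogenous(),
                          dose_ug = c(iohexol = 12000, inulin = 20000),
                          schedule_min = c(0, 2, 5, 10, 20, 30, 60, 90,
                                           120, 180, 240, 300)) {
  stopifnot(n_subjects >= 1, weeks >= 1,
            length(gfr_trajectory) == weeks,
            all(gfr_trajectory > 0), all(gfr_trajectory <= 1),
            gfr_baseline > 0, subject_cv >= 0,
            schedule_min[1L] == 0,
            !is.unsorted(schedule_min, strictly = TRUE))
  if (!all(names(markers) %in% names(dose_ug))) {
    stop("every marker needs a dose in dose_ug", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, weeks = weeks,
                 gfr_baseline = gfr_baseline,
                 gfr_trajectory = gfr_trajectory,
                 subject_cv = subject_cv,
                 markers = markers, endogenous = endogenous,
                 dose_ug = dose_ug, schedule_min = schedule_min),
            class = "cohort_config")
}

#' Default exogenous marker profiles
#'
#' Iohexol-like: rapid equilibration with extracellular fluid, so the
#' distribution phase carries a small AUC share. Inulin-like: slow
#' equilibration, large distribution-phase AUC share.
#' @return Named list of [marker_pk] objects.
#' @export
default_markers <- function() {
  list(iohexol = marker_pk(v_central = 22, v_peripheral = 50,
                           q_intercompartmental = 18, noise_cv = 0.05,
                           error_c50 = 2),
       inulin = marker_pk(v_central = 40, v_peripheral = 50,
                          q_intercompartmental = 2.5, noise_cv = 0.05,
                          error_c50 = 0.5))
}

#' Default endogenous marker models
#'
#' Production rates chosen so baseline steady-state concentrations sit at
#' realistic rat plasma scales (creatinine ~0.4 mg/dL, urea ~18 mg/dL,
#' cystatin-C ~1000 ng/mL at GFR 2.5 mL/min).
#' @return Named list of [endogenous_marker_model] objects.
#' @export
default_endogenous <- function() {
  list(creatinine = endogenous_marker_model(production_rate = 1,
                                            noise_cv = 0.12,
                                            biological_cv = 0.15),
       urea = endogenous_marker_model(production_rate = 45,
                                      noise_cv = 0.12,
                                      biological_cv = 0.15),
       cystatin_c = endogenous_marker_model(production_rate = 2500,
                                            noise_cv = 0.15,
                                            biological_cv = 0.18))
}

#' Simulate one disappearance curve
#'
#' Evaluates the exact biexponential implied by the marker's compartmental
#' parameters and the session's true clearance on the sampling schedule,
#' applies multiplicative lognormal noise with the marker's CV (or additive
#' Gaussian noise when `noise = "additive"`), flags values below the LLOQ,
#' and sets the `t = 0` pre-dose sample to zero. The generating clearance
#' is stored in attribute `true_clearance` for recovery tests.
#'
#' @param subject_id,week session identity.
#' @param marker marker name (must be in `config$markers`).
#' @param true_clearance generating clearance, mL/min.
#' @param config a [cohort_config].
#' @param noise `"lognormal"` (default) or `"additive"`.
#' @return A [subject_session] with attribute `true_clearance`.
#' @export
simulate_session <- function(subject_id, week, marker, true_clearance,
                             config, noise = c("lognormal", "additive")) {
  noise <- match.arg(noise)
  pk <- config$markers[[marker]]
  if (is.null(pk)) stop("unknown marker: ", marker, call. = FALSE)
  dose <- config$dose_ug[[marker]]
  tm <- compartmental_to_exponential(true_clearance, pk$v_central,
                                     pk$v_peripheral,
                                     pk$q_intercompartmental, dose)
  t_post <- config$schedule_min[config$schedule_min > 0]
  conc <- tm$fast$coefficient * exp(-tm$fast$rate * t_post) +
    tm$slow$coefficient * exp(-tm$slow$rate * t_post)
  if (pk$noise_cv > 0) {
    c50 <- if (is.null(pk$error_c50)) 0 else pk$error_c50
    cv <- pk$noise_cv * (1 + c50 / conc)
    if (noise == "lognormal") {
      sdlog <- sqrt(log(1 + cv^2))
      conc <- conc * exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog))
    } else {
      conc <- pmax(conc + stats::rnorm(length(conc), 0, cv * conc), 0)
    }
  }
  ses <- subject_session(subject_id, week, marker, dose_ug = dose,
                         time_min = c(0, t_post),
                         concentration = c(0, conc),
                         lloq = pk$lloq)
  attr(ses, "true_clearance") <- true_clearance
  ses
}

#' Simulate a steady-state endogenous marker value
#'
#' @param model an [endogenous_marker_model].
#' @param true_gfr current GFR, mL/min, positive.
#' @param noise `"lognormal"` (default) or `"additive"`.
#' @return Noisy steady-state concentration in the marker's units.
#' @export
simulate_endogenous <- function(model, true_gfr,
                                noise = c("lognormal", "additive")) {
  noise <- match.arg(noise)
  stopifnot(true_gfr > 0)
  ss <- model$production_rate / (true_gfr + model$nonrenal_clearance)
  bio_cv <- if (is.null(model$biological_cv)) 0 else model$biological_cv
  total_cv <- sqrt((1 + model$noise_cv^2) * (1 + bio_cv^2) - 1)
  if (total_cv > 0) {
    if (noise == "lognormal") {
      sdlog <- sqrt(log(1 + total_cv^2))
      ss <- ss * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog))
    } else {
      ss <- max(ss + stats::rnorm(1L, 0, total_cv * ss), 0)
    }
  }
  ss
}

#' Simulate a full longitudinal cohort
#'
#' Draws a per-animal baseline GFR (lognormal around `gfr_baseline` with
#' `subject_cv`), applies the weekly trajectory multipliers, and generates
#' one disappearance curve per subject-week-marker plus weekly steady-state
#' endogenous marker values. Fully determined by `seed`.
#'
#' @param config a [cohort_config].
#' @param seed integer RNG seed.
#' @param noise noise model passed to the per-session simulators.
#' @return A list with `sessions` (list of [subject_session]), `truth`
#'   (data.frame subject_id, week, true_clearance), `endogenous`
#'   (data.frame subject_id, week, marker, value) and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            noise = c("lognormal", "additive")) {
  noise <- match.arg(noise)
  set.seed(seed)
  subjects <- sprintf("A%d", seq_len(config$n_subjects))
  sdlog <- sqrt(log(1 + config$subject_cv^2))
  base <- config$gfr_baseline *
    exp(stats::rnorm(config$n_subjects, -sdlog^2 / 2, sdlog))
  weeks <- seq_len(config$weeks) - 1L

  sessions <- list()
  truth <- list()
  endo <- list()
  for (i in seq_along(subjects)) {
    for (w in weeks) {
      gfr <- base[i] * config$gfr_trajectory[w + 1L]
      truth[[length(truth) + 1L]] <-
        data.frame(subject_id = subjects[i], week = w, true_clearance = gfr)
      for (mk in names(config$markers)) {
        sessions[[length(sessions) + 1L]] <-
          simulate_session(subjects[i], w, mk, gfr, config, noise = noise)
      }
      for (em in names(config$endogenous)) {
        endo[[length(endo) + 1L]] <-
          data.frame(subject_id = subjects[i], week = w, marker = em,
                     value = simulate_endogenous(config$endogenous[[em]],
                                                 gfr, noise = noise))
      }
    }
  }
  list(sessions = sessions,
       truth = do.call(rbind, truth),
       endogenous = do.call(rbind, endo),
       config = config)
}
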