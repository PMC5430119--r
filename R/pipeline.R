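#' Read subject sessions from CSV
#'
#' Expects a UTF-8 CSV with header columns `subject_id`, `week`, `marker`,
#' `dose_ug`, `time_min`, `concentration_ug_ml` (one row per sample).
#' Rows are grouped into one session per (subject, week, marker); a row at
#' `time_min == 0` is taken as the pre-dose background draw. Row-level
#' problems (negative values, duplicate times, inconsistent dose within a
#' session) are collected and reported with line numbers in a single error.
#'
#' @param path CSV file path.
#' @param lloq lower limit of quantification passed to [subject_session];
#'   default 0.2.
#' @return A list of [subject_session] objects.
#' @export
read_sessions <- function(path, lloq = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "week", "marker", "dose_ug", "time_min",
                "concentration_ug_ml")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d$.line <- seq_len(nrow(d)) + 1L  # header is line 1

  problems <- character()
  bad <- !is.finite(d$time_min) | d$time_min < 0
  if (any(bad)) {
    problems <- c(problems, sprintf("line %d: invalid time_min %s",
                                    d$.line[bad], d$time_min[bad]))
  }
  bad <- !is.finite(d$concentration_ug_ml) | d$concentration_ug_ml < 0
  if (any(bad)) {
    problems <- c(problems, sprintf("line %d: invalid concentration %s",
                                    d$.line[bad], d$concentration_ug_ml[bad]))
  }
  bad <- !is.finite(d$dose_ug) | d$dose_ug <= 0
  if (any(bad)) {
    problems <- c(problems, sprintf("line %d: invalid dose_ug %s",
                                    d$.line[bad], d$dose_ug[bad]))
  }
  key <- interaction(d$subject_id, d$week, d$marker, d$time_min, drop = TRUE)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems,
                  sprintf("line %d: duplicate sample time %g for %s week %s %s",
                          d$.line[dup], d$time_min[dup], d$subject_id[dup],
                          d$week[dup], d$marker[dup]))
  }
  if (length(problems)) {
    stop("parse errors in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  grp <- split(d, interaction(d$subject_id, d$week, d$marker, drop = TRUE))
  sessions <- lapply(grp, function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    if (length(unique(g$dose_ug)) != 1L) {
      stop(sprintf("inconsistent dose_ug within session %s week %s %s (lines %s)",
                   g$subject_id[1L], g$week[1L], g$marker[1L],
                   paste(g$.line, collapse = ",")), call. = FALSE)
    }
    subject_session(g$subject_id[1L], g$week[1L], g$marker[1L],
                    dose_ug = g$dose_ug[1L], time_min = g$time_min,
                    concentration = g$concentration_ug_ml, lloq = lloq)
  })
  ord <- order(vapply(sessions, function(s) s$subject_id, character(1)),
               vapply(sessions, function(s) s$week, integer(1)),
               vapply(sessions, function(s) s$marker, character(1)))
  unname(sessions[ord])
}

#' Write subject sessions to CSV
#'
#' Inverse of [read_sessions]: one row per sample, with the pre-dose
#' background written as a `time_min = 0` row so a round trip reproduces
#' the sessions.
#'
#' @param sessions list of [subject_session] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, week = s$week, marker = s$marker,
               dose_ug = s$dose_ug,
               time_min = c(0, s$samples$time_min),
               concentration_ug_ml = c(s$background_conc,
                                       s$samples$concentration))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Estimate clearance by every requested method for a set of sessions
#'
#' @param sessions list of [subject_session] objects.
#' @param methods methods to run; any of `"trapezoidal"`,
#'   `"two_compartment"`, `"one_compartment"`, `"two_sample"`.
#' @param two_sample_times the `(t1, t2)` pair used by the two-sample
#'   method; default `c(30, 90)`.
#' @param threshold tail-extrapolation threshold for the trapezoidal
#'   method; default 0.5.
#' @param t_min earliest time in the one-compartment fit; default 30.
#' @return A data.frame with one row per session and method: `subject_id`,
#'   `week`, `marker`, `method`, `clearance_ml_min`, `auc`, `auc_observed`,
#'   `auc_extrapolated`, `fallback`, `note` (failure message when a method
#'   could not produce an estimate, in which case `clearance_ml_min` is
#'   `NA`).
#' @export
estimate_clearances <- function(sessions,
                                methods = c("trapezoidal", "two_compartment",
                                            "one_compartment", "two_sample"),
                                two_sample_times = c(30, 90),
                                threshold = 0.5, t_min = 30) {
  methods <- match.arg(methods, several.ok = TRUE)
  run_one <- function(ses, method) {
    est <- tryCatch(switch(method,
      trapezoidal = clearance_trapezoidal(ses, threshold = threshold),
      two_compartment = suppressWarnings(fit_two_compartment(ses)),
      one_compartment = fit_one_compartment(ses, t_min = t_min),
      two_sample = {
        s <- subtract_background(ses)$samples
        i1 <- match(two_sample_times[1L], s$time_min)
        i2 <- match(two_sample_times[2L], s$time_min)
        if (is.na(i1) || is.na(i2)) {
          stop("two-sample times not in schedule", call. = FALSE)
        }
        if (s$below_lloq[i1] || s$below_lloq[i2]) {
          stop("two-sample concentration below LLOQ", call. = FALSE)
        }
        clearance_two_sample(ses$dose_ug, two_sample_times[1L],
                             two_sample_times[2L],
                             s$concentration[i1], s$concentration[i2])
      }), error = function(e) conditionMessage(e))
    if (is.character(est)) {
      return(data.frame(subject_id = ses$subject_id, week = ses$week,
                        marker = ses$marker, method = method,
                        clearance_ml_min = NA_real_, auc = NA_real_,
                        auc_observed = NA_real_, auc_extrapolated = NA_real_,
                        fallback = NA, note = est))
    }
    data.frame(subject_id = ses$subject_id, week = ses$week,
               marker = ses$marker, method = method,
               clearance_ml_min = est$clearance_ml_min, auc = est$auc,
               auc_observed = est$auc_observed,
               auc_extrapolated = est$auc_extrapolated,
               fallback = isTRUE(est$diagnostics$fallback),
               note = "")
  }
  out <- do.call(rbind, lapply(sessions, function(ses) {
    do.call(rbind, lapply(methods, function(m) run_one(ses, m)))
  }))
  rownames(out) <- NULL
  out
}

#' Default method comparisons
#'
#' The reference/comparative pairs of the full agreement table for a
#' two-marker (inulin + iohexol), three-model design: inulin trapezoidal as
#' gold standard against everything, the inulin two-compartment block, and
#' the within-iohexol block.
#' @return A data.frame with columns `ref_marker`, `ref_method`,
#'   `comp_marker`, `comp_method`.
#' @export
default_comparisons <- function() {
  rbind(
    data.frame(ref_marker = "inulin", ref_method = "trapezoidal",
               comp_marker = c("iohexol", "iohexol", "iohexol",
                               "inulin", "inulin"),
               comp_method = c("two_compartment", "trapezoidal",
                               "one_compartment", "two_compartment",
                               "one_compartment")),
    data.frame(ref_marker = "inulin", ref_method = "two_compartment",
               comp_marker = c("iohexol", "iohexol", "iohexol", "inulin"),
               comp_method = c("two_compartment", "trapezoidal",
                               "one_compartment", "one_compartment")),
    data.frame(ref_marker = "iohexol", ref_method = "trapezoidal",
               comp_marker = "iohexol",
               comp_method = c("two_compartment", "one_compartment")),
    data.frame(ref_marker = "iohexol", ref_method = "two_compartment",
               comp_marker = "iohexol", comp_method = "one_compartment"))
}

#' Agreement table across clearance methods
#'
#' Pairs the per-session clearance estimates of each requested
#' reference/comparative combination by (subject, week) and summarizes
#' their agreement with [agreement_report]. Sessions where either member
#' is missing are dropped pairwise.
#'
#' @param estimates output of [estimate_clearances].
#' @param comparisons data.frame with columns `ref_marker`, `ref_method`,
#'   `comp_marker`, `comp_method`; defaults to [default_comparisons()]
#'   restricted to combinations present in `estimates`.
#' @param r2_weighting passed to [agreement_report].
#' @return A data.frame with one row per comparison (the columns of
#'   [as.data.frame.agreement_report]).
#' @export
compare_methods <- function(estimates, comparisons = NULL,
                            r2_weighting = "comparative") {
  lab <- function(marker, method) paste(marker, method, sep = "_")
  estimates$label <- lab(estimates$marker, estimates$method)
  have <- unique(estimates$label)
  if (is.null(comparisons)) {
    comparisons <- default_comparisons()
    keep <- lab(comparisons$ref_marker, comparisons$ref_method) %in% have &
      lab(comparisons$comp_marker, comparisons$comp_method) %in% have
    comparisons <- comparisons[keep, , drop = FALSE]
    if (!nrow(comparisons)) {
      stop("no default comparisons available for these estimates", call. = FALSE)
    }
  }
  key <- function(d) paste(d$subject_id, d$week, sep = "|")
  out <- lapply(seq_len(nrow(comparisons)), function(i) {
    rl <- lab(comparisons$ref_marker[i], comparisons$ref_method[i])
    cl <- lab(comparisons$comp_marker[i], comparisons$comp_method[i])
    r <- estimates[estimates$label == rl, , drop = FALSE]
    cc <- estimates[estimates$label == cl, , drop = FALSE]
    m <- merge(r[, c("subject_id", "week", "clearance_ml_min")],
               cc[, c("subject_id", "week", "clearance_ml_min")],
               by = c("subject_id", "week"), suffixes = c("_ref", "_comp"))
    m <- m[is.finite(m$clearance_ml_min_ref) &
             is.finite(m$clearance_ml_min_comp), , drop = FALSE]
    as.data.frame(agreement_report(m$clearance_ml_min_ref,
                                   m$clearance_ml_min_comp,
                                   labels = c(rl, cl),
                                   r2_weighting = r2_weighting))
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Either simulates a cohort or reads session/endogenous CSVs, fits every
#' clearance method, builds the method-agreement table, evaluates the
#' two-sample schedule permutations per marker, screens every measure for
#' the first week of significant change from baseline, and maps each
#' comparative measure onto the percent-of-kidney-function scale with the
#' line-versus-polynomial model selection. All outputs are written as CSV
#' under `output_dir` together with a plain-text run manifest recording the
#' seed and configuration; the result bundle is also returned.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure) with optional entries `sessions_csv`, `endogenous_csv`
#'   (read inputs) or `simulate` (a list of [cohort_config] arguments;
#'   used when no `sessions_csv` is given), `methods`, `two_sample_times`,
#'   `threshold`, `t_min`, `alpha`, `adjust` (multiplicity correction for
#'   the sensitivity screen, `"holm"` or `"tukey"`), `reference` (list with
#'   `marker`,
#'   `method`; default inulin trapezoidal), `pairs` (schedule pairs
#'   data.frame or list).
#' @param output_dir directory for the CSV outputs; created if needed.
#'   `NULL` skips writing.
#' @param seed RNG seed used for simulation; default 1.
#' @return Invisibly, a list with `sessions`, `estimates`, `agreement`,
#'   `schedules`, `sensitivity`, `normalization`, `truth` (when
#'   simulated), and `config`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  methods <- get("methods", c("trapezoidal", "two_compartment",
                              "one_compartment", "two_sample"))
  two_sample_times <- as.numeric(get("two_sample_times", c(30, 90)))
  threshold <- get("threshold", 0.5)
  t_min <- get("t_min", 30)
  alpha <- get("alpha", 0.05)
  adjust <- get("adjust", "holm")
  reference <- get("reference", list(marker = "inulin",
                                     method = "trapezoidal"))
  pairs <- as.data.frame(get("pairs", default_schedule_pairs()))

  truth <- NULL
  endogenous <- NULL
  if (!is.null(config$sessions_csv)) {
    sessions <- read_sessions(config$sessions_csv)
    if (!is.null(config$endogenous_csv)) {
      endogenous <- utils::read.csv(config$endogenous_csv,
                                    stringsAsFactors = FALSE)
    }
  } else {
    sim_args <- get("simulate", list())
    for (nm in c("gfr_trajectory", "schedule_min")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- as.numeric(sim_args[[nm]])
    }
    if (!is.null(sim_args$dose_ug)) sim_args$dose_ug <- unlist(sim_args$dose_ug)
    cfg <- do.call(cohort_config, sim_args)
    cohort <- simulate_cohort(cfg, seed = seed)
    sessions <- cohort$sessions
    truth <- cohort$truth
    endogenous <- cohort$endogenous
  }

  estimates <- estimate_clearances(sessions, methods = methods,
                                   two_sample_times = two_sample_times,
                                   threshold = threshold, t_min = t_min)
  agreement <- compare_methods(estimates)

  markers <- unique(estimates$marker)
  schedules <- do.call(rbind, lapply(markers, function(mk) {
    ses <- Filter(function(s) s$marker == mk, sessions)
    times <- ses[[1L]]$samples$time_min
    ok <- pairs$t1 %in% times & pairs$t2 %in% times
    if (!any(ok)) return(NULL)
    sc <- evaluate_schedules(ses, pairs[ok, , drop = FALSE])
    cbind(marker = mk, sc)
  }))

  # sensitivity: first week each measure departs from baseline
  sens_inputs <- split(estimates[is.finite(estimates$clearance_ml_min), ],
                       paste(estimates$marker, estimates$method,
                             sep = "_")[is.finite(estimates$clearance_ml_min)])
  sensitivity <- do.call(rbind, lapply(names(sens_inputs), function(nm) {
    d <- sens_inputs[[nm]]
    w <- tryCatch(first_significant_week(d$clearance_ml_min, d$week,
                                         d$subject_id, alpha = alpha,
                                         adjust = adjust),
                  error = function(e) NA_integer_)
    data.frame(measure = nm, first_significant_week = as.integer(w))
  }))
  if (!is.null(endogenous)) {
    sens_endo <- do.call(rbind, lapply(split(endogenous, endogenous$marker),
                                       function(d) {
      w <- tryCatch(first_significant_week(d$value, d$week, d$subject_id,
                                           alpha = alpha, adjust = adjust),
                    error = function(e) NA_integer_)
      data.frame(measure = d$marker[1L], first_significant_week = as.integer(w))
    }))
    sensitivity <- rbind(sensitivity, sens_endo)
  }

  # percent-of-function normalization against the reference measure
  normalization <- NULL
  ref_est <- estimates[estimates$marker == reference$marker &
                         estimates$method == reference$method &
                         is.finite(estimates$clearance_ml_min), , drop = FALSE]
  if (nrow(ref_est) && any(ref_est$week == 0)) {
    ref_pct_all <- percent_of_baseline(ref_est$clearance_ml_min, ref_est$week)
    ref_key <- paste(ref_est$subject_id, ref_est$week, sep = "|")
    norm_one <- function(value, week, subject_id, measure, direction) {
      key <- paste(subject_id, week, sep = "|")
      idx <- match(key, ref_key)
      ok <- !is.na(idx) & is.finite(value)
      if (sum(ok) <= 8L || !any(week[ok] == 0)) return(NULL)
      ns <- normalize_to_function_scale(value[ok], week[ok],
                                        ref_pct_all[idx[ok]],
                                        direction = direction)
      sel <- select_line_vs_poly6(ns$reference_pct, ns$marker_pct,
                                  alpha = alpha)
      cbind(measure = measure, ns, chosen = sel$chosen,
            f_statistic = sel$f_statistic, p_value = sel$p_value)
    }
    norm <- list()
    for (nm in names(sens_inputs)) {
      d <- sens_inputs[[nm]]
      if (nm == paste(reference$marker, reference$method, sep = "_")) next
      norm[[nm]] <- norm_one(d$clearance_ml_min, d$week, d$subject_id, nm,
                             "decreases")
    }
    if (!is.null(endogenous)) {
      for (d in split(endogenous, endogenous$marker)) {
        norm[[d$marker[1L]]] <- norm_one(d$value, d$week, d$subject_id,
                                         d$marker[1L], "increases")
      }
    }
    normalization <- do.call(rbind, norm)
    if (!is.null(normalization)) rownames(normalization) <- NULL
  }

  result <- list(sessions = sessions, estimates = estimates,
                 agreement = agreement, schedules = schedules,
                 sensitivity = sensitivity, normalization = normalization,
                 truth = truth, endogenous = endogenous,
                 config = config, seed = seed)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, name) {
      if (!is.null(d)) {
        utils::write.csv(d, file.path(output_dir, name), row.names = FALSE)
      }
    }
    write_sessions(sessions, file.path(output_dir, "sessions.csv"))
    wr(estimates, "estimates.csv")
    wr(agreement, "agreement.csv")
    wr(schedules, "schedules.csv")
    wr(sensitivity, "sensitivity.csv")
    wr(normalization, "normalization.csv")
    wr(endogenous, "endogenous.csv")
    wr(truth, "truth.csv")
    manifest <- c(sprintf("gfrpc %s", as.character(utils::packageVersion("gfrpc"))),
                  sprintf("seed: %d", seed),
                  sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                  "config:",
                  paste0("  ", utils::capture.output(utils::str(config))))
    writeLines(manifest, file.path(output_dir, "run_manifest.txt"))
  }
  invisible(result)
}
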