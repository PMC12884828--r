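#' Study design for the synthetic experience-sampling generator
#'
#' Describes a measurement-burst design: `n_waves` bursts of
#' `n_days_per_wave` consecutive days with `beeps_per_day` semi-random
#' prompts per day. Participants are assigned to one of `n_schedules`
#' wake-time-anchored beep schedules; the first prompt of a day falls at
#' least `min_first_beep_offset` minutes after the schedule's wake time and
#' consecutive same-day prompts are separated by gaps drawn uniformly from
#' `beep_gap_range` hours. Morning surveys (sleep items, bed/rise times) are
#' attached to each day.
#'
#' `target_mean_within_gap` and `target_mean_overnight_gap` document the
#' interval means the design aims for; they are also the defaults fed to
#' [interval_ratios()] downstream. With the default uniform 2-3 h gaps the
#' realized means are close to (slightly below/above) these targets.
#'
#' @param n_persons number of participants.
#' @param n_waves number of bursts (default 3).
#' @param n_days_per_wave days per burst (default 14).
#' @param beeps_per_day daily prompts (default 5).
#' @param n_schedules number of wake-time schedules (default 7).
#' @param wake_time_range clock-hour interval the schedules span (default
#'   `c(5, 11)`, i.e. 5 AM to 11 AM, quantized to whole hours).
#' @param min_first_beep_offset minutes between wake time and the earliest
#'   possible first prompt (default 55).
#' @param first_beep_jitter hours of uniform jitter added to the first
#'   prompt after the minimum offset (default 1).
#' @param latest_beep latest clock hour any prompt may occur (default
#'   23 + 55/60, i.e. 11:55 PM).
#' @param beep_gap_range hours; uniform support for same-day gaps
#'   (default `c(2, 3)`).
#' @param target_mean_within_gap,target_mean_overnight_gap documented design
#'   targets in hours (defaults 2.6 and 13.7).
#' @param wave_gap_days days between the start of consecutive waves
#'   (default 270, roughly nine months).
#' @param compliance probability that a prompted beep is answered
#'   (default 0.8).
#' @param seed default seed used by [simulate_ema()] when none is given.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_persons,
                         n_waves = 3L,
                         n_days_per_wave = 14L,
                         beeps_per_day = 5L,
                         n_schedules = 7L,
                         wake_time_range = c(5, 11),
                         min_first_beep_offset = 55,
                         first_beep_jitter = 1,
                         latest_beep = 23 + 55 / 60,
                         beep_gap_range = c(2, 3),
                         target_mean_within_gap = 2.6,
                         target_mean_overnight_gap = 13.7,
                         wave_gap_days = 270,
                         compliance = 0.8,
                         seed = 1L) {
  stopifnot(n_persons >= 1, n_waves >= 1, n_days_per_wave >= 1)
  if (beeps_per_day < 2) stop("beeps_per_day must be at least 2")
  if (beep_gap_range[1] <= 0 || beep_gap_range[2] < beep_gap_range[1])
    stop("beep_gap_range must be a positive increasing interval")
  if (compliance <= 0 || compliance > 1)
    stop("compliance must be in (0, 1]")
  structure(list(
    n_persons = as.integer(n_persons), n_waves = as.integer(n_waves),
    n_days_per_wave = as.integer(n_days_per_wave),
    beeps_per_day = as.integer(beeps_per_day),
    n_schedules = as.integer(n_schedules),
    wake_time_range = wake_time_range,
    min_first_beep_offset = min_first_beep_offset,
    first_beep_jitter = first_beep_jitter,
    latest_beep = latest_beep,
    beep_gap_range = beep_gap_range,
    target_mean_within_gap = target_mean_within_gap,
    target_mean_overnight_gap = target_mean_overnight_gap,
    wave_gap_days = wave_gap_days,
    compliance = compliance,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' Ground-truth parameters of the generating process
#'
#' Parameters of the multilevel AR model used to generate synthetic affect
#' series: fixed effects (`gamma00` intercept, `gamma10` overnight level
#' shift, `gamma20` within-day AR, `gamma30` overnight AR), person random
#' effect SDs `sd_u` for (intercept, overnight, within-day AR, overnight AR)
#' with correlation matrix `re_correlations`, wave- and day-level intercept
#' SDs, and the residual SD.
#'
#' `regime` selects the overnight process. Under `"continue"` the overnight
#' coefficient is forced to `gamma20^(dt_night/dt_within)` (the exponential
#' decay of the within-day AR over the full overnight interval); under
#' `"pause"` to `gamma20^((dt_night - time_in_bed)/dt_within)` (decay over
#' awake time only); under `"stop"` to 0. Under `"different"` the supplied
#' `gamma30` is used as-is.
#'
#' @param gamma00,gamma10,gamma20,gamma30 fixed effects (defaults: the
#'   negative-affect column of the worked reference fit).
#' @param sd_u length-4 vector of person random-effect SDs.
#' @param re_correlations 4x4 correlation matrix for the person effects.
#' @param sd_wave,sd_day,sd_resid wave/day intercept SDs and residual SD.
#' @param regime one of `"continue"`, `"pause"`, `"stop"`, `"different"`.
#' @param dt_within,dt_night,time_in_bed interval constants (hours) used to
#'   derive regime-implied overnight coefficients.
#' @param item_loadings length-4 loadings mapping the 0-10 composite to the
#'   0-100 items.
#' @param item_error_sd SD of item-level noise on the 0-100 scale.
#' @param p_stressor long-run probability of a momentary stressor report.
#' @param moderation_effects named list; each element is a list with fields
#'   `rule` (one of `"momentary_at_t"`, `"interval_event"`,
#'   `"morning_of_day"`, `"between_only"`) and any of `on_level`,
#'   `on_ar_within`, `on_ar_overnight` (effects of the person-centered
#'   momentary value) and `between_on_level`, `between_on_ar_within`,
#'   `between_on_ar_overnight` (effects of the grand-centered person mean).
#' @return object of class `truth_params`.
#' @export
truth_params <- function(gamma00 = 1.549, gamma10 = 0.180,
                         gamma20 = 0.280, gamma30 = 0.190,
                         sd_u = c(1.049, 0.241, 0.157, 0.147),
                         re_correlations = default_re_correlations(),
                         sd_wave = 0.431, sd_day = 0.337, sd_resid = 1.0,
                         regime = c("different", "continue", "pause", "stop"),
                         dt_within = 2.6, dt_night = 13.7, time_in_bed = 7.7,
                         item_loadings = rep(1, 4), item_error_sd = 5,
                         p_stressor = 0.16,
                         moderation_effects = list()) {
  regime <- match.arg(regime)
  stopifnot(length(sd_u) == 4, all(sd_u >= 0), sd_wave >= 0, sd_day >= 0,
            sd_resid >= 0)
  if (!isTRUE(all.equal(diag(re_correlations), rep(1, 4), check.attributes = FALSE)))
    stop("re_correlations must have unit diagonal")
  ev <- eigen(re_correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("re_correlations must be positive semi-definite")
  ratio_full <- dt_night / dt_within
  ratio_corr <- (dt_night - time_in_bed) / dt_within
  gamma30 <- switch(regime,
    continue  = extrapolate_ar(gamma20, ratio_full),
    pause     = extrapolate_ar(gamma20, ratio_corr),
    stop      = 0,
    different = gamma30
  )
  bad <- setdiff(unlist(lapply(moderation_effects, function(e) e$rule)),
                 c("momentary_at_t", "interval_event", "morning_of_day",
                   "between_only"))
  if (length(bad)) stop("unknown alignment rule: ", paste(bad, collapse = ", "))
  structure(list(
    gamma00 = gamma00, gamma10 = gamma10, gamma20 = gamma20, gamma30 = gamma30,
    sd_u = sd_u, re_correlations = re_correlations,
    sd_wave = sd_wave, sd_day = sd_day, sd_resid = sd_resid,
    regime = regime, dt_within = dt_within, dt_night = dt_night,
    time_in_bed = time_in_bed,
    item_loadings = item_loadings, item_error_sd = item_error_sd,
    p_stressor = p_stressor,
    moderation_effects = moderation_effects
  ), class = "truth_params")
}

#' Generating truth for the regime-recovery experiment
#'
#' Preset truths under which the four overnight regimes are mutually
#' separable at a typical design size. Under `"different"` the
#' negative-affect reference truth is used (its overnight coefficient of
#' 0.19 is far from both decay extrapolations, roughly 0.001 and 0.05).
#' Under `"continue"`, `"pause"` and `"stop"` a high-inertia process with a
#' within-day AR of 0.7 is used: its full-interval extrapolation (about
#' 0.15) and awake-time extrapolation (about 0.44) are mutually distinct
#' and distinct from zero relative to posterior uncertainty, which a
#' within-day AR as low as 0.28 can never achieve for continue vs. stop
#' (their implied overnight coefficients differ by about 0.001). The slope
#' random-effect SDs are reduced to 0.08 so that essentially every person's
#' AR coefficient stays inside the stationary region.
#'
#' @param regime one of `"continue"`, `"pause"`, `"stop"`, `"different"`.
#' @param ... overrides passed to [truth_params()].
#' @return object of class `truth_params`.
#' @export
regime_truth <- function(regime = c("continue", "pause", "stop", "different"),
                         ...) {
  regime <- match.arg(regime)
  if (regime == "different") default_truth("na", regime = "different", ...)
  else default_truth("na", gamma20 = 0.7,
                     sd_u = c(1.049, 0.241, 0.08, 0.08), regime = regime, ...)
}

#' Default person random-effect correlation matrix
#'
#' Identity except for a 0.6 correlation between the within-day and
#' overnight inertia slopes, reflecting that people with more within-day
#' inertia also tend to show more overnight inertia.
#' @return 4x4 correlation matrix.
#' @export
default_re_correlations <- function() {
  R <- diag(4)
  R[3, 4] <- R[4, 3] <- 0.6
  dimnames(R) <- rep(list(c("intercept", "overnight", "ar_within", "ar_overnight")), 2)
  R
}

#' Write / read design and truth configuration
#'
#' Serializes a [study_design()] and/or [truth_params()] to a single YAML
#' (default) or JSON file and reads it back, so simulation configurations
#' can be version-controlled and shared.
#'
#' @param design a [study_design()] or `NULL`.
#' @param truth a [truth_params()] or `NULL`.
#' @param file path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_config` returns `file` invisibly; `read_config` returns
#'   a list with `design` and `truth` (either may be `NULL`).
#' @export
write_config <- function(design = NULL, truth = NULL, file) {
  enc <- function(x) {
    if (is.null(x)) return(NULL)
    out <- unclass(x)
    if (!is.null(out$re_correlations))
      out$re_correlations <- as.vector(out$re_correlations)
    if (!is.null(out$moderation_effects) && !length(out$moderation_effects))
      out$moderation_effects <- NULL
    out
  }
  obj <- list(design = enc(design), truth = enc(truth))
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(obj, file, precision = 15)
  } else {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
  else jsonlite::read_json(file, simplifyVector = TRUE)
  design <- if (!is.null(obj$design)) {
    d <- obj$design
    do.call(study_design, d[intersect(names(d), names(formals(study_design)))])
  }
  truth <- if (!is.null(obj$truth)) {
    t <- obj$truth
    if (!is.null(t$re_correlations))
      t$re_correlations <- matrix(unlist(t$re_correlations), 4, 4)
    t$regime <- t$regime %||% "different"
    keep <- intersect(names(t), names(formals(truth_params)))
    tr <- do.call(truth_params, t[setdiff(keep, "regime")])
    # gamma30 was already regime-resolved at write time; keep the label
    tr$regime <- t$regime
    tr
  }
  list(design = design, truth = truth)
}

#' Reference generating truths for negative and positive affect
#'
#' Convenience presets with the fixed effects and variance components of the
#' worked reference fit for negative affect (`"na"`) and positive affect
#' (`"pa"`). Residual SDs (not part of the reference table) are set so the
#' implied variance-explained shares are plausible: 1.0 (NA) and 1.2 (PA).
#'
#' @param outcome `"na"` or `"pa"`.
#' @param ... overrides passed on to [truth_params()].
#' @return object of class `truth_params`.
#' @export
default_truth <- function(outcome = c("na", "pa"), ...) {
  outcome <- match.arg(outcome)
  args <- if (outcome == "na") {
    list(gamma00 = 1.549, gamma10 = 0.180, gamma20 = 0.280,
         gamma30 = 0.190, sd_u = c(1.049, 0.241, 0.157, 0.147),
         sd_wave = 0.431, sd_day = 0.337, sd_resid = 1.0)
  } else {
    list(gamma00 = 3.962, gamma10 = 0.785, gamma20 = 0.355,
         gamma30 = 0.186, sd_u = c(1.455, 0.735, 0.138, 0.148),
         sd_wave = 0.409, sd_day = 0.365, sd_resid = 1.2)
  }
  do.call(truth_params, utils::modifyList(args, list(...)))
}
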