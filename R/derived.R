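#' Interval summary for decay extrapolation
#'
#' Computes the corrected overnight interval (overnight interval minus time
#' in bed, i.e. the approximate time awake during the night) and the two
#' exponents used to extrapolate the within-day autoregression: the full
#' overnight interval and the corrected interval, each expressed as a
#' multiple of the average within-day interval. Raw (unrounded) ratios are
#' retained; rounded versions are kept for reporting-level reproduction of
#' printed tables.
#'
#' @param dt_withinday average within-day interval in hours (default 2.6).
#' @param dt_night average overnight interval in hours (default 13.7).
#' @param time_in_bed average time in bed in hours (default 7.7).
#' @param rounding decimals used for the reporting-level ratios
#'   (default 1).
#' @return object of class `interval_summary` with fields
#'   `dt_night_corrected`, `ratio_full`, `ratio_corrected`,
#'   `ratio_full_rounded`, `ratio_corrected_rounded`.
#' @export
interval_ratios <- function(dt_withinday = 2.6, dt_night = 13.7,
                            time_in_bed = 7.7, rounding = 1) {
  if (dt_withinday <= 0 || dt_night <= 0 || time_in_bed <= 0)
    stop("all intervals must be positive")
  if (time_in_bed >= dt_night)
    stop("time_in_bed must be smaller than the overnight interval")
  corr <- dt_night - time_in_bed
  structure(list(
    dt_withinday = dt_withinday, dt_night = dt_night,
    time_in_bed = time_in_bed, dt_night_corrected = corr,
    ratio_full = dt_night / dt_withinday,
    ratio_corrected = corr / dt_withinday,
    ratio_full_rounded = round(dt_night / dt_withinday, rounding),
    ratio_corrected_rounded = round(corr / dt_withinday, rounding),
    rounding = rounding
  ), class = "interval_summary")
}

#' Exponential-decay extrapolation of an AR coefficient
#'
#' Under an AR(1) process, the autoregression over an interval `ratio`
#' times longer than the base interval is the base coefficient raised to
#' the power `ratio`. Negative coefficients use the sign-preserving
#' continuous extension `-|gamma|^ratio` so the transform is total on the
#' reals (relevant only for posterior tail draws).
#'
#' @param gamma AR coefficient (vectorized).
#' @param ratio positive interval ratio.
#' @return extrapolated coefficient(s).
#' @export
extrapolate_ar <- function(gamma, ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  sign(gamma) * abs(gamma)^ratio
}

#' Point-estimate overnight contrasts from posterior medians
#'
#' Worked-example version of the overnight contrasts: applies the decay
#' extrapolation to the within-day coefficient's point estimate and
#' subtracts from the overnight coefficient. Used to reproduce printed
#' table values from their reported medians.
#'
#' @param gamma20,gamma30 within-day and overnight AR point estimates.
#' @param intervals an [interval_ratios()].
#' @param use_rounded use the reporting-level rounded exponents
#'   (default TRUE, matching printed tables).
#' @return named list with `contrast_continue` and `contrast_pause`.
#' @export
contrast_from_medians <- function(gamma20, gamma30,
                                  intervals = interval_ratios(),
                                  use_rounded = TRUE) {
  rf <- if (use_rounded) intervals$ratio_full_rounded else intervals$ratio_full
  rc <- if (use_rounded) intervals$ratio_corrected_rounded else intervals$ratio_corrected
  list(contrast_continue = gamma30 - extrapolate_ar(gamma20, rf),
       contrast_pause = gamma30 - extrapolate_ar(gamma20, rc))
}

#' Posterior-derived overnight contrasts and process classification
#'
#' For each posterior draw, computes the difference between the overnight
#' AR coefficient and the exponential-decay extrapolation of the
#' within-day AR coefficient over (a) the full overnight interval
#' (`contrast_continue`) and (b) the corrected, awake-time interval
#' (`contrast_pause`), then summarizes by posterior median and 95% HDI.
#' Point-estimate versions computed from the medians are attached for
#' worked-example checks, and the overnight process is classified via
#' [classify_process()].
#'
#' @param fit an `inertia_fit`, or a matrix/data frame with columns
#'   `gamma20` and `gamma30` of posterior draws.
#' @param intervals an [interval_ratios()].
#' @param use_rounded use rounded exponents in the per-draw transform
#'   (default FALSE: raw ratios).
#' @param prob HDI probability mass (default 0.95).
#' @return object of class `derived_summary`: list with `table` (median +
#'   HDI for gamma20, gamma30 and both contrasts), `point` (contrasts of
#'   the medians), `classification`, and the `intervals` used.
#' @export
overnight_contrasts <- function(fit, intervals = interval_ratios(),
                                use_rounded = FALSE, prob = 0.95) {
  if (inherits(fit, "inertia_fit")) {
    g20 <- posterior_draws(fit, "b_wd_lag")
    g30 <- posterior_draws(fit, "b_on_lag")
  } else {
    fit <- as.data.frame(fit)
    if (!all(c("gamma20", "gamma30") %in% names(fit)))
      stop("draws must contain gamma20 and gamma30")
    g20 <- fit$gamma20; g30 <- fit$gamma30
  }
  rf <- if (use_rounded) intervals$ratio_full_rounded else intervals$ratio_full
  rc <- if (use_rounded) intervals$ratio_corrected_rounded else intervals$ratio_corrected
  cc <- g30 - extrapolate_ar(g20, rf)
  cp <- g30 - extrapolate_ar(g20, rc)
  summ <- function(name, x) {
    h <- hdi(x, prob)
    tibble::tibble(quantity = name, median = stats::median(x),
                   lower = h[["lower"]], upper = h[["upper"]])
  }
  tab <- dplyr::bind_rows(summ("gamma20", g20), summ("gamma30", g30),
                          summ("contrast_continue", cc),
                          summ("contrast_pause", cp))
  out <- structure(list(
    table = tab,
    point = contrast_from_medians(stats::median(g20), stats::median(g30),
                                  intervals, use_rounded = use_rounded),
    intervals = intervals
  ), class = "derived_summary")
  out$classification <- classify_process(out)
  out
}

#' Classify the overnight process from HDI exclusion rules
#'
#' A candidate process is ruled out when the relevant 95% HDI excludes
#' zero: stopping is ruled out when the overnight coefficient's HDI
#' excludes 0; continuing when the continue-contrast HDI excludes 0;
#' pausing when the pause-contrast HDI excludes 0. If exactly one of
#' continue/pause/stop survives, that label is returned; if all three are
#' ruled out, `"different"`; if several survive, `"indeterminate"`.
#'
#' @param summary a `derived_summary` (from [overnight_contrasts()]), or a
#'   list with elements `gamma30`, `contrast_continue`, `contrast_pause`,
#'   each a length-2 numeric HDI `c(lower, upper)`.
#' @return character label.
#' @export
classify_process <- function(summary) {
  get_hdi <- function(q) {
    if (inherits(summary, "derived_summary")) {
      r <- summary$table[summary$table$quantity == q, ]
      c(r$lower, r$upper)
    } else summary[[q]]
  }
  excludes0 <- function(h) h[1] > 0 || h[2] < 0
  ruled_out <- c(
    stop = excludes0(get_hdi("gamma30")),
    continue = excludes0(get_hdi("contrast_continue")),
    pause = excludes0(get_hdi("contrast_pause"))
  )
  survivors <- names(ruled_out)[!ruled_out]
  if (length(survivors) == 0) "different"
  else if (length(survivors) == 1) survivors
  else "indeterminate"
}
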