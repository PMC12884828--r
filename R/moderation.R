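#' Moderation model specification
#'
#' Extends the base inertia model with one covariate at a time: main
#' effect(s) of the covariate's within- and between-person components plus
#' their cross-level interactions with the overnight dummy and both lag
#' terms. Time-varying covariates contribute both components (8 new fixed
#' effects); between-only covariates contribute a grand-mean-centered main
#' effect and three interactions (4 new fixed effects). The lagged affect
#' enters person-mean-centered, and moderation coefficients are fixed
#' effects (the random structure is unchanged).
#'
#' @param covariate covariate name. Time-varying: a beep-level column
#'   (`"urt"`, `"stressor"`) or `"sleep_quality"` from the morning table;
#'   between-only: a trait column from the person table, or
#'   `"stressor_prop"` for the person's proportion of beeps with a
#'   stressor.
#' @param kind `"time_varying"` or `"between_only"`.
#' @param rule alignment rule for time-varying covariates:
#'   `"momentary_at_t"` (the beep-t report moderates the interval ending at
#'   t), `"interval_event"` (the beep-t report covers the interval
#'   (t-1, t]), or `"morning_of_day"` (day d's morning report attaches to
#'   day d's overnight and within-day rows).
#' @param base a [model_spec()]; its centering is forced to
#'   `"person_mean"`.
#' @return object of class `moderation_spec`.
#' @export
moderation_spec <- function(covariate,
                            kind = c("time_varying", "between_only"),
                            rule = c("momentary_at_t", "interval_event",
                                     "morning_of_day"),
                            base = model_spec()) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  structure(list(covariate = covariate, kind = kind, rule = rule),
            class = "moderation_spec")
}

#' Attach a covariate to lagged rows according to an alignment rule
#'
#' Adds `<covariate>_aligned` to the lagged data: the value moderating the
#' interval that ends at each row. `momentary_at_t` and `interval_event`
#' attach the row's own beep-level report; `morning_of_day` attaches the
#' morning report of the row's calendar day (which covers both the
#' overnight transition into that day and the day's within-day
#' transitions).
#'
#' @param lagged a `lagged_ema` object.
#' @param covariate covariate name.
#' @param rule one of `"momentary_at_t"`, `"interval_event"`,
#'   `"morning_of_day"`.
#' @return the `lagged_ema` with the aligned column added.
#' @export
align_covariate <- function(lagged, covariate,
                            rule = c("momentary_at_t", "interval_event",
                                     "morning_of_day")) {
  rule <- match.arg(rule)
  b <- lagged$data
  if (rule %in% c("momentary_at_t", "interval_event")) {
    if (!covariate %in% names(b)) stop("unknown covariate: ", covariate)
    v <- b[[covariate]]
  } else {
    m <- lagged$mornings
    if (is.null(m) || !covariate %in% names(m))
      stop("unknown morning covariate: ", covariate)
    key <- paste(b$person_id, b$wave, b$day)
    v <- m[[covariate]][match(key, paste(m$person_id, m$wave, m$day))]
  }
  b[[paste0(covariate, "_aligned")]] <- v
  lagged$data <- b
  lagged
}

# Build the moderation design columns on eligible rows. `d` is the eligible
# subset of the lagged data; wd_lag/on_lag are the (centered) base lag
# columns.
moderation_columns <- function(d, mspec, wd_lag, on_lag) {
  cov <- mspec$covariate
  if (mspec$kind == "time_varying") {
    wcol <- paste0(cov, "_aligned_w"); bcol <- paste0(cov, "_aligned_b")
    if (!all(c(wcol, bcol) %in% names(d)))
      stop("covariate ", cov, " not aligned/decomposed; run align_covariate()",
           " and center_and_decompose() first")
    w <- d[[wcol]]; bt <- d[[bcol]]
    out <- cbind(w, bt, w * d$overnight, w * wd_lag, w * on_lag,
                 bt * d$overnight, bt * wd_lag, bt * on_lag)
    colnames(out) <- paste0(cov, c("_w", "_b", "_w:overnight", "_w:wd_lag",
                                   "_w:on_lag", "_b:overnight", "_b:wd_lag",
                                   "_b:on_lag"))
  } else {
    ccol <- paste0(cov, "_c")
    if (!ccol %in% names(d))
      stop("trait covariate ", cov, " not centered; run attach_trait() first")
    v <- d[[ccol]]
    out <- cbind(v, v * d$overnight, v * wd_lag, v * on_lag)
    colnames(out) <- paste0(cov, c("_c", "_c:overnight", "_c:wd_lag",
                                   "_c:on_lag"))
  }
  if (any(apply(out, 2, stats::sd) == 0))
    stop("degenerate (constant) moderation column for covariate ", cov)
  out
}

#' Attach a grand-mean-centered trait covariate to lagged rows
#'
#' Traits come from the person table; `"stressor_prop"` is computed as each
#' person's proportion of answered beeps reporting a stressor. Centering is
#' on the grand mean across persons.
#'
#' @param lagged a `lagged_ema` object.
#' @param covariate trait name.
#' @return the `lagged_ema` with `<covariate>_c` added.
#' @export
attach_trait <- function(lagged, covariate) {
  b <- lagged$data
  if (covariate == "stressor_prop") {
    v_person <- tapply(b$stressor, b$person_id, mean, na.rm = TRUE)
    ids <- as.numeric(names(v_person))
  } else {
    p <- lagged$persons
    if (is.null(p) || !covariate %in% names(p))
      stop("unknown trait covariate: ", covariate)
    v_person <- p[[covariate]]
    ids <- p$person_id
  }
  vc <- v_person - mean(v_person, na.rm = TRUE)
  b[[paste0(covariate, "_c")]] <- vc[match(b$person_id, ids)]
  lagged$data <- b
  lagged
}

#' Prepare data and model spec for a moderation fit
#'
#' Convenience wrapper: aligns the covariate, decomposes it (time-varying)
#' or centers it (between-only), and returns the lagged data together with
#' an extended [model_spec()] using the person-mean-centered lag. The
#' number of added fixed effects is 8 for time-varying covariates and 4
#' for between-only covariates.
#'
#' @param lagged a `lagged_ema` object.
#' @param mspec a [moderation_spec()].
#' @param outcome outcome name (default `"na"`).
#' @param priors a [prior_spec()].
#' @return list with `lagged` (prepared data) and `spec` (extended model
#'   spec).
#' @export
build_moderation_model <- function(lagged, mspec, outcome = "na",
                                   priors = prior_spec()) {
  if (mspec$kind == "time_varying") {
    lagged <- align_covariate(lagged, mspec$covariate, mspec$rule)
    lagged <- center_and_decompose(lagged, "person_mean",
                                   covariates = paste0(mspec$covariate,
                                                       "_aligned"))
  } else {
    lagged <- center_and_decompose(lagged, "person_mean")
    lagged <- attach_trait(lagged, mspec$covariate)
  }
  spec <- model_spec(outcome = outcome, centering = "person_mean",
                     priors = priors, moderation = mspec)
  list(lagged = lagged, spec = spec)
}

#' Fit a one-covariate moderation model
#'
#' @param lagged a `lagged_ema` object.
#' @param mspec a [moderation_spec()].
#' @param outcome outcome name.
#' @inheritParams fit_inertia
#' @return an `inertia_fit`.
#' @export
fit_moderation <- function(lagged, mspec, outcome = "na", chains = 4,
                           iter = 1500, warmup = 500, seed = 1) {
  prep <- build_moderation_model(lagged, mspec, outcome = outcome)
  fit_inertia(prep$lagged, prep$spec, chains = chains, iter = iter,
              warmup = warmup, seed = seed)
}

#' Summarize a moderation fit as a table row set
#'
#' Medians, 95% HDIs and HDI-excludes-zero flags for the covariate's
#' interactions with the within-day and overnight lag terms (and the
#' overnight dummy and main effects), split into within- and
#' between-person components.
#'
#' @param fit an `inertia_fit` from [fit_moderation()].
#' @param prob HDI probability mass (default 0.95).
#' @return tibble with columns `term`, `component`, `target`, `median`,
#'   `lower`, `upper`, `significant`.
#' @export
moderation_table <- function(fit, prob = 0.95) {
  mspec <- fit$spec$moderation
  if (is.null(mspec)) stop("fit has no moderation terms")
  cov <- mspec$covariate
  pars <- grep(paste0("^b_", cov, "_"), fit$par_names, value = TRUE)
  rows <- lapply(pars, function(p) {
    x <- posterior_draws(fit, p)
    h <- hdi(x, prob)
    nm <- sub("^b_", "", p)
    comp <- if (grepl("_w(:|$)", nm)) "within" else "between"
    target <- if (grepl(":wd_lag$", nm)) "withinday_inertia"
      else if (grepl(":on_lag$", nm)) "overnight_inertia"
      else if (grepl(":overnight$", nm)) "overnight_level"
      else "main_effect"
    tibble::tibble(term = nm, component = comp, target = target,
                   median = stats::median(x), lower = h[["lower"]],
                   upper = h[["upper"]],
                   significant = h[["lower"]] > 0 | h[["upper"]] < 0)
  })
  dplyr::bind_rows(rows)
}
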