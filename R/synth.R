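#' Build a wake-time-anchored beep schedule
#'
#' Generates prompt times (clock hours) for each day of one burst. The first
#' prompt of a day occurs at least `min_first_beep_offset` minutes after the
#' wake time, plus uniform jitter; consecutive same-day gaps are drawn
#' uniformly from `beep_gap_range`. If the drawn gaps would push a prompt
#' past `latest_beep`, the day's gaps are rescaled to fit (this binds only
#' for the latest schedules).
#'
#' @param design a [study_design()].
#' @param wake_time clock hour of habitual wake time; must lie in
#'   `design$wake_time_range`.
#' @param n_days number of days to schedule (default one burst).
#' @param seed optional seed.
#' @return numeric matrix `n_days x beeps_per_day` of clock hours.
#' @export
build_beep_schedule <- function(design, wake_time,
                                n_days = design$n_days_per_wave, seed = NULL) {
  if (wake_time < design$wake_time_range[1] ||
      wake_time > design$wake_time_range[2])
    stop("wake_time outside the design's wake_time_range")
  with_seed(seed, {
    k <- design$beeps_per_day
    out <- matrix(NA_real_, n_days, k)
    for (d in seq_len(n_days)) {
      first <- wake_time + design$min_first_beep_offset / 60 +
        stats::runif(1, 0, design$first_beep_jitter)
      gaps <- stats::runif(k - 1, design$beep_gap_range[1], design$beep_gap_range[2])
      avail <- design$latest_beep - first
      if (sum(gaps) > avail) gaps <- gaps * avail / sum(gaps)
      out[d, ] <- first + c(0, cumsum(gaps))
    }
    out
  })
}

# Assign each person a schedule (wake quantized to whole hours across the
# range) and lay out all (wave, day, beep) timestamps in hours since study
# start.
build_skeleton <- function(design) {
  wakes <- round(seq(design$wake_time_range[1], design$wake_time_range[2],
                     length.out = design$n_schedules))
  wake_of <- wakes[1 + (seq_len(design$n_persons) - 1) %% design$n_schedules]
  rows <- vector("list", design$n_persons)
  for (i in seq_len(design$n_persons)) {
    per_wave <- vector("list", design$n_waves)
    for (w in seq_len(design$n_waves)) {
      sched <- build_beep_schedule(design, wake_of[i])
      offset <- (w - 1) * design$wave_gap_days * 24
      per_wave[[w]] <- tibble::tibble(
        person_id = i, wave = w,
        day = rep(seq_len(design$n_days_per_wave), each = design$beeps_per_day),
        beep = rep(seq_len(design$beeps_per_day), design$n_days_per_wave),
        clock = as.vector(t(sched)),
        timestamp = offset + (rep(seq_len(design$n_days_per_wave),
                                  each = design$beeps_per_day) - 1) * 24 +
          as.vector(t(sched))
      )
    }
    rows[[i]] <- dplyr::bind_rows(per_wave)
  }
  list(beeps = dplyr::bind_rows(rows), wake_of = wake_of)
}

format_clock12 <- function(hours) {
  hours <- hours %% 24
  h <- floor(hours); m <- round((hours - h) * 60)
  h[m == 60] <- h[m == 60] + 1; m[m == 60] <- 0
  ampm <- ifelse(h %% 24 >= 12, "PM", "AM")
  h12 <- h %% 12; h12[h12 == 0] <- 12
  sprintf("%d:%02d %s", h12, m, ampm)
}

#' Generate momentary and trait covariates for a scheduled skeleton
#'
#' Adds unconstructive repetitive thoughts (three 0-100 items plus a 0-10
#' composite), binary stressor reports, morning sleep quality (four 0-100
#' items, composite, bed/rise clock strings, time in bed), and person-level
#' trait scores. Population means and spreads follow the descriptive table
#' of the reference study. Latent person means are kept as attributes so
#' affect generation can apply moderation effects on exactly centered
#' values.
#'
#' @param skeleton list with `beeps` tibble (from the internal skeleton
#'   builder) or an `ema_data` object whose beeps are used as the skeleton.
#' @param truth a [truth_params()].
#' @param design the [study_design()].
#' @param seed optional seed.
#' @return list with `beeps` (covariate columns added), `mornings`,
#'   `persons`.
#' @export
simulate_covariates <- function(skeleton, truth, design, seed = NULL) {
  with_seed(seed, {
    beeps <- skeleton$beeps
    n <- design$n_persons
    # momentary unconstructive repetitive thoughts
    urt_mean <- clip(stats::rnorm(n, 3.5, 1.0), 0.5, 9.5)
    urt_lat <- urt_mean[beeps$person_id] + stats::rnorm(nrow(beeps), 0, 1.8)
    urt <- clip(urt_lat, 0, 10)
    urt_items <- sapply(1:3, function(j)
      clip(urt * 10 + stats::rnorm(nrow(beeps), 0, truth$item_error_sd), 0, 100))
    beeps$urt_1 <- urt_items[, 1]; beeps$urt_2 <- urt_items[, 2]
    beeps$urt_3 <- urt_items[, 3]
    beeps$urt <- urt
    beeps$stressor <- stats::rbinom(nrow(beeps), 1, truth$p_stressor)

    # mornings: one row per (person, wave, day)
    mornings <- dplyr::distinct(beeps, .data$person_id, .data$wave, .data$day)
    sq_mean <- clip(stats::rnorm(n, 6.4, 1.2), 0.5, 9.5)
    sq_lat <- sq_mean[mornings$person_id] + stats::rnorm(nrow(mornings), 0, 1.5)
    sq <- clip(sq_lat, 0, 10)
    mornings$sleep_1 <- clip(sq * 10 + stats::rnorm(nrow(mornings), 0, truth$item_error_sd), 0, 100)
    mornings$sleep_2 <- clip(sq * 10 + stats::rnorm(nrow(mornings), 0, truth$item_error_sd), 0, 100)
    # items 3 and 4 are difficulty items, stored reverse-keyed (high = worse)
    mornings$sleep_3 <- clip(100 - sq * 10 + stats::rnorm(nrow(mornings), 0, truth$item_error_sd), 0, 100)
    mornings$sleep_4 <- clip(100 - sq * 10 + stats::rnorm(nrow(mornings), 0, truth$item_error_sd), 0, 100)
    mornings$sleep_quality <- sq
    wake_of <- skeleton$wake_of %||% rep(8, n)
    rise <- wake_of[mornings$person_id] + stats::rnorm(nrow(mornings), 0, 0.5)
    tib <- clip(stats::rnorm(nrow(mornings), 7.7, 1.4), 4, 12)
    mornings$rise_time <- format_clock12(rise)
    mornings$bed_time <- format_clock12(rise - tib)
    mornings$time_in_bed <- round(tib, 2)

    # person-level traits (means/SDs from the reference descriptives)
    persons <- tibble::tibble(
      person_id = seq_len(n),
      neuroticism = clip(stats::rnorm(n, 2.49, 0.63), 1, 5),
      rumination = clip(stats::rnorm(n, 3.01, 0.78), 0, 5),
      perceived_stress = clip(stats::rnorm(n, 1.76, 0.49), 1, 5),
      depression = clip(stats::rnorm(n, 1.93, 0.80), 1, 5),
      anxiety = clip(stats::rnorm(n, 2.39, 0.75), 1, 5),
      life_satisfaction = clip(stats::rnorm(n, 3.67, 1.34), 1, 7)
    )
    attr(beeps, "urt_person_mean") <- urt_mean
    attr(mornings, "sq_person_mean") <- sq_mean
    list(beeps = beeps, mornings = mornings, persons = persons)
  })
}

# Per-row coefficient adjustments implied by the moderation effects. Uses
# the latent person means for exact centering of time-varying covariates.
moderation_adjustments <- function(beeps, mornings, persons, truth) {
  n_rows <- nrow(beeps)
  adj <- list(level = numeric(n_rows), ar_w = numeric(n_rows),
              ar_o = numeric(n_rows))
  effs <- truth$moderation_effects
  if (!length(effs)) return(adj)
  urt_pm <- attr(beeps, "urt_person_mean")
  sq_pm <- attr(mornings, "sq_person_mean")
  for (nm in names(effs)) {
    e <- effs[[nm]]
    rule <- e$rule %||% "momentary_at_t"
    if (rule == "between_only") {
      v <- persons[[nm]]
      if (is.null(v)) stop("unknown covariate: ", nm)
      vc <- (v - mean(v))[beeps$person_id]
      adj$level <- adj$level + (e$on_level %||% 0) * vc
      adj$ar_w <- adj$ar_w + (e$on_ar_within %||% 0) * vc
      adj$ar_o <- adj$ar_o + (e$on_ar_overnight %||% 0) * vc
    } else {
      if (rule == "morning_of_day") {
        key <- paste(beeps$person_id, beeps$wave, beeps$day)
        mkey <- paste(mornings$person_id, mornings$wave, mornings$day)
        v <- mornings$sleep_quality[match(key, mkey)]
        pm <- sq_pm[beeps$person_id]
      } else {
        v <- beeps[[nm]]
        if (is.null(v)) stop("unknown covariate: ", nm)
        pm <- if (nm == "urt" && !is.null(urt_pm)) urt_pm[beeps$person_id]
              else stats::ave(v, beeps$person_id)
      }
      w <- v - pm
      b <- pm - mean(pm)
      adj$level <- adj$level + (e$on_level %||% 0) * w +
        (e$between_on_level %||% 0) * b
      adj$ar_w <- adj$ar_w + (e$on_ar_within %||% 0) * w +
        (e$between_on_ar_within %||% 0) * b
      adj$ar_o <- adj$ar_o + (e$on_ar_overnight %||% 0) * w +
        (e$between_on_ar_overnight %||% 0) * b
    }
  }
  adj
}

#' Simulate affect series on a scheduled skeleton
#'
#' Generates a momentary affect composite from the multilevel AR model:
#' person effects (u0..u3) drawn from a multivariate normal with the truth's
#' SDs and correlations, wave- and day-level intercept deviations, and
#' row-wise means using the previous prompt's value with the within-day AR
#' on same-day rows and the overnight AR (plus the overnight level shift) on
#' each day's first prompt. Each wave's first prompt is initialized at a
#' draw from the person's within-day stationary distribution. The composite
#' is kept on the model's (unbounded) scale; the bounded 0-100 items are
#' rendered from it via `item_loadings` plus clipped noise.
#'
#' @param skeleton covariate-augmented skeleton (see
#'   [simulate_covariates()]); covariates are only required when
#'   `truth$moderation_effects` is non-empty.
#' @param truth a [truth_params()].
#' @param design the [study_design()].
#' @param outcome name for the generated composite column (`"na"` or
#'   `"pa"`); items get names like `na_1..na_4`.
#' @param gap_bounds within-day and overnight gap windows (hours) defining
#'   which transitions follow the AR equations; must match the bounds used
#'   at analysis time. Rows with no admissible predecessor (start of a
#'   wave, or an out-of-bounds/non-adjacent gap) are drawn from the
#'   person's stationary distribution.
#' @param seed optional seed.
#' @return the skeleton's beeps tibble with composite and item columns
#'   added; person effects stored in `attr(, "person_effects")`.
#' @export
simulate_affect <- function(skeleton, truth, design, outcome = "na",
                            gap_bounds = list(withinday = c(1, 4),
                                              overnight = c(10, 17)),
                            seed = NULL) {
  with_seed(seed, {
    beeps <- skeleton$beeps
    urt_pm_attr <- attr(beeps, "urt_person_mean")
    n <- design$n_persons
    S <- diag(truth$sd_u) %*% truth$re_correlations %*% diag(truth$sd_u)
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-8) stop("random-effect covariance not PSD")
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    u <- matrix(stats::rnorm(n * 4), n, 4) %*% rt
    colnames(u) <- c("u0", "u1", "u2", "u3")

    adj <- moderation_adjustments(beeps, skeleton$mornings, skeleton$persons,
                                  truth)

    ord <- order(beeps$person_id, beeps$timestamp)
    beeps <- beeps[ord, ]
    adj <- lapply(adj, function(a) if (length(a) == nrow(beeps)) a[ord] else a)

    y <- numeric(nrow(beeps))
    pid <- beeps$person_id; wv <- beeps$wave; dy <- beeps$day
    bp <- beeps$beep; ts <- beeps$timestamp
    n_row <- nrow(beeps)
    same_wave <- c(FALSE, pid[-1] == pid[-n_row] & wv[-1] == wv[-n_row])
    same_day <- same_wave & c(FALSE, dy[-1] == dy[-n_row])
    adjacent <- same_day & c(FALSE, bp[-1] == bp[-n_row] + 1)
    gap <- c(NA_real_, ts[-1] - ts[-n_row])
    wd_tr <- adjacent & gap >= gap_bounds$withinday[1] &
      gap <= gap_bounds$withinday[2]
    on_tr <- same_wave & !same_day & gap >= gap_bounds$overnight[1] &
      gap <= gap_bounds$overnight[2]
    xi_key <- paste(pid, wv); xi_lv <- unique(xi_key)
    xi <- stats::rnorm(length(xi_lv), 0, truth$sd_wave)[match(xi_key, xi_lv)]
    zt_key <- paste(pid, wv, dy); zt_lv <- unique(zt_key)
    zeta <- stats::rnorm(length(zt_lv), 0, truth$sd_day)[match(zt_key, zt_lv)]
    eps <- stats::rnorm(n_row, 0, truth$sd_resid)

    for (r in seq_len(n_row)) {
      i <- pid[r]
      b2 <- truth$gamma20 + u[i, "u2"] + adj$ar_w[r]
      b3 <- truth$gamma30 + u[i, "u3"] + adj$ar_o[r]
      icpt <- truth$gamma00 + u[i, "u0"] + xi[r] + zeta[r] + adj$level[r]
      if (isTRUE(wd_tr[r])) {
        y[r] <- icpt + b2 * y[r - 1] + eps[r]
      } else if (isTRUE(on_tr[r])) {
        y[r] <- icpt + truth$gamma10 + u[i, "u1"] + b3 * y[r - 1] + eps[r]
      } else {
        # no admissible predecessor: draw from the person's stationary
        # distribution within this wave (independent of the current day's
        # deviation, which the likelihood conditions on)
        b2s <- min(max(b2, -0.95), 0.95)  # guard near unit roots
        mu_i <- (truth$gamma00 + u[i, "u0"] + xi[r]) / (1 - b2s)
        if (truth$sd_resid == 0) {
          y[r] <- mu_i
        } else {
          sd_st <- truth$sd_resid / sqrt(1 - b2s^2)
          y[r] <- mu_i + eps[r] / truth$sd_resid * sd_st
        }
      }
    }
    beeps[[outcome]] <- y
    n_items <- length(truth$item_loadings)
    for (j in seq_len(n_items)) {
      noise <- if (truth$item_error_sd > 0)
        stats::rnorm(nrow(beeps), 0, truth$item_error_sd) else 0
      beeps[[paste0(outcome, "_", j)]] <-
        clip(y * 10 * truth$item_loadings[j] + noise, 0, 100)
    }
    beeps <- beeps[order(ord), ]  # restore original row order
    attr(beeps, "urt_person_mean") <- urt_pm_attr
    attr(beeps, "person_effects") <- u
    skeleton$beeps <- beeps
    skeleton
  })
}

#' Thin an EMA dataset to a target compliance level
#'
#' Each beep row (and each morning row) is independently retained with
#' probability `compliance`, emulating completely-at-random nonresponse.
#'
#' @param ema an `ema_data` object (see [simulate_ema()]).
#' @param compliance retention probability in (0, 1].
#' @param seed optional seed.
#' @return the thinned `ema_data` object.
#' @export
apply_missingness <- function(ema, compliance, seed = NULL) {
  if (compliance <= 0 || compliance > 1) stop("compliance must be in (0, 1]")
  if (compliance == 1) return(ema)
  with_seed(seed, {
    keep_b <- stats::runif(nrow(ema$beeps)) < compliance
    keep_m <- stats::runif(nrow(ema$mornings)) < compliance
    a_b <- attr(ema$beeps, "urt_person_mean")
    a_m <- attr(ema$mornings, "sq_person_mean")
    ema$beeps <- ema$beeps[keep_b, ]
    ema$mornings <- ema$mornings[keep_m, ]
    attr(ema$beeps, "urt_person_mean") <- a_b
    attr(ema$mornings, "sq_person_mean") <- a_m
    ema
  })
}

#' Simulate a complete synthetic EMA dataset
#'
#' End-to-end generator: builds wake-time-anchored beep schedules, momentary
#' and trait covariates, negative- and positive-affect series from the
#' multilevel AR model, and beep-level missingness. Seeds for the stages
#' are derived deterministically from `seed`, so e.g. the affect stage is
#' reproducible independently of whether covariates carry moderation
#' effects.
#'
#' With `missingness = "pre"` (the default) the answered beeps are decided
#' first and the AR process is generated over the answered schedule, using
#' the same adjacency and gap-window rules the estimation stage applies;
#' the generated data then follow exactly the model being estimated, which
#' is what a parameter-recovery experiment requires. With
#' `missingness = "post"` the process is generated over the full schedule
#' (affect evolves through unanswered prompts) and rows are thinned
#' afterwards; this emulates how nonresponse works in reality and lets one
#' study the estimator's robustness to it.
#'
#' @param design a [study_design()].
#' @param truth_na generating truth for negative affect.
#' @param truth_pa generating truth for positive affect; `NULL` skips the
#'   positive-affect series.
#' @param missingness `"pre"` or `"post"` (see Details).
#' @param seed integer seed (default `design$seed`).
#' @return object of class `ema_data`: list with tibbles `beeps`,
#'   `mornings`, `persons`, plus `design` and the truths.
#' @export
simulate_ema <- function(design, truth_na = default_truth("na"),
                         truth_pa = default_truth("pa"),
                         missingness = c("pre", "post"),
                         seed = design$seed) {
  seed <- as.integer(seed)
  missingness <- match.arg(missingness)
  if (is.null(truth_na) && is.null(truth_pa))
    stop("at least one of truth_na, truth_pa must be given")
  truth_cov <- truth_na %||% truth_pa
  sk <- with_seed(seed, build_skeleton(design))
  sk <- simulate_covariates(sk, truth_cov, design, seed = seed + 1L)
  if (missingness == "pre" && design$compliance < 1) {
    sk_ema <- structure(list(beeps = sk$beeps, mornings = sk$mornings),
                        class = "ema_data")
    sk_ema <- apply_missingness(sk_ema, design$compliance, seed = seed + 4L)
    sk$beeps <- sk_ema$beeps
    sk$mornings <- sk_ema$mornings
  }
  u_na <- NULL
  if (!is.null(truth_na)) {
    sk <- simulate_affect(sk, truth_na, design, outcome = "na", seed = seed + 2L)
    u_na <- attr(sk$beeps, "person_effects")
  }
  u_pa <- NULL
  if (!is.null(truth_pa)) {
    sk <- simulate_affect(sk, truth_pa, design, outcome = "pa", seed = seed + 3L)
    u_pa <- attr(sk$beeps, "person_effects")
  }
  ema <- structure(list(beeps = sk$beeps, mornings = sk$mornings,
                        persons = sk$persons, design = design,
                        truth_na = truth_na, truth_pa = truth_pa,
                        person_effects = list(na = u_na, pa = u_pa)),
                   class = "ema_data")
  if (missingness == "post")
    ema <- apply_missingness(ema, design$compliance, seed = seed + 4L)
  ema
}

#' Write / read an EMA dataset as plain CSV files
#'
#' Three files are written: `beeps.csv` (one row per answered prompt),
#' `mornings.csv` (one row per morning survey), `persons.csv` (one row per
#' person with trait scores).
#'
#' @param ema an `ema_data` object.
#' @param dir directory to write to (created if needed).
#' @return `write_ema` returns `dir` invisibly; `read_ema` returns an
#'   `ema_data` object (without design/truth metadata).
#' @export
write_ema <- function(ema, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ema$beeps, file.path(dir, "beeps.csv"))
  readr::write_csv(ema$mornings, file.path(dir, "mornings.csv"))
  readr::write_csv(ema$persons, file.path(dir, "persons.csv"))
  invisible(dir)
}

#' @rdname write_ema
#' @param dir directory containing `beeps.csv`, `mornings.csv`,
#'   `persons.csv`.
#' @export
read_ema <- function(dir) {
  structure(list(
    beeps = readr::read_csv(file.path(dir, "beeps.csv"), show_col_types = FALSE),
    mornings = readr::read_csv(file.path(dir, "mornings.csv"), show_col_types = FALSE),
    persons = readr::read_csv(file.path(dir, "persons.csv"), show_col_types = FALSE),
    design = NULL, truth_na = NULL, truth_pa = NULL
  ), class = "ema_data")
}
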