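#' Composite scoring specification
#'
#' @param name scale name.
#' @param items character vector of item column names.
#' @param reverse_coded subset of `items` to reverse on the input range
#'   before averaging.
#' @param input_range numeric length-2, the item response range
#'   (default 0-100).
#' @param rescale_divisor divisor applied to the item average
#'   (default 10, mapping 0-100 items to a 0-10 composite).
#' @return object of class `composite_spec`.
#' @export
composite_spec <- function(name, items, reverse_coded = character(),
                           input_range = c(0, 100), rescale_divisor = 10) {
  stopifnot(length(items) >= 1)
  if (!all(reverse_coded %in% items))
    stop("reverse_coded must be a subset of items")
  structure(list(name = name, items = items, reverse_coded = reverse_coded,
                 input_range = input_range,
                 rescale_divisor = rescale_divisor),
            class = "composite_spec")
}

#' Compute a rescaled composite score
#'
#' Reverse-coded items are mapped `x -> max - x` on the input range, then
#' the mean over answered items is taken and divided by the rescale
#' divisor. Rows with all items missing get a missing composite.
#'
#' @param rows data frame holding the item columns.
#' @param spec a [composite_spec()].
#' @return numeric vector, one composite per row.
#' @export
compute_composite <- function(rows, spec) {
  missing_cols <- setdiff(spec$items, names(rows))
  if (length(missing_cols))
    stop("unknown item column(s): ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(rows[spec$items])
  for (it in spec$reverse_coded) {
    j <- match(it, spec$items)
    m[, j] <- spec$input_range[2] + spec$input_range[1] - m[, j]
  }
  out <- rowMeans(m, na.rm = TRUE) / spec$rescale_divisor
  out[!is.finite(out)] <- NA_real_
  out
}

parse_clock12 <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d{1,2}):(\\d{2})\\s*([AaPp])\\.?[Mm]\\.?\\s*$", x))
  vapply(m, function(p) {
    if (length(p) != 4) return(NA_real_)
    h <- as.numeric(p[2]); mn <- as.numeric(p[3])
    if (is.na(h) || h < 1 || h > 12 || mn > 59) return(NA_real_)
    h <- h %% 12
    if (toupper(p[4]) == "P") h <- h + 12
    h + mn / 60
  }, numeric(1))
}

#' Time in bed from 12-hour clock strings
#'
#' Duration from bed time to rise time, adding 24 h when the rise time
#' precedes the bed time on the clock. Implausibly long durations (above
#' the `plausible` window) are recoded by a deterministic rule ladder:
#' first toggle AM/PM on the bed time, then on the rise time; if no toggle
#' yields a plausible duration the value is set missing. Implausibly short
#' durations are treated as unrecoverable entry errors and set missing
#' directly (a toggle always shifts the duration by exactly 12 h, so a
#' near-zero duration would be "rescued" to a spurious ~12 h value).
#' Unparseable strings are set missing.
#'
#' @param bed_time,rise_time character vectors of 12-h clock strings, e.g.
#'   `"11:00 PM"`.
#' @param plausible plausibility window in hours (default `c(2, 16)`).
#' @return numeric vector of durations in hours, with an attribute
#'   `"recoded"` (logical: toggled by the rule ladder) for logging.
#' @export
compute_time_in_bed <- function(bed_time, rise_time, plausible = c(2, 16)) {
  bed <- parse_clock12(bed_time)
  rise <- parse_clock12(rise_time)
  dur <- function(b, r) ifelse(r > b, r - b, r - b + 24)
  d <- dur(bed, rise)
  ok <- !is.na(d) & d >= plausible[1] & d <= plausible[2]
  recoded <- rep(FALSE, length(d))
  toggle <- function(h) (h + 12) %% 24
  # rule ladder (too-long durations only): toggle AM/PM on bed, then rise
  for (alt in list(function(b, r) dur(toggle(b), r),
                   function(b, r) dur(b, toggle(r)))) {
    idx <- which(!ok & !is.na(bed) & !is.na(rise) & d > plausible[2])
    if (!length(idx)) break
    d2 <- alt(bed[idx], rise[idx])
    fix <- d2 >= plausible[1] & d2 <= plausible[2]
    d[idx[fix]] <- d2[fix]
    recoded[idx[fix]] <- TRUE
    ok[idx[fix]] <- TRUE
  }
  d[!ok] <- NA_real_
  attr(d, "recoded") <- recoded
  d
}

#' Construct adjacent-beep lags with within-day/overnight dummy coding
#'
#' For every answered beep the immediately preceding answered beep of the
#' same person is considered. A row is likelihood-eligible as a within-day
#' transition when the previous answered beep is the directly preceding
#' scheduled beep of the same day and the gap lies within the within-day
#' bounds; it is eligible as an overnight transition when it is the first
#' answered beep of its calendar day and the gap to the previous answered
#' beep lies within the overnight bounds (so a missed first beep lets the
#' second beep carry the overnight lag). All other rows keep a missing lag
#' and are flagged with an exclusion reason.
#'
#' @param ema an `ema_data` object (or any list with a `beeps` tibble
#'   carrying `person_id`, `wave`, `day`, `beep`, `timestamp` and affect
#'   composites `na`/`pa`).
#' @param gap_bounds list with elements `withinday` and `overnight`, each a
#'   length-2 numeric vector of hours (defaults `c(1, 4)` and `c(10, 17)`).
#' @return object of class `lagged_ema`: list with `data` (the lagged
#'   tibble), `mornings`, `persons`, `gap_bounds`, `mode` and `exclusions`
#'   (counts by reason).
#' @export
construct_lags <- function(ema,
                           gap_bounds = list(withinday = c(1, 4),
                                             overnight = c(10, 17))) {
  b <- ema$beeps
  b <- dplyr::arrange(b, .data$person_id, .data$timestamp)
  if (anyDuplicated(b[c("person_id", "timestamp")]))
    stop("duplicate (person, timestamp) entries in beep data")
  if (any(unlist(tapply(b$timestamp, b$person_id, function(t) diff(t) <= 0))))
    stop("timestamps must be strictly increasing within person")

  same_person <- c(FALSE, b$person_id[-1] == b$person_id[-nrow(b)])
  lag_of <- function(x) c(NA, x[-length(x)])
  prev_wave <- lag_of(b$wave); prev_day <- lag_of(b$day)
  prev_beep <- lag_of(b$beep); prev_ts <- lag_of(b$timestamp)
  gap <- ifelse(same_person, b$timestamp - prev_ts, NA_real_)
  same_wave <- same_person & b$wave == prev_wave
  same_day <- same_wave & b$day == prev_day
  first_of_day <- same_person & !same_day   # first answered beep of its day
  adjacent <- same_day & b$beep == prev_beep + 1

  wd <- adjacent & gap >= gap_bounds$withinday[1] & gap <= gap_bounds$withinday[2]
  on <- first_of_day & same_wave &
    gap >= gap_bounds$overnight[1] & gap <= gap_bounds$overnight[2]
  wd[is.na(wd)] <- FALSE; on[is.na(on)] <- FALSE
  eligible <- wd | on

  reason <- rep(NA_character_, nrow(b))
  reason[!same_person] <- "no_previous_beep"
  reason[same_person & !same_wave] <- "wave_boundary"
  reason[same_day & !adjacent] <- "previous_beep_unanswered"
  reason[(adjacent | (first_of_day & same_wave)) & !eligible &
           same_person & same_wave] <- "gap_out_of_bounds"
  reason[eligible] <- NA_character_

  b$gap <- gap
  b$withinday <- as.integer(eligible & wd)
  b$overnight <- as.integer(eligible & on)
  for (col in intersect(c("na", "pa", "urt"), names(b))) {
    b[[paste0(col, "_lag")]] <- ifelse(eligible, lag_of(b[[col]]), NA_real_)
  }
  b$eligible <- eligible
  b$exclude_reason <- reason

  excl <- table(reason[!eligible], useNA = "no")
  structure(list(data = b, mornings = ema$mornings, persons = ema$persons,
                 gap_bounds = gap_bounds, mode = "uncentered",
                 exclusions = as.list(excl)),
            class = "lagged_ema")
}

#' Center lagged affect and decompose time-varying covariates
#'
#' `mode = "uncentered"` leaves the lagged affect untouched (the default for
#' estimating raw inertia); `mode = "person_mean"` adds person-mean-centered
#' lag columns (`na_lag_c`, ...), used by the moderation models. Every
#' covariate named in `covariates` that is present on the lagged rows is
#' decomposed into `<cov>_w` (momentary value minus person mean) and
#' `<cov>_b` (person mean minus grand mean of person means).
#'
#' @param lagged a `lagged_ema` object.
#' @param mode `"uncentered"` or `"person_mean"`.
#' @param covariates character vector of time-varying covariate columns to
#'   decompose.
#' @return the updated `lagged_ema` object.
#' @export
center_and_decompose <- function(lagged,
                                 mode = c("uncentered", "person_mean"),
                                 covariates = character()) {
  mode <- match.arg(mode)
  b <- lagged$data
  if (mode == "person_mean") {
    for (col in grep("_lag$", names(b), value = TRUE)) {
      pm <- stats::ave(b[[col]], b$person_id,
                       FUN = function(x) mean(x, na.rm = TRUE))
      b[[paste0(col, "_c")]] <- b[[col]] - pm
    }
  }
  for (cov in covariates) {
    if (!cov %in% names(b)) stop("covariate not found on lagged rows: ", cov)
    pm <- stats::ave(b[[cov]], b$person_id,
                     FUN = function(x) mean(x, na.rm = TRUE))
    grand <- mean(tapply(b[[cov]], b$person_id, mean, na.rm = TRUE), na.rm = TRUE)
    b[[paste0(cov, "_w")]] <- b[[cov]] - pm
    b[[paste0(cov, "_b")]] <- pm - grand
  }
  lagged$data <- b
  lagged$mode <- mode
  lagged
}

#' Exclusion report
#'
#' Counts of beep rows excluded from the likelihood by reason.
#'
#' @param lagged a `lagged_ema` object.
#' @param file optional path; when given, the counts are written as JSON.
#' @return named list of counts (invisibly when writing).
#' @export
exclusion_report <- function(lagged, file = NULL) {
  rep <- c(lagged$exclusions,
           list(eligible = sum(lagged$data$eligible),
                total = nrow(lagged$data)))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE)
    return(invisible(rep))
  }
  rep
}
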