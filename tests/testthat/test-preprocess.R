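test_that("composite scoring averages, reverse-codes, and rescales", {
  spec <- composite_spec("na", paste0("na_", 1:4))
  df <- tibble::tibble(na_1 = c(40, NA), na_2 = c(40, NA),
                       na_3 = c(40, NA), na_4 = c(40, NA))
  expect_equal(compute_composite(df, spec), c(4, NA_real_))

  sleep <- composite_spec("sleep", paste0("sleep_", 1:4),
                          reverse_coded = c("sleep_3", "sleep_4"))
  df2 <- tibble::tibble(sleep_1 = 80, sleep_2 = 60, sleep_3 = 30, sleep_4 = 10)
  expect_equal(compute_composite(df2, sleep), mean(c(80, 60, 70, 90)) / 10)

  # partial missingness: mean over answered items
  df3 <- tibble::tibble(na_1 = 20, na_2 = NA, na_3 = 40, na_4 = NA)
  expect_equal(compute_composite(df3, spec), 3)

  expect_error(compute_composite(df2, spec), "unknown item column")
})

test_that("time in bed handles clock arithmetic, the toggle ladder, and junk", {
  expect_equal(compute_time_in_bed("11:00 PM", "6:30 AM")[1], 7.5)
  # implausible as stated; toggling AM/PM on the bed time makes it 7 PM
  tib <- compute_time_in_bed("7:00 AM", "6:30 AM")
  expect_equal(tib[1], 11.5)
  expect_true(attr(tib, "recoded")[1])
  expect_true(is.na(compute_time_in_bed("10:00 PM", "10:05 PM")[1]))
  expect_true(is.na(compute_time_in_bed("not a time", "6:30 AM")[1]))
  # vectorized, mixed cases
  res <- compute_time_in_bed(c("11:30 PM", "10:00 AM"), c("7:00 AM", "6:00 AM"))
  expect_equal(res[1], 7.5)
  expect_equal(res[2], 8)  # bed toggled to 10 PM
})

test_that("lag construction encodes adjacency, gaps, and dummies exactly", {
  df <- tibble::tibble(
    person_id = c(1, 1, 1, 1, 1,   2, 2, 2,   3, 3),
    wave      = 1,
    day       = c(1, 1, 1, 2, 2,   1, 1, 2,   1, 1),
    beep      = c(1, 2, 4, 1, 3,   4, 5, 1,   1, 2),
    timestamp = c(9, 11.5, 16, 33, 38.5,
                  18, 21, 33,
                  9, 18),
    na = c(2, 3, 1, 4, 2, 5, 4, 3, 1, 2)
  )
  lag <- toy_lagged(df)
  b <- dplyr::arrange(lag$data, person_id, timestamp)

  # person 1: 9 -> 11.5 same day adjacent, gap 2.5 => within-day
  expect_equal(b$withinday[2], 1L)
  expect_equal(b$gap[2], 2.5)
  expect_equal(b$na_lag[2], 2)
  # 11.5 -> 16: gap 4.5 h and beep 3 was skipped: excluded
  expect_equal(b$withinday[3], 0L)
  expect_true(is.na(b$na_lag[3]))
  expect_equal(b$exclude_reason[3], "previous_beep_unanswered")
  # 16 -> 33 overnight day 1 -> 2, gap 17 (inclusive bound)
  expect_equal(b$overnight[4], 1L)
  expect_equal(b$na_lag[4], 1)
  # 33 -> 38.5 same day but beep 1 -> 3: not adjacent
  expect_true(is.na(b$na_lag[5]))

  # person 2: 18 -> 21 within-day 3 h; 21 -> 33 overnight 12 h
  expect_equal(b$withinday[7], 1L)
  expect_equal(b$overnight[8], 1L)
  expect_equal(b$gap[8], 12)

  # person 3: 9 -> 18 same day gap 9 h: outside both windows
  expect_true(is.na(b$na_lag[10]))

  # dummy partition on eligible rows
  el <- b[b$eligible, ]
  expect_true(all(el$withinday + el$overnight == 1))
  expect_true(all(b$withinday[!b$eligible] == 0 & b$overnight[!b$eligible] == 0))
})

test_that("duplicate timestamps are rejected", {
  df <- tibble::tibble(person_id = c(1, 1), wave = 1, day = 1, beep = c(1, 2),
                       timestamp = c(9, 9), na = c(1, 2))
  expect_error(toy_lagged(df), "duplicate")
})

test_that("widening gap bounds never loses eligible rows", {
  lag1 <- small_lagged(n_persons = 15, seed = 42)
  ema <- structure(list(beeps = lag1$data[names(lag1$data) != "gap"],
                        mornings = lag1$mornings, persons = lag1$persons),
                   class = "ema_data")
  narrow <- construct_lags(ema, list(withinday = c(1.5, 3.5),
                                     overnight = c(11, 16)))
  wide <- construct_lags(ema, list(withinday = c(1, 4.5),
                                   overnight = c(9, 18)))
  expect_gte(sum(wide$data$eligible), sum(narrow$data$eligible))
})

test_that("fully compliant generated data have no skipped-beep exclusions", {
  d <- study_design(n_persons = 10, n_waves = 1, seed = 17, compliance = 1)
  ema <- simulate_ema(d, truth_pa = NULL)
  lag <- construct_lags(ema)
  expect_null(lag$exclusions[["previous_beep_unanswered"]])
  expect_gt(sum(lag$data$eligible) / nrow(lag$data), 0.9)
  rep <- exclusion_report(lag)
  expect_equal(rep$total, nrow(lag$data))
  expect_equal(rep$eligible, sum(lag$data$eligible))
})

test_that("centering and within/between decomposition are exact", {
  df <- tibble::tibble(
    person_id = c(1, 1, 1, 2, 2, 2), wave = 1, day = c(1, 1, 1, 1, 1, 1),
    beep = c(1, 2, 3, 1, 2, 3), timestamp = c(9, 11, 13, 9, 11, 13),
    na = c(5, 5, 5, 1, 2, 3), urt = c(2, 4, 6, 1, 2, 3)
  )
  lag <- toy_lagged(df)
  cen <- center_and_decompose(lag, "person_mean", covariates = "urt")
  b <- cen$data
  # person 1 has a constant lag: centered values are 0
  expect_equal(b$na_lag_c[b$person_id == 1 & b$eligible],
               rep(0, 2))
  # covariate (2,4,6): within = (-2,0,2); between = 4 - grand mean 3 = 1
  expect_equal(b$urt_w[b$person_id == 1], c(-2, 0, 2))
  expect_equal(unique(b$urt_b[b$person_id == 1]), 1)
  expect_equal(unique(b$urt_b[b$person_id == 2]), -1)
  # person means of within components are zero; grand mean of between is zero
  expect_equal(as.numeric(tapply(b$urt_w, b$person_id, mean)), c(0, 0))
  expect_equal(mean(tapply(b$urt_b, b$person_id, unique)), 0)
  # uncentered mode leaves the lag untouched
  unc <- center_and_decompose(lag, "uncentered")
  expect_identical(unc$data$na_lag, lag$data$na_lag)
})
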