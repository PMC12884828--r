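test_that("beep schedules respect wake-time anchoring and gap rules", {
  d <- study_design(n_persons = 5, seed = 1)
  sch <- build_beep_schedule(d, wake_time = 6, n_days = 50, seed = 3)
  expect_true(all(sch[, 1] >= 6 + 55 / 60))
  expect_true(all(sch <= d$latest_beep + 1e-9))
  expect_true(all(diff(t(sch)) > 0 | diff(t(sch)) < -5))  # increasing within day

  # degenerate gap range pins all same-day gaps
  d2 <- study_design(n_persons = 1, beep_gap_range = c(2.6, 2.6))
  sch2 <- build_beep_schedule(d2, wake_time = 6, n_days = 10, seed = 4)
  gaps <- t(apply(sch2, 1, diff))
  expect_equal(as.vector(gaps), rep(2.6, length(gaps)), tolerance = 1e-10)

  expect_error(build_beep_schedule(d, wake_time = 3), "wake_time")
})

test_that("simulated gaps have the designed within-day and overnight structure", {
  d <- study_design(n_persons = 40, n_waves = 1, seed = 8, compliance = 1)
  ema <- simulate_ema(d, truth_pa = NULL)
  lag <- construct_lags(ema)
  wd_gaps <- lag$data$gap[lag$data$withinday == 1]
  on_gaps <- lag$data$gap[lag$data$overnight == 1]
  expect_gt(length(wd_gaps), 1000)
  expect_true(mean(wd_gaps) > 2.4 && mean(wd_gaps) < 2.7)
  expect_true(all(on_gaps >= 10 & on_gaps <= 17))
  expect_true(mean(on_gaps) > 13 && mean(on_gaps) < 15)
})

test_that("generator reduces to the fixed-effect mean when all variation is off", {
  tr <- truth_params(gamma00 = 2, gamma10 = 0.5, gamma20 = 0, gamma30 = 0,
                     sd_u = rep(0, 4), sd_wave = 0, sd_day = 0, sd_resid = 0,
                     item_error_sd = 0)
  d <- study_design(n_persons = 3, n_waves = 1, n_days_per_wave = 4,
                    seed = 5, compliance = 1)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  lag <- construct_lags(ema)
  b <- lag$data
  expect_equal(b$na[b$overnight == 1], rep(2.5, sum(b$overnight == 1)))
  expect_equal(b$na[b$withinday == 1], rep(2, sum(b$withinday == 1)))
})

test_that("missingness thinning is binomial, seed-stable, and identity at 1", {
  d <- study_design(n_persons = 60, n_waves = 1, seed = 2, compliance = 1)
  ema <- simulate_ema(d, truth_pa = NULL)
  expect_identical(apply_missingness(ema, 1), ema)
  thin1 <- apply_missingness(ema, 0.8, seed = 9)
  thin2 <- apply_missingness(ema, 0.8, seed = 9)
  expect_identical(thin1$beeps, thin2$beeps)
  frac <- nrow(thin1$beeps) / nrow(ema$beeps)
  expect_true(abs(frac - 0.8) < 0.02)
  expect_error(apply_missingness(ema, 0), "compliance")
  expect_error(apply_missingness(ema, 1.2), "compliance")
})

test_that("simulate_ema is deterministic given design, truth, and seed", {
  d <- study_design(n_persons = 6, n_waves = 2, n_days_per_wave = 3, seed = 77)
  e1 <- simulate_ema(d)
  e2 <- simulate_ema(d)
  expect_identical(e1$beeps, e2$beeps)
  expect_identical(e1$mornings, e2$mornings)
  expect_identical(e1$persons, e2$persons)
})

test_that("regime presets pin the overnight coefficient", {
  expect_equal(truth_params(gamma20 = 0.5, regime = "stop")$gamma30, 0)
  tr <- truth_params(gamma20 = 0.5, regime = "continue")
  expect_equal(tr$gamma30, 0.5^(13.7 / 2.6))
  tr <- truth_params(gamma20 = 0.5, regime = "pause")
  expect_equal(tr$gamma30, 0.5^(6 / 2.6))
  expect_equal(truth_params(gamma30 = 0.3, regime = "different")$gamma30, 0.3)
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(truth_params(re_correlations = bad), "semi-definite")
})

test_that("long single-person run converges to the AR(1) stationary mean", {
  # gamma30 = gamma20 and gamma10 = 0 makes the process AR(1) throughout,
  # with stationary mean gamma00 / (1 - gamma20)
  tr <- truth_params(gamma00 = 1.5, gamma10 = 0, gamma20 = 0.4, gamma30 = 0.4,
                     sd_u = rep(0, 4), sd_wave = 0, sd_day = 0, sd_resid = 0.5,
                     regime = "different")
  d <- study_design(n_persons = 1, n_waves = 1, n_days_per_wave = 500,
                    seed = 31, compliance = 1)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  expect_equal(mean(ema$beeps$na), 1.5 / 0.6, tolerance = 0.05)
})

test_that("items round-trip to the generating composite when noiseless", {
  tr <- default_truth("na", item_error_sd = 0)
  d <- study_design(n_persons = 8, n_waves = 1, n_days_per_wave = 5, seed = 13)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  b <- ema$beeps
  recon <- rowMeans(b[paste0("na_", 1:4)]) / 10
  in_range <- b$na >= 0 & b$na <= 10   # items are clipped outside this range
  expect_equal(recon[in_range], b$na[in_range], tolerance = 1e-12)
})

test_that("stressor rate matches its long-run probability", {
  d <- study_design(n_persons = 60, n_waves = 1, seed = 3, compliance = 1)
  ema <- simulate_ema(d, truth_pa = NULL)
  expect_lt(abs(mean(ema$beeps$stressor) - 0.16), 0.015)
})

test_that("design and truth configurations round-trip through YAML and JSON", {
  d <- study_design(n_persons = 12, n_waves = 2, compliance = 0.75, seed = 9)
  tr <- default_truth("pa", regime = "pause")
  for (ext in c("yaml", "json")) {
    f <- file.path(withr::local_tempdir(), paste0("config.", ext))
    write_config(d, tr, f)
    back <- read_config(f)
    expect_equal(back$design$n_persons, 12L)
    expect_equal(back$design$compliance, 0.75)
    expect_equal(back$truth$gamma30, tr$gamma30, tolerance = 1e-9)
    expect_equal(back$truth$regime, "pause")
    expect_equal(back$truth$re_correlations, tr$re_correlations,
                 tolerance = 1e-9, ignore_attr = TRUE)
    # the round-tripped config drives an equivalent simulation (YAML
    # serializes doubles at finite precision)
    e1 <- simulate_ema(d, truth_na = NULL, truth_pa = tr)
    e2 <- simulate_ema(back$design, truth_na = NULL, truth_pa = back$truth)
    expect_equal(e2$beeps$pa, e1$beeps$pa, tolerance = 1e-8)
  }
})

test_that("EMA tables round-trip through CSV", {
  d <- study_design(n_persons = 4, n_waves = 1, n_days_per_wave = 3, seed = 55)
  ema <- simulate_ema(d)
  dir <- withr::local_tempdir()
  write_ema(ema, dir)
  back <- read_ema(dir)
  expect_equal(as.data.frame(back$beeps), as.data.frame(ema$beeps),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(back$mornings), nrow(ema$mornings))
  expect_equal(back$persons$neuroticism, ema$persons$neuroticism,
               tolerance = 1e-12)
})
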