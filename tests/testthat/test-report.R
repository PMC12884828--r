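test_that("omega equals one for noiseless items at both levels", {
  set.seed(2)
  cl <- rep(1:50, each = 8)
  latent <- rnorm(50)[cl] + rnorm(length(cl))
  items <- outer(latent, c(1, 1, 1, 1))
  om <- multilevel_omega(items, cl)
  expect_equal(om$omega_within, 1)
  expect_equal(om$omega_between, 1)
})

test_that("omega recovers known two-level factor parameters", {
  lw <- c(1, 0.8, 1.2, 0.9); tw <- 0.5
  lb <- c(1, 1, 1, 1); tb <- 0.2
  dat <- make_two_level_items(400, 12, lw, rep(tw, 4), lb, rep(tb, 4),
                              seed = 7)
  om <- multilevel_omega(dat$items, dat$cluster)
  expect_equal(om$omega_within, omega_true(lw, rep(tw, 4)), tolerance = 0.03)
  expect_equal(om$omega_between, omega_true(lb, rep(tb, 4)), tolerance = 0.07)
  # monotonicity: noisier items give lower omega at that level
  dat2 <- make_two_level_items(400, 12, lw, rep(2, 4), lb, rep(tb, 4),
                               seed = 7)
  om2 <- multilevel_omega(dat2$items, dat2$cluster)
  expect_lt(om2$omega_within, om$omega_within)
})

test_that("a level without variance is flagged rather than estimated", {
  set.seed(3)
  items <- matrix(rnorm(400 * 3), 400, 3) %*% diag(3) + rnorm(400)
  cl <- rep(1:40, each = 10)   # clusters carry no real between variance
  om <- multilevel_omega(items, cl)
  expect_true(om$between_degenerate || om$omega_between < 0.9)
  expect_error(multilevel_omega(items[1:10, ], rep(1, 10)), "clusters")
})

test_that("conditional variance explained dominates marginal on every draw", {
  lag <- small_lagged(n_persons = 15, seed = 201)
  fit <- quiet_fit(lag, model_spec("na"), chains = 2, iter = 600, warmup = 300,
                   seed = 5)
  r2 <- variance_r2(fit)
  expect_true(all(r2$draws$conditional >= r2$draws$marginal))
  expect_true(r2$marginal > 0 && r2$conditional < 1)
  expect_gt(r2$conditional, 0.3)  # strong person heterogeneity in the truth
})

test_that("marginal variance explained vanishes for a null process", {
  tr <- truth_params(gamma00 = 0, gamma10 = 0, gamma20 = 0, gamma30 = 0,
                     sd_u = rep(0, 4), sd_wave = 0, sd_day = 0, sd_resid = 1,
                     regime = "different")
  d <- study_design(n_persons = 25, n_waves = 1, seed = 202, compliance = 1)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  fit <- quiet_fit(construct_lags(ema), model_spec("na"),
                   chains = 2, iter = 600, warmup = 300, seed = 6)
  r2 <- variance_r2(fit)
  expect_lt(r2$marginal, 0.02)
})

test_that("person slope extraction reflects the generating slope correlation", {
  R <- default_re_correlations()
  R[3, 4] <- R[4, 3] <- 0.9
  tr <- default_truth("na", re_correlations = R)
  d <- study_design(n_persons = 120, n_waves = 1, seed = 203)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  fit <- quiet_fit(construct_lags(ema), model_spec("na"),
                   chains = 2, iter = 1000, warmup = 400, seed = 7)
  sl <- person_slopes(list(na = fit))
  expect_equal(nrow(sl$slopes), 120)
  # shrinkage attenuates, but a strong generating correlation survives
  expect_gt(sl$correlations["na_withinday", "na_overnight"], 0.45)
  # slopes center near the fixed effects
  expect_equal(mean(sl$slopes$na_withinday), 0.28, tolerance = 0.06)
})

test_that("degenerate person effects are flagged in the slope table", {
  tr <- truth_params(sd_u = c(0.6, 0, 0, 0), regime = "different",
                     sd_resid = 1)
  d <- study_design(n_persons = 30, n_waves = 1, seed = 204)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  fit <- quiet_fit(construct_lags(ema), model_spec("na"),
                   chains = 2, iter = 400, warmup = 200, seed = 8)
  # person slopes all shrink onto the fixed effect: near-constant vectors
  sl_sd <- apply(as.matrix(person_slopes(list(na = fit))$slopes[-1]), 2, sd)
  expect_true(all(sl_sd < 0.1))
})

test_that("report assembly mirrors the fitted and derived quantities", {
  lag <- small_lagged(n_persons = 15, seed = 205)
  fit <- quiet_fit(lag, model_spec("na"), chains = 2, iter = 600, warmup = 300,
                   seed = 9)
  ds <- overnight_contrasts(fit)
  r2 <- variance_r2(fit)
  rep <- suppressMessages(assemble_tables(list(na = fit), list(na = ds),
                                          r2 = list(na = r2)))
  expect_s3_class(rep$table2, "tbl_df")
  labels <- rep$table2$parameter
  expect_true(all(c("Intercept", "overnight", "within-day inertia",
                    "overnight inertia", "SD intercept id", "SD overnight",
                    "SD within-day inertia", "SD overnight inertia",
                    "SD intercept id wave day") %in% labels))
  expect_equal(sum(grepl("^overnight - withinday", labels)), 2)
  # medians pass through untouched
  expect_equal(rep$table2$estimate[labels == "overnight - withinday^5.3"],
               ds$table$median[ds$table$quantity == "contrast_continue"])
  expect_equal(unname(rep$classification["na"]), ds$classification)

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "table2.csv")))
  expect_true(file.exists(file.path(dir, "report.md")))

  # moderation rows flow into the interaction table
  mt <- tibble::tibble(term = "urt_w:wd_lag", component = "within",
                       target = "withinday_inertia", median = 0.03,
                       lower = 0.01, upper = 0.05, significant = TRUE)
  rep2 <- assemble_tables(list(na = fit), list(na = ds),
                          moderation = list(urt = mt))
  expect_equal(nrow(rep2$table3), 1)
  expect_true(rep2$table3$significant)
})
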