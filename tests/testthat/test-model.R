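test_that("log_posterior matches a naive row-by-row oracle", {
  lag <- small_lagged(n_persons = 8, seed = 7)
  spec <- model_spec("na")
  md <- emainertia:::build_model_data(lag, spec)
  for (s in 1:20) {
    p <- random_params(md, spec, seed = 1000 + s)
    a <- log_posterior(p, lag, spec)
    b <- naive_log_posterior(p, lag, spec)
    expect_lt(abs(a - b) / abs(b), 1e-10)
  }
  # random-effect blocks can be switched off independently
  spec2 <- model_spec("na", wave_re = FALSE, day_re = FALSE)
  p <- random_params(md, spec2, seed = 2)
  expect_lt(abs(log_posterior(p, lag, spec2) -
                  naive_log_posterior(p, lag, spec2)) /
              abs(naive_log_posterior(p, lag, spec2)), 1e-10)
  expect_error(log_posterior(utils::modifyList(p, list(gamma = c(NA, 0, 0, 0))),
                             lag, spec2), "non-finite")
})

test_that("log_posterior is invariant to row permutations", {
  lag <- small_lagged(n_persons = 6, seed = 19)
  spec <- model_spec("na")
  md <- emainertia:::build_model_data(lag, spec)
  p <- random_params(md, spec, seed = 5)
  v1 <- log_posterior(p, lag, spec)
  perm <- withr::with_seed(1, sample(nrow(lag$data)))
  lag2 <- lag
  lag2$data <- lag$data[perm, ]   # group labels are order-invariant factors
  expect_equal(log_posterior(p, lag2, spec), v1, tolerance = 1e-12)
})

test_that("zero-residual single-row likelihood equals the normal constant", {
  df <- tibble::tibble(person_id = 1, wave = 1, day = c(1, 1), beep = c(1, 2),
                       timestamp = c(9, 11), na = c(2, 2))
  lag <- toy_lagged(df)
  spec <- model_spec("na", person_re = FALSE, wave_re = FALSE, day_re = FALSE,
                     priors = prior_spec(gamma_sd = Inf))
  # mean = gamma00 + gamma20 * lag = 1 + 0.5 * 2 = 2 = observed
  p <- list(gamma = c(1, 0, 0.5, 0), sig2_eps = 1)
  lp <- log_posterior(p, lag, spec)
  sigma_prior <- log(2) + lgamma(2) - lgamma(1.5) - 0.5 * log(3 * pi * 2.5^2) -
    2 * log1p(1 / (3 * 2.5^2)) - log(2)
  expect_equal(lp - sigma_prior, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("posterior equals the prior when no data rows are eligible", {
  df <- tibble::tibble(person_id = 1:4, wave = 1, day = 1, beep = 1,
                       timestamp = 9, na = c(1, 2, 3, 4))
  lag <- toy_lagged(df)   # four isolated beeps: nothing is eligible
  expect_equal(sum(lag$data$eligible), 0)
  fit <- quiet_fit(lag, model_spec("na", person_re = FALSE, wave_re = FALSE,
                                   day_re = FALSE),
                   chains = 2, iter = 3000, warmup = 500, seed = 3)
  g <- posterior_draws(fit, "b_wd_lag")
  ks_g <- stats::ks.test(g, "pnorm", 0, 10)
  expect_gt(ks_g$p.value, 0.001)
  # sigma draws follow the half-t(3, 2.5) prior (thinned: the variance
  # chain is Markov even without data)
  s <- posterior_draws(fit, "sigma")[seq(1, 5000, by = 10)]
  ht_cdf <- function(x) 2 * (stats::pt(x / 2.5, df = 3) - 0.5)
  expect_gt(stats::ks.test(s, ht_cdf)$p.value, 0.001)
})

test_that("with random effects off and flat priors the fit reproduces OLS", {
  lag <- small_lagged(n_persons = 20, seed = 11)
  spec <- model_spec("na", person_re = FALSE, wave_re = FALSE, day_re = FALSE,
                     priors = prior_spec(gamma_sd = Inf))
  fit <- quiet_fit(lag, spec, chains = 2, iter = 3000, warmup = 500, seed = 4)
  d <- lag$data[lag$data$eligible, ]
  ols <- stats::lm(na ~ overnight + I(na_lag * withinday) +
                     I(na_lag * overnight), data = d)
  post_means <- sapply(paste0("b_", c("(Intercept)", "overnight", "wd_lag",
                                      "on_lag")),
                       function(p) mean(posterior_draws(fit, p)))
  expect_equal(unname(post_means), unname(coef(ols)), tolerance = 0.01)
})

test_that("fits are reproducible and invariant to chain relabeling", {
  lag <- small_lagged(n_persons = 10, seed = 23)
  f1 <- quiet_fit(lag, model_spec("na"), chains = 2, iter = 400, warmup = 200,
                  seed = 12)
  f2 <- quiet_fit(lag, model_spec("na"), chains = 2, iter = 400, warmup = 200,
                  seed = 12)
  expect_identical(f1$draws, f2$draws)
  # relabel chains: pooled medians and HDIs unchanged
  swapped <- f1$draws[, c(2, 1), , drop = FALSE]
  for (p in c("b_wd_lag", "sigma")) {
    expect_equal(stats::median(swapped[, , p]), stats::median(f1$draws[, , p]))
    expect_equal(hdi(as.vector(swapped[, , p])),
                 hdi(as.vector(f1$draws[, , p])))
  }
})

test_that("degenerate data are rejected with a diagnostic", {
  df <- tibble::tibble(person_id = 1, wave = 1, day = 1, beep = 1:5,
                       timestamp = c(9, 11, 13, 15, 17), na = 3)
  expect_error(quiet_fit(toy_lagged(df), model_spec("na")), "zero variance")
})

test_that("split R-hat and ESS behave like the textbook definitions", {
  set.seed(6)
  arr <- array(stats::rnorm(1000 * 4 * 2), c(1000, 4, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  rep <- diagnose(arr)
  expect_true(all(abs(rep$table$rhat - 1) < 0.02))
  expect_true(rep$converged)
  # agreement with an independent implementation
  for (k in 1:2)
    expect_equal(rep$table$rhat[k], reference_split_rhat(arr[, , k]),
                 tolerance = 1e-8)
  # non-mixing construction
  bad <- arr
  bad[, 1, 1] <- bad[, 1, 1] + 10
  rep2 <- diagnose(bad)
  expect_gt(rep2$table$rhat[1], 1.5)
  expect_false(rep2$converged)
  expect_error(diagnose(arr[, 1, , drop = FALSE]), "2 chains")
})

test_that("the sampler recovers strong generating effects at small n", {
  tr <- truth_params(gamma00 = 2, gamma10 = 0.3, gamma20 = 0.5, gamma30 = 0.1,
                     sd_u = c(0.8, 0.1, 0.1, 0.1), sd_wave = 0.2, sd_day = 0.2,
                     sd_resid = 0.8, regime = "different")
  d <- study_design(n_persons = 40, n_waves = 1, seed = 3, compliance = 0.9)
  ema <- simulate_ema(d, truth_na = tr, truth_pa = NULL)
  fit <- quiet_fit(construct_lags(ema), model_spec("na"),
                   chains = 2, iter = 1000, warmup = 400, seed = 2)
  s <- summary(fit)
  est <- function(p) s$median[s$parameter == p]
  expect_equal(est("b_wd_lag"), 0.5, tolerance = 0.08)
  expect_equal(est("b_on_lag"), 0.1, tolerance = 0.1)
  expect_equal(est("sigma"), 0.8, tolerance = 0.08)
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
})
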