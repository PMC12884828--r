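# Shared fixtures and independent oracles for the test suite.

quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_inertia(...)))

# Small simulated dataset reused by several tests
small_lagged <- function(n_persons = 25, seed = 101, compliance = 0.8,
                         truth = default_truth("na")) {
  d <- study_design(n_persons = n_persons, n_waves = 1, seed = seed,
                    compliance = compliance)
  ema <- simulate_ema(d, truth_na = truth, truth_pa = NULL)
  construct_lags(ema)
}

# Hand-built minimal lagged_ema object (bypasses the generator entirely)
toy_lagged <- function(df, mornings = NULL, persons = NULL) {
  ema <- structure(list(beeps = tibble::as_tibble(df), mornings = mornings,
                        persons = persons), class = "ema_data")
  construct_lags(ema)
}

# Independent naive implementation of the log joint density: explicit loops,
# no shared code with the package's vectorized version.
naive_log_posterior <- function(params, lagged, spec) {
  md <- emainertia:::build_model_data(lagged, spec)
  p <- params
  lp <- 0
  for (r in seq_along(md$y)) {
    mu <- 0
    for (j in seq_len(ncol(md$X))) mu <- mu + md$X[r, j] * p$gamma[j]
    if (spec$person_re)
      for (j in 1:4) mu <- mu + md$Z[r, j] * p$u[md$pid[r] + 1, j]
    if (spec$wave_re) mu <- mu + p$xi[md$wid[r] + 1]
    if (spec$day_re) mu <- mu + p$zeta[md$did[r] + 1]
    lp <- lp - 0.5 * log(2 * pi * p$sig2_eps) -
      (md$y[r] - mu)^2 / (2 * p$sig2_eps)
  }
  pr <- spec$priors
  lhalf_t_v <- function(s2, df, A) {
    s <- sqrt(s2)
    log(2) + lgamma((df + 1) / 2) - lgamma(df / 2) -
      0.5 * log(df * pi * A^2) -
      (df + 1) / 2 * log(1 + s2 / (df * A^2)) - log(2 * s)
  }
  if (spec$person_re) {
    S <- p$Sigma
    Sinv <- solve(S)
    for (i in seq_len(nrow(p$u))) {
      ui <- p$u[i, ]
      lp <- lp - 0.5 * (4 * log(2 * pi) +
                          determinant(S)$modulus +
                          drop(t(ui) %*% Sinv %*% ui))
    }
    q <- 4; nu <- pr$re_df; A <- pr$re_scale; nuq <- nu + q - 1
    lmvg <- sum(lgamma((nuq + 1 - 1:q) / 2)) + q * (q - 1) / 4 * log(pi)
    lp <- lp + q * (lgamma((nu + q) / 2) - lgamma(0.5) - log(A)) +
      (q * nuq / 2) * log(nu) - lmvg -
      ((nu + 2 * q) / 2) * determinant(S)$modulus -
      ((nu + q) / 2) * sum(log(nu * diag(Sinv) + 1 / A^2))
  }
  if (spec$wave_re) {
    for (x in p$xi) lp <- lp - 0.5 * log(2 * pi * p$sig2_xi) -
        x^2 / (2 * p$sig2_xi)
    lp <- lp + lhalf_t_v(p$sig2_xi, pr$sd_df, pr$sd_scale)
  }
  if (spec$day_re) {
    for (x in p$zeta) lp <- lp - 0.5 * log(2 * pi * p$sig2_zeta) -
        x^2 / (2 * p$sig2_zeta)
    lp <- lp + lhalf_t_v(p$sig2_zeta, pr$sd_df, pr$sd_scale)
  }
  lp <- lp + lhalf_t_v(p$sig2_eps, pr$sd_df, pr$sd_scale)
  if (is.finite(pr$gamma_sd))
    for (g in p$gamma) lp <- lp - 0.5 * log(2 * pi * pr$gamma_sd^2) -
        g^2 / (2 * pr$gamma_sd^2)
  as.numeric(lp)
}

# Random parameter point consistent with a model-data layout
random_params <- function(md, spec, seed) {
  set.seed(seed)
  S <- stats::rWishart(1, 8, diag(4) / 8)[, , 1]
  list(gamma = stats::rnorm(ncol(md$X), 0, 1),
       u = matrix(stats::rnorm(md$n_person * 4, 0, 0.5), md$n_person, 4),
       xi = stats::rnorm(md$n_wavegrp, 0, 0.5),
       zeta = stats::rnorm(md$n_daygrp, 0, 0.5),
       Sigma = S,
       sig2_xi = stats::runif(1, 0.05, 2),
       sig2_zeta = stats::runif(1, 0.05, 2),
       sig2_eps = stats::runif(1, 0.1, 2))
}

# Two-level one-factor data with known loadings and uniquenesses
make_two_level_items <- function(n_cluster, n_obs, lambda_w, theta_w,
                                 lambda_b, theta_b, seed = 1) {
  set.seed(seed)
  p <- length(lambda_w)
  eta_b <- rnorm(n_cluster)
  items_b <- outer(eta_b, lambda_b) +
    matrix(rnorm(n_cluster * p, 0, sqrt(theta_b)), n_cluster, p, byrow = FALSE)
  cl <- rep(seq_len(n_cluster), each = n_obs)
  eta_w <- rnorm(n_cluster * n_obs)
  items_w <- outer(eta_w, lambda_w) +
    matrix(rnorm(n_cluster * n_obs * p, 0, sqrt(theta_w)),
           n_cluster * n_obs, p)
  list(items = items_b[cl, ] + items_w, cluster = cl)
}

omega_true <- function(lambda, theta)
  sum(lambda)^2 / (sum(lambda)^2 + sum(theta))

# Textbook split R-hat (independent of the package's implementation)
reference_split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  chains <- cbind(mat[1:half, , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(chains); nn <- nrow(chains)
  mean_j <- colMeans(chains)
  var_j <- apply(chains, 2, stats::var)
  B <- nn / (m - 1) * sum((mean_j - mean(mean_j))^2)
  W <- mean(var_j)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
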