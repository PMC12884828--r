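#' Prior settings for the multilevel AR model
#'
#' Broad zero-centered normal priors on fixed effects and weakly
#' informative heavy-tailed priors on all standard deviations, implemented
#' through the Huang-Wand (2013) conjugate scale-mixture family: every
#' scalar SD (wave, day, residual) is marginally half-Student-t with
#' `sd_df` degrees of freedom and scale `sd_scale`; the person
#' random-effect covariance gets a mixture inverse-Wishart whose SDs are
#' marginally half-t(`re_df`, `re_scale`) and whose correlations are
#' marginally uniform on (-1, 1) when `re_df = 2`. These match the default
#' prior family of mainstream Bayesian multilevel software while keeping
#' every full conditional conjugate.
#'
#' @param gamma_sd prior SD of fixed effects; `Inf` gives an improper flat
#'   prior.
#' @param sd_df,sd_scale half-t degrees of freedom and scale for the
#'   scalar SDs (defaults 3 and 2.5).
#' @param re_df,re_scale half-t degrees of freedom and scale for the
#'   person random-effect SDs (defaults 2 and 2.5).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(gamma_sd = 10, sd_df = 3, sd_scale = 2.5,
                       re_df = 2, re_scale = 2.5) {
  stopifnot(gamma_sd > 0, sd_df > 0, sd_scale > 0, re_df > 0, re_scale > 0)
  structure(list(gamma_sd = gamma_sd, sd_df = sd_df, sd_scale = sd_scale,
                 re_df = re_df, re_scale = re_scale), class = "prior_spec")
}

#' Model specification for the dummy-separated inertia model
#'
#' Describes the fixed effects (intercept, overnight level shift,
#' within-day lag term, overnight lag term, plus optional moderation
#' terms), the random structure (correlated person effects on all four base
#' terms; independent person-wave and person-wave-day intercept
#' deviations), and the centering mode of the lagged affect.
#'
#' @param outcome `"na"` or `"pa"` (any composite column with a matching
#'   `<outcome>_lag` works).
#' @param centering `"uncentered"` (raw lag; for estimating inertia levels)
#'   or `"person_mean"` (centered lag; used by moderation models).
#' @param person_re,wave_re,day_re switches for the three random terms.
#' @param priors a [prior_spec()].
#' @param moderation optional [moderation_spec()].
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome = "na",
                       centering = c("uncentered", "person_mean"),
                       person_re = TRUE, wave_re = TRUE, day_re = TRUE,
                       priors = prior_spec(), moderation = NULL) {
  centering <- match.arg(centering)
  structure(list(outcome = outcome, centering = centering,
                 person_re = person_re, wave_re = wave_re, day_re = day_re,
                 priors = priors, moderation = moderation),
            class = "model_spec")
}

# Build y, X, Z and grouping indices from a lagged dataset.
build_model_data <- function(lagged, spec) {
  b <- lagged$data
  lag_col <- paste0(spec$outcome, "_lag")
  if (!lag_col %in% names(b)) stop("no lag column for outcome ", spec$outcome)
  if (spec$centering == "person_mean") {
    lc <- paste0(lag_col, "_c")
    if (!lc %in% names(b))
      lagged <- center_and_decompose(lagged, "person_mean")
    b <- lagged$data
    lag_use <- b[[paste0(lag_col, "_c")]]
  } else {
    lag_use <- b[[lag_col]]
  }
  keep <- b$eligible & !is.na(b[[spec$outcome]]) & !is.na(lag_use)
  if (!is.null(spec$moderation)) {
    cov <- spec$moderation$covariate
    need <- if (spec$moderation$kind == "time_varying")
      paste0(cov, c("_aligned_w", "_aligned_b")) else paste0(cov, "_c")
    for (cn in intersect(need, names(b))) keep <- keep & !is.na(b[[cn]])
  }
  d <- b[keep, ]
  lag_use <- lag_use[keep]
  X <- cbind(`(Intercept)` = rep(1, nrow(d)), overnight = d$overnight,
             wd_lag = lag_use * d$withinday,
             on_lag = lag_use * d$overnight)
  if (nrow(d) == 0)
    X <- matrix(numeric(0), 0, 4,
                dimnames = list(NULL, c("(Intercept)", "overnight",
                                        "wd_lag", "on_lag")))
  Z <- X[, 1:4, drop = FALSE]
  if (!is.null(spec$moderation)) {
    X <- cbind(X, moderation_columns(d, spec$moderation,
                                     wd_lag = Z[, "wd_lag"],
                                     on_lag = Z[, "on_lag"]))
  }
  pid_f <- factor(d$person_id)
  wid_f <- factor(paste(d$person_id, d$wave))
  did_f <- factor(paste(d$person_id, d$wave, d$day))
  list(y = d[[spec$outcome]], X = X, Z = Z,
       pid = as.integer(pid_f) - 1L, wid = as.integer(wid_f) - 1L,
       did = as.integer(did_f) - 1L,
       n_person = nlevels(pid_f), n_wavegrp = nlevels(wid_f),
       n_daygrp = nlevels(did_f),
       person_ids = as.numeric(levels(pid_f)), rows = which(keep),
       data = d)
}

#' Log joint posterior density of the multilevel AR model
#'
#' Evaluates the log joint density (likelihood over likelihood-eligible
#' rows plus all priors and random-effect densities) at a given parameter
#' point. This is the single source of truth the Gibbs sampler targets; it
#' is exposed so alternative backends and brute-force oracles can be
#' checked against it.
#'
#' @param params list with elements `gamma` (fixed effects), `u`
#'   (n_person x 4 matrix), `xi`, `zeta` (vectors of group deviations),
#'   `Sigma` (4x4), `sig2_xi`, `sig2_zeta`, `sig2_eps` (variances).
#'   Random-effect elements may be omitted when the corresponding term is
#'   switched off in `spec`.
#' @param lagged a `lagged_ema` object.
#' @param spec a [model_spec()].
#' @return scalar log density.
#' @export
log_posterior <- function(params, lagged, spec = model_spec()) {
  md <- build_model_data(lagged, spec)
  p <- params
  if (any(!is.finite(p$gamma)) || !is.finite(p$sig2_eps))
    stop("non-finite parameter values")
  mu <- as.vector(md$X %*% p$gamma)
  lp <- 0
  pr <- spec$priors
  if (spec$person_re) {
    mu <- mu + rowSums(md$Z * p$u[md$pid + 1L, , drop = FALSE])
    lp <- lp + sum(dmvnorm_log(p$u, p$Sigma)) +
      lhw_cov_log(p$Sigma, pr$re_df, pr$re_scale)
  }
  if (spec$wave_re) {
    mu <- mu + p$xi[md$wid + 1L]
    lp <- lp + sum(stats::dnorm(p$xi, 0, sqrt(p$sig2_xi), log = TRUE)) +
      lhalf_t_var_log(p$sig2_xi, pr$sd_df, pr$sd_scale)
  }
  if (spec$day_re) {
    mu <- mu + p$zeta[md$did + 1L]
    lp <- lp + sum(stats::dnorm(p$zeta, 0, sqrt(p$sig2_zeta), log = TRUE)) +
      lhalf_t_var_log(p$sig2_zeta, pr$sd_df, pr$sd_scale)
  }
  lp <- lp + sum(stats::dnorm(md$y, mu, sqrt(p$sig2_eps), log = TRUE))
  lp <- lp + lhalf_t_var_log(p$sig2_eps, pr$sd_df, pr$sd_scale)
  if (is.finite(spec$priors$gamma_sd))
    lp <- lp + sum(stats::dnorm(p$gamma, 0, spec$priors$gamma_sd, log = TRUE))
  lp
}

dmvnorm_log <- function(U, S) {
  Sinv <- solve(S)
  ld <- determinant(S, logarithm = TRUE)$modulus
  q <- ncol(S)
  -0.5 * (q * log(2 * pi) + as.numeric(ld) + rowSums((U %*% Sinv) * U))
}

# log density of a variance whose SD is half-t(df, A)
lhalf_t_var_log <- function(s2, df, A) {
  s <- sqrt(s2)
  lht <- log(2) + lgamma((df + 1) / 2) - lgamma(df / 2) -
    0.5 * log(df * pi * A^2) - (df + 1) / 2 * log1p(s2 / (df * A^2))
  lht - log(2 * s)  # Jacobian d sigma / d sigma^2
}

# log marginal density of the Huang-Wand covariance prior: the latent
# inverse-gamma scales are integrated out analytically
lhw_cov_log <- function(S, nu, A) {
  q <- ncol(S)
  nuq <- nu + q - 1
  Sinv <- solve(S)
  lmvgamma <- sum(lgamma((nuq + 1 - seq_len(q)) / 2)) +
    q * (q - 1) / 4 * log(pi)
  const <- q * (lgamma((nu + q) / 2) - lgamma(0.5) - log(A)) +
    (q * nuq / 2) * log(nu) - lmvgamma
  as.numeric(
    const - ((nu + 2 * q) / 2) * determinant(S, logarithm = TRUE)$modulus -
      ((nu + q) / 2) * sum(log(nu * diag(Sinv) + 1 / A^2))
  )
}

#' Fit the multilevel inertia model by blocked Gibbs sampling
#'
#' Samples the posterior defined by [log_posterior()] with a conjugate
#' blocked Gibbs sampler (all full conditionals of the linear-Gaussian
#' model are closed-form). Chains run sequentially from a single seed, so
#' results are fully reproducible.
#'
#' @param lagged a `lagged_ema` object.
#' @param spec a [model_spec()].
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain (default 1500).
#' @param warmup warm-up iterations discarded per chain (default 500).
#' @param seed integer seed.
#' @param rhat_threshold convergence threshold for the report
#'   (default 1.05).
#' @return object of class `inertia_fit`: list with `draws`
#'   (array iterations x chains x parameters), `u` (per-chain arrays of
#'   person-effect draws), `par_names`, `spec`, `model_data`,
#'   `convergence`, and `mcmc` settings.
#' @export
fit_inertia <- function(lagged, spec = model_spec(), chains = 4, iter = 1500,
                        warmup = 500, seed = 1, rhat_threshold = 1.05) {
  md <- build_model_data(lagged, spec)
  if (spec$person_re && spec$wave_re && md$n_wavegrp == md$n_person &&
      md$n_person > 0) {
    # one wave per person: the wave-level intercept duplicates the person
    # intercept and the split of their variance is not identified
    message("single wave per person: dropping the wave-level intercept")
    spec$wave_re <- FALSE
  }
  if (length(md$y) > 0) {
    if (stats::var(md$y) == 0)
      stop("degenerate data: outcome has zero variance on eligible rows")
    if (spec$centering == "uncentered" &&
        (sum(md$X[, "overnight"]) == 0 || sum(md$X[, "overnight"] == 0) == 0))
      stop("need at least one within-day and one overnight eligible row")
  }
  pr <- spec$priors
  gprec <- if (is.finite(pr$gamma_sd)) 1 / pr$gamma_sd^2 else 0
  n_keep <- iter - warmup
  P <- ncol(md$X)
  par_names <- c(paste0("b_", colnames(md$X)))
  if (spec$person_re) {
    base <- c("Intercept", "overnight", "wd_lag", "on_lag")
    par_names <- c(par_names, paste0("sd_person__", base),
                   paste0("cor_person__",
                          c("Intercept.overnight", "Intercept.wd_lag",
                            "Intercept.on_lag", "overnight.wd_lag",
                            "overnight.on_lag", "wd_lag.on_lag")))
  }
  if (spec$wave_re) par_names <- c(par_names, "sd_wave__Intercept")
  if (spec$day_re) par_names <- c(par_names, "sd_day__Intercept")
  par_names <- c(par_names, "sigma")

  draws <- array(NA_real_, c(n_keep, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  u_draws <- vector("list", chains)
  set.seed(seed)
  for (ch in seq_len(chains)) {
    res <- gibbs_lmm(md$y, md$X, md$Z, md$pid, md$wid, md$did,
                     md$n_person, md$n_wavegrp, md$n_daygrp,
                     spec$person_re, spec$wave_re, spec$day_re,
                     gprec, pr$sd_df, pr$sd_scale, pr$re_df, pr$re_scale,
                     as.integer(iter), as.integer(warmup))
    cols <- res$gamma
    if (spec$person_re) {
      st <- res$sigma_tri  # upper triangle incl. diagonal, row-major by row i<=j
      # order: (1,1)(1,2)(1,3)(1,4)(2,2)(2,3)(2,4)(3,3)(3,4)(4,4)
      v_idx <- c(1, 5, 8, 10)
      sds <- sqrt(st[, v_idx, drop = FALSE])
      cor_idx <- rbind(c(2, 1, 2), c(3, 1, 3), c(4, 1, 4),
                       c(6, 2, 3), c(7, 2, 4), c(9, 3, 4))
      cors <- sapply(seq_len(nrow(cor_idx)), function(k)
        st[, cor_idx[k, 1]] / (sds[, cor_idx[k, 2]] * sds[, cor_idx[k, 3]]))
      cols <- cbind(cols, sds, cors)
      u_draws[[ch]] <- res$u
    }
    if (spec$wave_re) cols <- cbind(cols, sqrt(res$sig2_wave))
    if (spec$day_re) cols <- cbind(cols, sqrt(res$sig2_day))
    cols <- cbind(cols, sqrt(res$sig2_eps))
    draws[, ch, ] <- cols
  }
  conv <- diagnose_array(draws, par_names, threshold = rhat_threshold)
  if (!conv$converged)
    warning("some parameters have R-hat >= ", rhat_threshold,
            " (max ", round(max(conv$table$rhat, na.rm = TRUE), 3), ")")
  structure(list(draws = draws, u = u_draws, par_names = par_names,
                 spec = spec, model_data = md, convergence = conv,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup,
                             seed = seed)),
            class = "inertia_fit")
}

#' Extract a parameter's pooled posterior draws
#' @param fit an `inertia_fit`.
#' @param par parameter name (see `fit$par_names`).
#' @return numeric vector of pooled post-warmup draws.
#' @export
posterior_draws <- function(fit, par) {
  if (!par %in% fit$par_names) stop("unknown parameter: ", par)
  as.vector(fit$draws[, , par])
}

split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(mat) {
  # crude bulk ESS: pooled chains, Geyer initial positive sequence
  n <- nrow(mat); m <- ncol(mat)
  cm <- colMeans(mat); W <- mean(apply(mat, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(n * m)
  lag_max <- min(n - 1, 200)
  acfs <- sapply(seq_len(m), function(j)
    stats::acf(mat[, j], lag.max = lag_max, plot = FALSE,
               demean = TRUE)$acf[, 1, 1])
  rho <- rowMeans(acfs)[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, n * m / (1 + 2 * s))
}

diagnose_array <- function(draws, par_names, threshold = 1.05) {
  tab <- tibble::tibble(
    parameter = par_names,
    rhat = vapply(seq_along(par_names),
                  function(k) split_rhat(draws[, , k, drop = TRUE]), numeric(1)),
    ess = vapply(seq_along(par_names),
                 function(k) ess_basic(draws[, , k, drop = TRUE]), numeric(1))
  )
  list(table = tab, threshold = threshold,
       converged = all(tab$rhat < threshold, na.rm = TRUE))
}

#' Convergence diagnostics (split R-hat, effective sample size)
#'
#' @param fit an `inertia_fit` (or a draws array iterations x chains x
#'   parameters).
#' @param threshold R-hat convergence threshold (default 1.05).
#' @return list with per-parameter `table`, the `threshold`, and
#'   `converged` (all split R-hat below threshold).
#' @export
diagnose <- function(fit, threshold = 1.05) {
  draws <- if (inherits(fit, "inertia_fit")) fit$draws else fit
  if (dim(draws)[2] < 2) stop("diagnostics require at least 2 chains")
  pn <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  diagnose_array(draws, pn, threshold)
}

#' Posterior summary of an inertia model fit
#'
#' @param object an `inertia_fit`.
#' @param prob HDI probability mass (default 0.95).
#' @param ... unused.
#' @return tibble with posterior median and HDI bounds per parameter.
#' @export
summary.inertia_fit <- function(object, prob = 0.95, ...) {
  rows <- lapply(object$par_names, function(p) {
    x <- posterior_draws(object, p)
    h <- hdi(x, prob)
    tibble::tibble(parameter = p, median = stats::median(x),
                   lower = h[["lower"]], upper = h[["upper"]])
  })
  dplyr::bind_rows(rows)
}
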