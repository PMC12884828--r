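#' Multilevel composite reliability (McDonald's omega)
#'
#' Decomposes the item covariance matrix into pooled within-cluster and
#' between-cluster components (method-of-moments, Searle's expected mean
#' squares), fits a one-factor model to each level by maximum likelihood,
#' and computes omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta) per
#' level. With zero item uniqueness at a level (rank-one covariance) omega
#' is exactly 1.
#'
#' @param items data frame or matrix of item scores (>= 2 columns).
#' @param cluster cluster id vector (e.g. person id), same length as rows.
#' @return object of class `omega_estimate`: list with `omega_within`,
#'   `omega_between`, and per-level loadings/uniquenesses; a level whose
#'   covariance is not positive (no between-cluster variance) yields `NA`
#'   with a flag.
#' @export
multilevel_omega <- function(items, cluster) {
  m <- as.matrix(items)
  stopifnot(ncol(m) >= 2, nrow(m) == length(cluster))
  cl <- factor(cluster)
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]; cl <- droplevels(cl[keep])
  n_i <- as.vector(table(cl))
  if (all(n_i < 2)) stop("need clusters with at least 2 observations")
  N <- nrow(m); k <- nlevels(cl)
  means <- apply(m, 2, function(x) tapply(x, cl, mean))
  centered <- m - means[cl, , drop = FALSE]
  S_w <- crossprod(centered) / (N - k)
  gm <- colMeans(m)
  dev <- sweep(means, 2, gm)
  MS_b <- crossprod(dev * sqrt(n_i)) / (k - 1)
  n_tilde <- (N - sum(n_i^2) / N) / (k - 1)
  S_b <- (MS_b - S_w) / n_tilde

  fit_level <- function(S) {
    if (any(diag(S) <= 0)) return(NULL)
    ev <- eigen(S, symmetric = TRUE)
    if (ev$values[1] <= 0) return(NULL)
    # rank-one covariance: noiseless items, omega = 1 exactly
    if (ev$values[2] < 1e-10 * ev$values[1]) {
      lam <- sqrt(ev$values[1]) * ev$vectors[, 1]
      lam <- lam * sign(sum(lam))
      return(list(loadings = lam, uniquenesses = rep(0, ncol(S)), omega = 1))
    }
    p <- ncol(S)
    lam0 <- sqrt(max(ev$values[1], 1e-8)) * ev$vectors[, 1]
    lam0 <- lam0 * sign(sum(lam0))
    th0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
    floor_th <- 1e-8 * mean(diag(S))
    obj <- function(par) {
      lam <- par[1:p]; th <- exp(par[(p + 1):(2 * p)]) + floor_th
      Sig <- tcrossprod(lam) + diag(th, p)
      ld <- determinant(Sig, logarithm = TRUE)
      if (ld$sign <= 0) return(1e10)
      tr <- tryCatch(sum(diag(solve(Sig, S))), error = function(e) NA_real_)
      if (!is.finite(tr)) return(1e10)
      as.numeric(ld$modulus) + tr
    }
    op <- stats::optim(c(lam0, log(th0)), obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    lam <- op$par[1:p]; th <- exp(op$par[(p + 1):(2 * p)]) + floor_th
    lam <- lam * sign(sum(lam))
    list(loadings = lam, uniquenesses = th,
         omega = sum(lam)^2 / (sum(lam)^2 + sum(th)))
  }

  fw <- fit_level(S_w)
  fb <- fit_level(S_b)
  structure(list(
    omega_within = if (is.null(fw)) NA_real_ else fw$omega,
    omega_between = if (is.null(fb)) NA_real_ else fb$omega,
    within = fw, between = fb,
    S_within = S_w, S_between = S_b,
    between_degenerate = is.null(fb)
  ), class = "omega_estimate")
}

#' Marginal and conditional variance explained
#'
#' Per posterior draw: the marginal share is the variance of the
#' fixed-effect predictions over the total model-implied variance (fixed +
#' random + residual); the conditional share adds the random-effect
#' variance (person effects via the row-average quadratic form z' Sigma z,
#' plus the wave- and day-level intercept variances). Summarized by the
#' posterior median.
#'
#' @param fit an `inertia_fit`.
#' @return list with `marginal`, `conditional` (medians) and `draws`
#'   (per-draw tibble).
#' @export
variance_r2 <- function(fit) {
  md <- fit$model_data
  spec <- fit$spec
  dn <- dim(fit$draws)
  gpar <- paste0("b_", colnames(md$X))
  gidx <- match(gpar, fit$par_names)
  n_draw <- dn[1] * dn[2]
  G <- matrix(fit$draws[, , gidx], n_draw, length(gidx))
  var_f <- apply(G %*% t(md$X), 1, stats::var)
  var_r <- rep(0, n_draw)
  if (spec$person_re) {
    sd_idx <- match(paste0("sd_person__",
                           c("Intercept", "overnight", "wd_lag", "on_lag")),
                    fit$par_names)
    cor_idx <- match(paste0("cor_person__",
                            c("Intercept.overnight", "Intercept.wd_lag",
                              "Intercept.on_lag", "overnight.wd_lag",
                              "overnight.on_lag", "wd_lag.on_lag")),
                     fit$par_names)
    SD <- matrix(fit$draws[, , sd_idx], n_draw, 4)
    CR <- matrix(fit$draws[, , cor_idx], n_draw, 6)
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    # mean over rows of z' Sigma z = sum_jk Sigma_jk * mean(z_j z_k)
    M <- crossprod(md$Z) / nrow(md$Z)
    var_r <- var_r + rowSums(SD^2 * matrix(diag(M), n_draw, 4, byrow = TRUE))
    for (pp in seq_len(6)) {
      j <- pairs[pp, 1]; k <- pairs[pp, 2]
      var_r <- var_r + 2 * CR[, pp] * SD[, j] * SD[, k] * M[j, k]
    }
  }
  if (spec$wave_re)
    var_r <- var_r + as.vector(fit$draws[, , "sd_wave__Intercept"])^2
  if (spec$day_re)
    var_r <- var_r + as.vector(fit$draws[, , "sd_day__Intercept"])^2
  sig2 <- as.vector(fit$draws[, , "sigma"])^2
  tot <- var_f + var_r + sig2
  marg <- var_f / tot
  cond <- (var_f + var_r) / tot
  list(marginal = stats::median(marg), conditional = stats::median(cond),
       draws = tibble::tibble(marginal = marg, conditional = cond))
}

#' Person-specific inertia slopes and their correlations
#'
#' Posterior means of the conditional slopes (fixed effect + person
#' deviation) for within-day and overnight inertia, per outcome, with the
#' Pearson correlation matrix across the slope vectors. These are shrunken
#' (partially pooled) individual estimates.
#'
#' @param fits named list of `inertia_fit` objects (e.g.
#'   `list(na = fit_na, pa = fit_pa)`), each fitted with person random
#'   effects.
#' @return object of class `slope_table`: list with `slopes` (tibble, one
#'   row per person) and `correlations` (matrix, `NA` with a warning when
#'   a slope vector is essentially constant).
#' @export
person_slopes <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  per_fit <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    if (!fit$spec$person_re) stop("fit ", nm, " has no person effects")
    g20 <- stats::median(posterior_draws(fit, "b_wd_lag"))
    g30 <- stats::median(posterior_draws(fit, "b_on_lag"))
    u_mean <- Reduce(`+`, lapply(fit$u, function(a) apply(a, c(2, 3), mean))) /
      length(fit$u)
    tb <- tibble::tibble(person_id = fit$model_data$person_ids,
                         wd = g20 + u_mean[, 3], on = g30 + u_mean[, 4])
    names(tb)[2:3] <- paste0(nm, c("_withinday", "_overnight"))
    tb
  })
  slopes <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "person_id"),
                   per_fit)
  if (nrow(slopes) < length(per_fit[[1]]$person_id))
    warning("outcomes fitted on different person sets; aligned on intersection")
  sl <- as.matrix(slopes[-1])
  degenerate <- apply(sl, 2, stats::sd) < 1e-8
  if (any(degenerate)) {
    warning("slope vector(s) essentially constant; correlations undefined")
    cors <- matrix(NA_real_, ncol(sl), ncol(sl),
                   dimnames = list(colnames(sl), colnames(sl)))
  } else {
    cors <- stats::cor(sl)
  }
  structure(list(slopes = slopes, correlations = cors), class = "slope_table")
}

#' Assemble report tables
#'
#' Builds a fixed-effects + calculated-parameters + random-effect-SD table
#' per outcome (the layout of the reference results table) and, when
#' moderation rows are supplied, an interaction grid with significance
#' flags.
#'
#' @param fits named list of `inertia_fit` objects per outcome.
#' @param derived named list of `derived_summary` objects per outcome.
#' @param moderation optional named list (by covariate) of tibbles from
#'   [moderation_table()].
#' @param r2 optional named list per outcome from [variance_r2()].
#' @return object of class `inertia_report`: list with `table2` (tibble),
#'   `table3` (tibble or NULL), `classification` (named labels), and
#'   `observations`.
#' @export
assemble_tables <- function(fits, derived, moderation = NULL, r2 = NULL) {
  stopifnot(identical(sort(names(fits)), sort(names(derived))))
  fixed_rows <- c("b_(Intercept)" = "Intercept", "b_overnight" = "overnight",
                  "b_wd_lag" = "within-day inertia",
                  "b_on_lag" = "overnight inertia")
  sd_rows <- c("sd_person__Intercept" = "SD intercept id",
               "sd_wave__Intercept" = "SD intercept id wave",
               "sd_day__Intercept" = "SD intercept id wave day",
               "sd_person__overnight" = "SD overnight",
               "sd_person__wd_lag" = "SD within-day inertia",
               "sd_person__on_lag" = "SD overnight inertia")
  out <- lapply(names(fits), function(nm) {
    s <- summary(fits[[nm]])
    dtab <- derived[[nm]]$table
    rf <- derived[[nm]]$intervals$ratio_full_rounded
    rc <- derived[[nm]]$intervals$ratio_corrected_rounded
    pick <- function(par, label) {
      r <- s[s$parameter == par, ]
      tibble::tibble(outcome = nm, parameter = label, estimate = r$median,
                     lower = r$lower, upper = r$upper)
    }
    pick_d <- function(q, label) {
      r <- dtab[dtab$quantity == q, ]
      tibble::tibble(outcome = nm, parameter = label, estimate = r$median,
                     lower = r$lower, upper = r$upper)
    }
    dplyr::bind_rows(
      dplyr::bind_rows(lapply(names(fixed_rows), function(p)
        pick(p, fixed_rows[[p]]))),
      pick_d("contrast_continue",
             sprintf("overnight - withinday^%s", rf)),
      pick_d("contrast_pause",
             sprintf("overnight - withinday^%s", rc)),
      dplyr::bind_rows(lapply(names(sd_rows), function(p)
        if (p %in% s$parameter) pick(p, sd_rows[[p]]) else NULL))
    )
  })
  table2 <- dplyr::bind_rows(out)
  table3 <- NULL
  if (!is.null(moderation) && length(moderation)) {
    table3 <- dplyr::bind_rows(lapply(names(moderation), function(cv) {
      tab <- moderation[[cv]]
      tab$covariate <- cv
      tab[tab$target %in% c("withinday_inertia", "overnight_inertia"), ]
    }))
  } else {
    message("no moderation results supplied; interaction table omitted")
  }
  obs <- vapply(fits, function(f) length(f$model_data$y), numeric(1))
  r2tab <- if (!is.null(r2)) {
    dplyr::bind_rows(lapply(names(r2), function(nm)
      tibble::tibble(outcome = nm, marginal = r2[[nm]]$marginal,
                     conditional = r2[[nm]]$conditional)))
  } else NULL
  structure(list(
    table2 = table2, table3 = table3,
    classification = vapply(derived, function(d) d$classification,
                            character(1)),
    observations = obs, r2 = r2tab
  ), class = "inertia_report")
}

#' Write a report bundle to disk
#'
#' Writes `table2.csv`, `table3.csv` (when present), and a short
#' `report.md` with classification labels, observation counts and R2.
#'
#' @param report an `inertia_report` from [assemble_tables()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table2, file.path(dir, "table2.csv"))
  if (!is.null(report$table3))
    readr::write_csv(report$table3, file.path(dir, "table3.csv"))
  lines <- c("# Inertia model report", "",
             paste0("- Overnight process classification: ",
                    paste(sprintf("%s = %s", names(report$classification),
                                  report$classification), collapse = "; ")),
             paste0("- Observations: ",
                    paste(sprintf("%s = %d", names(report$observations),
                                  report$observations), collapse = "; ")))
  if (!is.null(report$r2))
    lines <- c(lines,
               paste0("- Marginal / conditional R2: ",
                      paste(sprintf("%s = %.3f / %.3f", report$r2$outcome,
                                    report$r2$marginal, report$r2$conditional),
                            collapse = "; ")))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
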