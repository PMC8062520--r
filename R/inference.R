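#' MCMC configuration
#'
#' Defaults follow the full estimation protocol: three chains, 100,000 valid
#' posterior draws in total after discarding the first 2,000 iterations of
#' each chain as burn-in and keeping one of every 10 iterations. Tests and
#' examples use a much smaller budget (a few thousand draws without
#' thinning), which is adequate for the property-based checks shipped with
#' the package.
#'
#' @param n_chains Number of chains (default 3).
#' @param n_iterations Total valid posterior draws across chains (default
#'   100,000); each chain keeps `ceiling(n_iterations / n_chains)` draws.
#' @param burn_in Iterations discarded at the start of each chain (default 2,000).
#' @param thinning Keep one draw in `thinning` (default 10).
#' @param seed Integer seed; the whole fit is reproducible given the seed.
#' @param n_lags Number of residual lag terms in the otolith observation
#'   model (default 2, the order selected by [select_lags()] on the source data).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 3, n_iterations = 1e5, burn_in = 2000,
                       thinning = 10, seed = 1, n_lags = 2) {
  stopifnot(
    n_chains >= 1, n_iterations >= 1, burn_in >= 0, thinning >= 1,
    n_lags >= 0
  )
  structure(
    list(
      n_chains = as.integer(n_chains), n_iterations = as.integer(n_iterations),
      burn_in = as.integer(burn_in), thinning = as.integer(thinning),
      seed = as.integer(seed), n_lags = as.integer(n_lags)
    ),
    class = "fit_config"
  )
}

#' Fit the integral growth model by MCMC
#'
#' Joint Bayesian estimation of all growth-model parameters from an otolith
#' daily-increment dataset and a calibration catch dataset: per-fish Gompertz
#' parameters with hierarchical population distributions, the degree-day
#' slope of the asymptote, the lag coefficients of the increment residuals,
#' the otolith-to-length regression coefficients, and the two observation
#' noise scales. The likelihood is normal on otolith radii around the
#' lag-corrected Gompertz expectation and normal on catch lengths around the
#' radius-times-conversion expectation, with latent individual parameters for
#' the catch fish drawn from the same population distributions (partial
#' pooling). Priors are virtually uninformative: wide normals on regression
#' coefficients, half-normals on scales, uniform(-1, 1) on lag coefficients.
#'
#' @param otolith_data Otolith readings tibble (`fish_id`, `age_days`,
#'   `radius_um`, `capture_date`, `region`) or an `otolith_dataset`.
#' @param catch_data Calibration catch tibble (`fish_id`, `fl_cm`,
#'   `age_days`, `capture_date`, `region`) or a `catch_dataset`.
#' @param sst An `sst_series` or named list of them (one per region).
#' @param cfg A [fit_config()].
#' @param environmental If `FALSE`, fixes `beta_t = beta_p = 0`, giving the
#'   environment-independent comparison model.
#' @param point A [geo_point()] for photoperiod at birth.
#' @param priors Optional list overriding the default prior scales.
#' @return An object of class `growth_fit` with elements `draws` (tibble of
#'   population-level and per-otolith-fish draws, one row per kept iteration,
#'   with `.chain`, `.iteration` and `.deviance` columns), `summary`
#'   (posterior means, quantiles and split R-hat per parameter), `dic`,
#'   `config` and the inputs needed for validation.
#' @export
fit_integral_model <- function(otolith_data, catch_data, sst,
                               cfg = fit_config(), environmental = TRUE,
                               point = balearic_point(),
                               priors = default_priors()) {
  if (inherits(otolith_data, "otolith_dataset")) otolith_data <- otolith_data$readings
  if (inherits(catch_data, "catch_dataset")) catch_data <- catch_data$records
  stopifnot(inherits(cfg, "fit_config"))
  d <- prepare_fit_data(otolith_data, catch_data, sst, point, cfg$n_lags)
  n_keep <- as.integer(ceiling(cfg$n_iterations / cfg$n_chains))
  st0 <- init_state(d, cfg$n_lags, env = environmental)

  chains <- withr::with_seed(cfg$seed, {
    chain_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_chains)
    lapply(seq_len(cfg$n_chains), function(ch) {
      run_chain(d, st0, cfg, priors, environmental, n_keep, chain_seeds[ch])
    })
  })

  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iteration = seq_len(n_keep)),
      tibble::as_tibble(chains[[ch]]$pop),
      tibble::as_tibble(chains[[ch]]$fish)
    )
  })
  clat_mean <- Reduce(`+`, lapply(chains, `[[`, "clat_mean")) / length(chains)

  par_cols <- setdiff(names(draws), c(".chain", ".iteration", ".deviance"))
  fixed <- if (environmental) character() else c("beta_t", "beta_p")
  summ <- purrr::map_dfr(par_cols, function(p) {
    x <- draws[[p]]
    per_chain <- split(x, draws$.chain)
    rh <- if (p %in% fixed || stats::sd(x) == 0 || length(per_chain) < 2L) {
      NA_real_
    } else {
      compute_rhat(per_chain)
    }
    q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    tibble::tibble(
      param = p, mean = mean(x), sd = stats::sd(x),
      q2.5 = q[1], median = q[3], q97.5 = q[5], iqr = q[4] - q[2], rhat = rh
    )
  })

  fit <- structure(
    list(
      draws = draws, summary = summ, config = cfg,
      environmental = environmental,
      calibration_ids = unique(catch_data$fish_id),
      clat_mean = clat_mean,
      internals = d, point = point, priors = priors, dic = NULL
    ),
    class = "growth_fit"
  )
  fit$dic <- compute_dic(fit)
  fit
}

# Total data deviance at a parameter configuration, with the asymptote
# intercepts integrated out (matching the deviance recorded per draw).
deviance_at <- function(d, pop_vec, fish_vec, hyper_vec, clat, n_lags, n_fish) {
  m <- d$catch$m
  phi <- if (n_lags) pop_vec[4 + seq_len(n_lags)] else numeric()
  marginal_deviance(
    d,
    logb = log(fish_vec[n_fish + seq_len(n_fish)]),
    logc = log(fish_vec[2 * n_fish + seq_len(n_fish)]),
    phi = phi,
    slope = pop_vec[["linf_slope"]],
    sigma_oto = pop_vec[["sigma_oto"]],
    mu0 = hyper_vec[["mu_linf0"]],
    sd0 = hyper_vec[["sd_linf0"]],
    clogb = clat[m + seq_len(m)],
    clogc = clat[2 * m + seq_len(m)],
    beta0 = pop_vec[["beta0"]],
    beta_t = pop_vec[["beta_t"]],
    beta_p = pop_vec[["beta_p"]],
    sigma_len = pop_vec[["sigma_len"]]
  )
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`: the posterior mean
#' deviance plus the effective number of parameters. The deviance integrates
#' the asymptote intercepts (per-fish and catch-latent) out of the
#' likelihood under their population distribution; conditioning on them
#' would let a model without environmental terms absorb the environmental
#' signal into the latents, blunting the comparison. Lower is better.
#'
#' @param fit A `growth_fit`.
#' @param recompute_deviances If `TRUE`, recompute the per-draw deviances
#'   from the stored parameter draws instead of using the `.deviance` column
#'   recorded during sampling.
#' @return The DIC value (numeric scalar), with `dbar`, `dhat` and `p_d`
#'   attached as attributes.
#' @export
compute_dic <- function(fit, recompute_deviances = FALSE) {
  stopifnot(inherits(fit, "growth_fit"))
  d <- fit$internals
  n_fish <- d$oto$n_fish
  n_lags <- d$n_lags
  pop_cols <- c(
    "linf_slope", "beta0", "beta_t", "beta_p",
    if (n_lags) paste0("phi", seq_len(n_lags)), "sigma_oto", "sigma_len"
  )
  fish_cols <- c(
    paste0("linf0.", d$oto$fish_ids), paste0("b.", d$oto$fish_ids),
    paste0("c.", d$oto$fish_ids)
  )
  hyper_cols <- c("mu_linf0", "sd_linf0")
  devs <- if (recompute_deviances) {
    vapply(seq_len(nrow(fit$draws)), function(i) {
      deviance_at(
        d, unlist(fit$draws[i, pop_cols]),
        unlist(fit$draws[i, fish_cols]),
        unlist(fit$draws[i, hyper_cols]), fit$clat_mean, n_lags, n_fish
      )
    }, numeric(1))
  } else {
    fit$draws$.deviance
  }
  if (!all(is.finite(devs))) stop("non-finite deviance draws", call. = FALSE)
  dbar <- mean(devs)
  pop_mean <- vapply(pop_cols, function(p) mean(fit$draws[[p]]), numeric(1))
  fish_mean <- vapply(fish_cols, function(p) mean(fit$draws[[p]]), numeric(1))
  hyper_mean <- vapply(hyper_cols, function(p) mean(fit$draws[[p]]), numeric(1))
  dhat <- deviance_at(
    d, pop_mean, fish_mean, hyper_mean, fit$clat_mean, n_lags,
    n_fish
  )
  p_d <- dbar - dhat
  structure(dbar + p_d, dbar = dbar, dhat = dhat, p_d = p_d)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Split R-hat: each chain is halved, and the classical potential scale
#' reduction factor is computed over the resulting sequences. Values near 1
#' indicate convergence; the full-protocol fits in the source analysis
#' reached values at or below 1.01 for all parameters.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return The R-hat value (numeric scalar, >= 1 up to floating point).
#' @export
compute_rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains", call. = FALSE)
  }
  len <- lengths(chains)
  if (length(unique(len)) != 1L || len[1] < 10L) {
    stop("chains must have equal lengths >= 10", call. = FALSE)
  }
  half <- floor(len[1] / 2)
  seqs <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[half + seq_len(half)])
  }), recursive = FALSE)
  m <- length(seqs)
  n <- half
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) {
    return(1)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Select the residual lag order for the otolith model
#'
#' Increments the number of lag terms one by one until the within-fish
#' residuals of the radius-at-age model no longer show temporal
#' autocorrelation, judged by a Ljung-Box test on the lag-fit innovations
#' pooled across fish (autocorrelations computed within fish only, three
#' lags tested, alpha = 0.05). Input is either a tibble of residuals
#' (`fish_id`, `resid`, ordered by age within fish) or otolith readings, in
#' which case per-fish residuals are obtained from individual Gompertz
#' least-squares fits.
#'
#' @param data Residuals tibble (columns `fish_id`, `resid`) or otolith
#'   readings tibble (columns `fish_id`, `age_days`, `radius_um`).
#' @param max_lags Largest order to consider.
#' @param alpha Significance level of the pooled Ljung-Box test.
#' @return List with `n_lags` (smallest adequate order) and `report` (tibble
#'   with the fitted lag coefficients and test results per candidate order).
#'   If no candidate order passes, returns `max_lags` with a warning.
#' @export
select_lags <- function(data, max_lags = 5, alpha = 0.05) {
  stopifnot(max_lags >= 0)
  if (!"resid" %in% names(data)) {
    stopifnot(all(c("fish_id", "age_days", "radius_um") %in% names(data)))
    data <- data |>
      dplyr::arrange(.data$fish_id, .data$age_days) |>
      dplyr::group_by(.data$fish_id) |>
      dplyr::group_modify(~ {
        f <- gompertz_point_fit(.x$age_days, .x$radius_um)
        tibble::tibble(resid = .x$radius_um - f)
      }) |>
      dplyr::ungroup()
  }
  resids <- split(data$resid, data$fish_id)
  report <- purrr::map_dfr(0:max_lags, function(n) {
    inn <- lag_innovations(resids, n)
    lb <- pooled_ljung_box(inn$innovations, n_test = 3)
    tibble::tibble(
      n_lags = n,
      phi = list(inn$phi),
      q_stat = lb$q, df = lb$df, p_value = lb$p
    )
  })
  ok <- report$p_value > alpha
  if (!any(ok)) {
    warning("residual autocorrelation persists at max_lags = ", max_lags)
    n_sel <- max_lags
  } else {
    n_sel <- report$n_lags[which(ok)[1]]
  }
  list(n_lags = n_sel, report = report)
}

# Per-fish Gompertz least-squares fitted values (for residual extraction only).
gompertz_point_fit <- function(age, radius) {
  p <- gompertz_point_params(age, radius)
  p$linf * exp(-exp(p$logb) * exp(-exp(p$logc) * age))
}

# Fit shared AR(n) coefficients to within-fish residuals by least squares and
# return the innovation series per fish.
lag_innovations <- function(resids, n) {
  if (n == 0) {
    return(list(phi = numeric(), innovations = resids))
  }
  ys <- list()
  xs <- list()
  for (r in resids) {
    t_len <- length(r)
    if (t_len <= n) next
    idx <- (n + 1):t_len
    ys[[length(ys) + 1]] <- r[idx]
    xs[[length(xs) + 1]] <- vapply(seq_len(n), function(k) r[idx - k], numeric(length(idx)))
  }
  y <- unlist(ys)
  x <- do.call(rbind, xs)
  phi <- as.vector(stats::lm.fit(x, y)$coefficients)
  innovations <- lapply(resids, function(r) {
    t_len <- length(r)
    if (t_len <= n) {
      return(numeric(0))
    }
    idx <- (n + 1):t_len
    pred <- rowSums(vapply(
      seq_len(n), function(k) phi[k] * r[idx - k],
      numeric(length(idx))
    ))
    r[idx] - pred
  })
  list(phi = phi, innovations = innovations)
}

# Ljung-Box statistic with autocorrelations pooled within (never across) fish.
pooled_ljung_box <- function(series_list, n_test = 3) {
  series_list <- series_list[lengths(series_list) > n_test]
  all_v <- unlist(series_list)
  n_tot <- length(all_v)
  denom <- sum((all_v - mean(all_v))^2)
  r_k <- vapply(seq_len(n_test), function(k) {
    num <- sum(vapply(series_list, function(e) {
      e <- e - mean(all_v)
      t_len <- length(e)
      sum(e[(k + 1):t_len] * e[1:(t_len - k)])
    }, numeric(1)))
    num / denom
  }, numeric(1))
  q <- n_tot * (n_tot + 2) * sum(r_k^2 / (n_tot - seq_len(n_test)))
  list(q = q, df = n_test, p = stats::pchisq(q, n_test, lower.tail = FALSE))
}

#' Validate a fitted growth model on held-out catch records
#'
#' Posterior predictive furcal length for each validation fish: for every
#' retained posterior draw, individual Gompertz parameters are drawn from the
#' population distributions of that draw, the otolith radius at the fish's
#' age is computed under its thermal history, converted to length with that
#' draw's regression coefficients, and observation noise is added. Accuracy
#' is the root-mean-square deviation of the posterior-median predictions;
#' precision is the mean predictive interquartile range. Residuals are
#' summarised by region and by month of birth, and a coverage table over
#' 50-day age bins reports the fraction of observations inside the central
#' 95% predictive band.
#'
#' @param fit A `growth_fit`.
#' @param validation_data Validation catch tibble (disjoint fish ids from the
#'   calibration set).
#' @param sst The `sst_series` (or named list) covering the validation fish.
#' @param n_pred_draws Number of posterior draws used (subsampled evenly).
#' @param seed Optional seed for the predictive noise.
#' @return An object of class `validation_report`: list with `rmsd_cm`,
#'   `mean_iqr_cm`, `per_fish`, `by_region`, `by_birth_month`, `bin_coverage`.
#' @export
validate <- function(fit, validation_data, sst, n_pred_draws = 400, seed = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (inherits(validation_data, "catch_dataset")) {
    validation_data <- validation_data$records
  }
  overlap <- intersect(validation_data$fish_id, fit$calibration_ids)
  if (length(overlap)) {
    stop("validation ids overlap calibration set (e.g. `", overlap[1], "`)",
      call. = FALSE
    )
  }
  series <- sst_as_list(sst)
  vd <- validation_data |>
    dplyr::mutate(
      capture_date = as.Date(.data$capture_date),
      birth_date = .data$capture_date - .data$age_days
    )
  m <- nrow(vd)
  ct <- t_b <- numeric(m)
  for (i in seq_len(m)) {
    s <- sst_for_region(series, vd$region[i])
    ct[i] <- cumulative_temperature(s, vd$birth_date[i], vd$age_days[i])
    t_b[i] <- s$temp_c[as.integer(vd$birth_date[i] - s$date[1]) + 1L]
  }
  p_b <- photoperiod_hours(fit$point, vd$birth_date)

  dr <- fit$draws
  take <- unique(round(seq(1, nrow(dr), length.out = min(n_pred_draws, nrow(dr)))))
  sim <- function() {
    preds <- matrix(NA_real_, m, length(take))
    for (j in seq_along(take)) {
      s <- dr[take[j], ]
      linf0 <- stats::rnorm(m, s$mu_linf0, s$sd_linf0)
      b <- exp(stats::rnorm(m, s$mu_logb, s$sd_logb))
      cc <- exp(stats::rnorm(m, s$mu_logc, s$sd_logc))
      otr <- (linf0 + s$linf_slope * ct) * exp(-b * exp(-cc * vd$age_days))
      mu <- otr * (s$beta0 + s$beta_t * t_b + s$beta_p * p_b)
      preds[, j] <- mu + stats::rnorm(m, 0, s$sigma_len)
    }
    preds
  }
  preds <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  qs <- t(apply(preds, 1, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  per_fish <- tibble::tibble(
    fish_id = vd$fish_id, region = vd$region,
    birth_month = as.integer(format(vd$birth_date, "%m")),
    age_days = vd$age_days,
    observed_cm = vd$fl_cm,
    predicted_cm = qs[, 3],
    iqr_cm = qs[, 4] - qs[, 2],
    lo95_cm = qs[, 1], hi95_cm = qs[, 5],
    resid_cm = vd$fl_cm - qs[, 3]
  )
  by_region <- per_fish |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(), median_resid_cm = stats::median(.data$resid_cm),
      iqr_resid_cm = stats::IQR(.data$resid_cm), .groups = "drop"
    )
  by_birth_month <- per_fish |>
    dplyr::group_by(.data$birth_month) |>
    dplyr::summarise(
      n = dplyr::n(), median_resid_cm = stats::median(.data$resid_cm),
      iqr_resid_cm = stats::IQR(.data$resid_cm), .groups = "drop"
    )
  bin_coverage <- per_fish |>
    dplyr::mutate(
      age_bin = cut(.data$age_days, seq(0, ceiling(max(.data$age_days) / 50) * 50, 50))
    ) |>
    dplyr::group_by(.data$age_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      coverage = mean(.data$observed_cm >= .data$lo95_cm &
        .data$observed_cm <= .data$hi95_cm),
      .groups = "drop"
    )
  structure(
    list(
      rmsd_cm = sqrt(mean(per_fish$resid_cm^2)),
      mean_iqr_cm = mean(per_fish$iqr_cm),
      per_fish = per_fish, by_region = by_region,
      by_birth_month = by_birth_month, bin_coverage = bin_coverage
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Growth-model validation report\n")
  cat(sprintf("  accuracy (RMSD):        %.3f cm\n", x$rmsd_cm))
  cat(sprintf("  precision (mean IQR):   %.3f cm\n", x$mean_iqr_cm))
  cat(sprintf("  validation fish:        %d\n", nrow(x$per_fish)))
  invisible(x)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Integral growth model fit (%s)\n",
    if (x$environmental) "environment-dependent" else "environment-independent"
  ))
  cat(sprintf(
    "  %d chains x %d kept draws, burn-in %d, thinning %d\n",
    x$config$n_chains, max(x$draws$.iteration), x$config$burn_in,
    x$config$thinning
  ))
  cat(sprintf("  DIC: %.1f\n", as.numeric(x$dic)))
  pop <- x$summary[x$summary$param %in% c(
    "linf_slope", "beta0", "beta_t", "beta_p", "phi1", "phi2",
    "sigma_oto", "sigma_len"
  ), ]
  print(pop, n = nrow(pop))
  invisible(x)
}

#' Tidy a fitted growth model
#'
#' @param x A `growth_fit`.
#' @param pars `"population"` (default) for shared parameters only, or
#'   `"all"` to include per-fish parameters.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate` (posterior
#'   mean), `std.error` (posterior sd), `conf.low`, `conf.high` (central 95%
#'   credible interval) and `rhat`.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, pars = c("population", "all"), ...) {
  pars <- match.arg(pars)
  s <- x$summary
  if (pars == "population") {
    s <- s[!grepl("^(linf0|b|c)\\.", s$param), ]
  }
  tibble::tibble(
    term = s$param, estimate = s$mean, std.error = s$sd,
    conf.low = s$q2.5, conf.high = s$q97.5, rhat = s$rhat
  )
}

#' Glance at a fitted growth model
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One-row tibble with the DIC, effective parameter count, draw
#'   counts and the worst split R-hat.
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    environmental = x$environmental,
    n_chains = x$config$n_chains,
    n_draws = nrow(x$draws),
    dic = as.numeric(x$dic),
    p_d = attr(x$dic, "p_d"),
    max_rhat = max(x$summary$rhat, na.rm = TRUE)
  )
}
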