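test_that("split R-hat flags non-convergence and passes well-mixed chains", {
  set.seed(2)
  x <- rnorm(2000)
  # identical copies: only the tiny between-half variability remains
  expect_equal(compute_rhat(list(x, x, x)), 1, tolerance = 1e-3)

  set.seed(5)
  chains <- replicate(3, rnorm(10000), simplify = FALSE)
  expect_lt(compute_rhat(chains), 1.01)

  bad <- list(rnorm(5000, 0), rnorm(5000, 10))
  expect_gt(compute_rhat(bad), 1.1)

  # pooled-and-split converged draws stay near 1
  pool <- unlist(chains)
  resplit <- split(pool, rep(1:3, each = 10000))
  expect_lt(compute_rhat(resplit), 1.01)

  expect_error(compute_rhat(list(rnorm(100))), "2 chains")
  expect_error(compute_rhat(list(rnorm(5), rnorm(5))), ">= 10")

  # independent cross-check against coda's Gelman-Rubin diagnostic
  set.seed(8)
  ch <- replicate(3, cumsum(rnorm(4000)) / 20 + rnorm(4000), simplify = FALSE)
  ours <- compute_rhat(ch)
  coda_val <- coda::gelman.diag(
    coda::mcmc.list(lapply(ch, coda::mcmc)),
    autoburnin = FALSE
  )$psrf[1, 1]
  expect_equal(ours, unname(coda_val), tolerance = 0.05)
})

test_that("lag-order selection recovers white noise and AR structure", {
  gen_resid <- function(phi, n_fish = 20, len = 100, seed = 1) {
    withr::with_seed(seed, {
      purrr::map_dfr(seq_len(n_fish), function(i) {
        e <- rnorm(len)
        r <- numeric(len)
        for (t in seq_len(len)) {
          r[t] <- e[t]
          for (k in seq_along(phi)) if (t > k) r[t] <- r[t] + phi[k] * r[t - k]
        }
        tibble::tibble(fish_id = sprintf("f%02d", i), resid = r)
      })
    })
  }
  white <- gen_resid(numeric(), seed = 3)
  expect_equal(select_lags(white)$n_lags, 0)

  ar2 <- gen_resid(c(0.5, 0.2), seed = 4)
  sel <- select_lags(ar2)
  expect_equal(sel$n_lags, 2)
  expect_equal(sel$report$phi[[3]], c(0.5, 0.2), tolerance = 0.12)

  ar1 <- gen_resid(0.5, seed = 5)
  hits <- vapply(1:7, function(s) {
    select_lags(gen_resid(0.5, n_fish = 10, seed = 10 + s))$n_lags
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.5)
})

test_that("lag selection extracts residuals from raw otolith readings", {
  sst <- seasonal_sst(seed = 14)
  ds <- generate_otolith_dataset(sst,
    n_fish = 10, days_range = c(60, 100),
    seed = 15
  )
  sel <- select_lags(ds$readings, max_lags = 4)
  expect_gte(sel$n_lags, 1) # generated residuals are AR(2)-correlated
  expect_equal(nrow(sel$report), 5)
  expect_true(all(diff(sel$report$q_stat) <= 0) || sel$n_lags <= 2)
})

test_that("a reduced-budget fit is reproducible and structurally sound", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_s3_class(fit, "growth_fit")
  expect_equal(nrow(fit$draws), 400)
  td <- tidy(fit)
  expect_true(all(c(
    "linf_slope", "beta0", "beta_t", "beta_p", "phi1",
    "phi2", "sigma_oto", "sigma_len"
  ) %in% td$term))
  expect_true(all(is.finite(fit$draws$.deviance)))
  expect_true(is.finite(as.numeric(fit$dic)))

  # seeded determinism: a second fit with the same config is bitwise equal
  cfg <- fit_config(
    n_chains = 2, n_iterations = 400, burn_in = 200,
    thinning = 1, seed = 7
  )
  fit2 <- fit_integral_model(tf$oto, tf$cd, tf$sst, cfg = cfg)
  expect_identical(fit$draws, fit2$draws)
  expect_identical(as.numeric(fit$dic), as.numeric(fit2$dic))
})

test_that("DIC has zero effective parameters at a degenerate posterior", {
  fit <- tiny_fit()$fit
  par_cols <- setdiff(names(fit$draws), c(".chain", ".iteration"))
  deg <- fit
  means <- colMeans(fit$draws[par_cols])
  for (p in par_cols) deg$draws[[p]] <- rep(means[[p]], nrow(deg$draws))
  dic <- compute_dic(deg, recompute_deviances = TRUE)
  expect_equal(attr(dic, "p_d"), 0, tolerance = 1e-6)
  expect_equal(as.numeric(dic), attr(dic, "dhat"), tolerance = 1e-6)
  # and the regular DIC of a real posterior has positive p_D
  expect_gt(attr(compute_dic(fit), "p_d"), 0)
})

test_that("validation reports are internally consistent and guard id overlap", {
  tf <- tiny_fit()
  vd <- generate_catch_dataset(tf$sst, n_fish = 60, seed = 99)
  vd$records$fish_id <- sprintf("val-%03d", seq_len(60))
  rep <- validate(tf$fit, vd$records, tf$sst, n_pred_draws = 150, seed = 3)
  expect_equal(rep$rmsd_cm, sqrt(mean(rep$per_fish$resid_cm^2)))
  expect_equal(rep$mean_iqr_cm, mean(rep$per_fish$iqr_cm))
  expect_gt(rep$rmsd_cm, 0)
  expect_true(all(rep$bin_coverage$coverage >= 0 & rep$bin_coverage$coverage <= 1))
  expect_true(all(rep$per_fish$iqr_cm > 0))
  expect_setequal(
    rep$by_region$region, unique(vd$records$region)
  )
  # predictions should be in a plausible length range, not degenerate
  expect_gt(stats::cor(rep$per_fish$observed_cm, rep$per_fish$predicted_cm), 0.5)

  overlap <- vd$records
  overlap$fish_id[1] <- tf$cd$records$fish_id[1]
  expect_error(validate(tf$fit, overlap, tf$sst), "overlap")
})

test_that("fit and validation artifacts persist to plain-text files", {
  tf <- tiny_fit()
  dir <- withr::local_tempdir()
  write_fit_artifacts(tf$fit, dir)
  draws <- readr::read_csv(file.path(dir, "posterior_draws.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(draws), nrow(tf$fit$draws))
  rep <- jsonlite::read_json(file.path(dir, "fit_report.json"))
  expect_equal(rep$dic$dic, as.numeric(tf$fit$dic))
  expect_equal(rep$config$n_chains, tf$fit$config$n_chains)

  vd <- generate_catch_dataset(tf$sst, n_fish = 25, seed = 101)
  vd$records$fish_id <- sprintf("pv-%03d", seq_len(25))
  vr <- validate(tf$fit, vd$records, tf$sst, n_pred_draws = 80, seed = 2)
  write_validation_report(vr, dir)
  back <- jsonlite::read_json(file.path(dir, "validation_report.json"))
  expect_equal(back$rmsd_cm, vr$rmsd_cm)
  per <- readr::read_csv(file.path(dir, "validation_per_fish.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(per), 25)
})

test_that("fit errors name the offending fish for unresolvable histories", {
  tf <- tiny_fit()
  bad <- tf$oto$readings
  bad$capture_date[bad$fish_id == "oto-003"] <- as.Date("2010-01-01")
  expect_error(
    fit_integral_model(bad, tf$cd, tf$sst,
      cfg = fit_config(n_chains = 2, n_iterations = 50, burn_in = 10, thinning = 1)
    ),
    "oto-003"
  )
})
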