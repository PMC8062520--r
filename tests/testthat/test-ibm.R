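test_that("survival probability matches its closed form and decomposes", {
  mp <- mortality_params()
  expect_equal(survival_probability(0, 0, mp), 1)
  expect_equal(
    survival_probability(365, 0, mortality_params(f_annual = 0)),
    exp(-1.703)
  )
  expect_equal(survival_probability(365, 0, mortality_params(f_annual = 0)),
    0.1821362947349750,
    tolerance = 1e-12
  )
  # multiplicative decomposition into natural and fishing factors
  p_total <- survival_probability(200, 31, mp)
  p_nat <- survival_probability(200, 0, mp)
  p_fish <- exp(-(mp$f_annual / 365) * 31)
  expect_equal(p_total, p_nat * p_fish)
  expect_gt(p_nat, 0)
  expect_lte(p_nat, 1)
  # doubling exposure squares the fishing factor
  p1 <- survival_probability(200, 10, mp) / p_nat
  p2 <- survival_probability(200, 20, mp) / p_nat
  expect_equal(p2, p1^2)
  expect_error(survival_probability(-1, 0, mp), "non-negative")
})

test_that("fishery exposure days follow the calendar convention", {
  mp <- mortality_params()
  days <- seq(as.Date("2003-06-01"), as.Date("2003-09-20"), by = "day")
  # always-vulnerable fish: full Aug 16..Sep 15 span
  big <- tibble::tibble(date = days, fl_cm = 25)
  expect_equal(days_vulnerable(big, mp), 31L)
  # never vulnerable
  small <- tibble::tibble(date = days, fl_cm = 10)
  expect_equal(days_vulnerable(small, mp), 0L)
  # crossing exactly on Sep 1: days strictly after, through Sep 15
  cross <- tibble::tibble(
    date = days,
    fl_cm = ifelse(days >= as.Date("2003-09-01"), 21, 15)
  )
  expect_equal(days_vulnerable(cross, mp), 14L)
  # reaching size after the evaluation date
  late <- tibble::tibble(
    date = days,
    fl_cm = ifelse(days >= as.Date("2003-09-16"), 21, 15)
  )
  expect_equal(days_vulnerable(late, mp), 0L)
  expect_error(
    days_vulnerable(tibble::tibble(
      date = days[days < as.Date("2003-09-01")],
      fl_cm = 25
    ), mp),
    "too short"
  )
})

test_that("population simulation respects mortality switches and seeding", {
  sst <- seasonal_sst(seed = 21, noise = 0)
  pdf <- hatch_date_pdf(sst)
  pop <- truth_params()$pop
  none <- mortality_params(m_annual = 0, f_annual = 0)
  d0 <- simulate_population(sst, pdf, pop, none, n = 800, seed = 3)
  expect_true(all(d0$fish$survived[!is.na(d0$fish$survived)]))
  expect_true(all(d0$fish$survival_prob[!is.na(d0$fish$survival_prob)] == 1))
  n_big <- sum(!is.na(d0$fish$length_at_eval_cm) &
    d0$fish$length_at_eval_cm >= 20)
  expect_equal(length(d0$lengths), n_big)
  expect_true(all(d0$lengths >= 20))

  mp <- mortality_params()
  d1 <- simulate_population(sst, pdf, pop, mp, n = 500, seed = 4)
  d2 <- simulate_population(sst, pdf, pop, mp, n = 500, seed = 4)
  expect_identical(d1$fish, d2$fish)
  expect_identical(d1$summary, d2$summary)
})

test_that("realized survival matches the mean survival probability", {
  sst <- seasonal_sst(seed = 22, noise = 0)
  pdf <- hatch_date_pdf(sst)
  pop <- truth_params()$pop
  d <- simulate_population(sst, pdf, pop, mortality_params(), n = 1e5, seed = 9)
  ok <- !is.na(d$fish$survived)
  p_bar <- mean(d$fish$survival_prob[ok])
  se <- sqrt(sum(d$fish$survival_prob[ok] * (1 - d$fish$survival_prob[ok]))) / sum(ok)
  expect_lt(abs(mean(d$fish$survived[ok]) - p_bar), 3 * se)
})

test_that("percent change is exact on constructed distributions", {
  mk <- function(lengths, label) {
    structure(
      list(
        scenario = label, lengths = lengths, no_catch = length(lengths) == 0,
        summary = tibble::tibble(mean_cm = mean(lengths))
      ),
      class = "catch_distribution"
    )
  }
  base <- mk(rep(40, 100), "base")
  expect_equal(percent_change(base, base), 0)
  up <- mk(rep(45.28, 100), "up")
  expect_equal(percent_change(up, base), 13.2)
  scaled <- mk(rep(40, 100) * 1.1, "scaled")
  expect_equal(percent_change(scaled, base), 10)
  empty <- mk(numeric(), "none")
  expect_error(percent_change(up, empty), "empty")
})

test_that("scenario experiments propagate warming into larger catch sizes", {
  sst <- seasonal_sst(seed = 23, noise = 0)
  specs <- list(
    baseline = scenario_spec("baseline"),
    warm3 = scenario_spec("uniform_offset", offset_c = 3)
  )
  ex <- run_scenario_experiment(
    sst, specs, spawning_params(), truth_params()$pop,
    mortality_params(),
    n = 3000, seed = 31
  )
  expect_equal(ex$summary$pct_change_mean[ex$summary$scenario == "baseline"], 0)
  expect_gt(ex$summary$pct_change_mean[ex$summary$scenario == "warm3"], 0)
  expect_setequal(unique(ex$lengths$scenario), c("baseline", "warm3"))
  # mean length never decreases across increasing uniform offsets
  means <- vapply(c(0, 1.5, 3), function(off) {
    sp <- if (off == 0) {
      scenario_spec("baseline")
    } else {
      scenario_spec("uniform_offset", offset_c = off)
    }
    series <- apply_scenario(sst, sp)
    pp <- hatch_date_pdf(series)
    simulate_population(series, pp, truth_params()$pop, mortality_params(),
      n = 3000, seed = 32
    )$summary$mean_cm
  }, numeric(1))
  expect_true(all(diff(means) > -0.2)) # monotone up to Monte Carlo noise
})
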