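#' Mortality and fishery parameters
#'
#' Instantaneous natural and fishing mortality with the fishery's size and
#' season constraints. Defaults follow the Mediterranean age-0 dolphinfish
#' FAD fishery: natural mortality 1.703 per year (empirical longevity-based
#' estimate for a 3-year maximum lifespan), fishing mortality 5 per year
#' (mid-range of the 3-6 per year reported for the fishery), size of
#' vulnerability 20 cm furcal length, season opening August 15 and
#' evaluation of the catch one month later on September 15. Annual rates are
#' converted to daily scale by dividing by 365 and multiplying by exposure
#' days. Fishing mortality operates only on days after both the season has
#' opened and the fish has reached the vulnerability size.
#'
#' @param m_annual Instantaneous natural mortality (1/year).
#' @param f_annual Instantaneous fishing mortality (1/year).
#' @param t_max_years Maximum lifespan behind the natural-mortality estimate
#'   (documentation only; `m_annual` is the configurable input).
#' @param vulnerability_fl Minimum catchable furcal length (cm).
#' @param season_open Season opening, `"MM-DD"` or a full date.
#' @param evaluation_date Date the length distribution is evaluated,
#'   `"MM-DD"` or a full date; must not precede `season_open`.
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(m_annual = 1.703, f_annual = 5, t_max_years = 3,
                             vulnerability_fl = 20, season_open = "08-15",
                             evaluation_date = "09-15") {
  if (m_annual < 0 || f_annual < 0) stop("mortality rates must be >= 0", call. = FALSE)
  if (vulnerability_fl <= 0) stop("`vulnerability_fl` must be > 0", call. = FALSE)
  structure(
    list(
      m_annual = m_annual, f_annual = f_annual, t_max_years = t_max_years,
      vulnerability_fl = vulnerability_fl, season_open = season_open,
      evaluation_date = evaluation_date
    ),
    class = "mortality_params"
  )
}

# Resolve "MM-DD" season fields against a calendar year.
resolve_season <- function(mp, year) {
  to_date <- function(x) {
    if (inherits(x, "Date")) {
      return(x)
    }
    if (grepl("^\\d{4}-", x)) as.Date(x) else as.Date(sprintf("%d-%s", year, x))
  }
  open <- to_date(mp$season_open)
  eval_date <- to_date(mp$evaluation_date)
  if (eval_date < open) {
    stop("`evaluation_date` must not precede `season_open`", call. = FALSE)
  }
  list(open = open, eval = eval_date)
}

#' Survival probability to the evaluation date
#'
#' `P = exp(-(m/365) * age - (f/365) * days_vulnerable)`: exponential decay
#' under natural mortality over the whole life and under fishing mortality
#' over the days of fishery exposure only. The two factors decompose
#' multiplicatively.
#'
#' @param age_at_eval_days Age at the evaluation date (days, >= 0); vectorised.
#' @param days_vulnerable Days of fishery exposure (>= 0); vectorised.
#' @param mp A [mortality_params()].
#' @return Survival probability in `(0, 1]`.
#' @export
#' @examples
#' survival_probability(365, 0, mortality_params(f_annual = 0)) # exp(-1.703)
survival_probability <- function(age_at_eval_days, days_vulnerable, mp) {
  stopifnot(inherits(mp, "mortality_params"))
  if (any(age_at_eval_days < 0) || any(days_vulnerable < 0)) {
    stop("ages and day counts must be non-negative", call. = FALSE)
  }
  exp(-(mp$m_annual / 365) * age_at_eval_days -
    (mp$f_annual / 365) * days_vulnerable)
}

#' Days of fishery exposure along a length trajectory
#'
#' Counts the days on which fishing mortality operates: days strictly after
#' the later of the season opening and the day the fish first reaches the
#' vulnerability size, through the evaluation date inclusive. A fish already
#' vulnerable before the opening is exposed for the full opening-to-
#' evaluation span (31 days for August 15 to September 15).
#'
#' @param trajectory Tibble with columns `date` and `fl_cm`, covering through
#'   the evaluation date.
#' @param mp A [mortality_params()].
#' @return Integer number of exposure days.
#' @export
days_vulnerable <- function(trajectory, mp) {
  stopifnot(all(c("date", "fl_cm") %in% names(trajectory)))
  year <- as.integer(format(max(trajectory$date), "%Y"))
  season <- resolve_season(mp, year)
  if (max(trajectory$date) < season$eval) {
    stop("trajectory too short: must cover through ", format(season$eval),
      call. = FALSE
    )
  }
  hit <- which(trajectory$fl_cm >= mp$vulnerability_fl)
  if (!length(hit)) {
    return(0L)
  }
  reach <- trajectory$date[hit[1]]
  max(0L, as.integer(season$eval - max(season$open, reach)))
}

#' Simulate a population and its length distribution at catch
#'
#' The individual-based simulation: `n` birthdates are sampled from the
#' hatch-date distribution; each fish receives individual Gompertz
#' parameters from the population distributions, grows daily under the
#' scenario's thermal forcing (lag corrections are zero for simulated fish,
#' which have no observation history), and its furcal length trajectory
#' determines when it becomes vulnerable to the fishery. Survival to the
#' evaluation date is Bernoulli with the exponential survival probability;
#' the catch distribution collects surviving fish at or above the
#' vulnerability size.
#'
#' @param sst The scenario `sst_series`.
#' @param pdf Hatch-date distribution for the scenario (see [hatch_date_pdf()]).
#' @param pop A [growth_params()] whose `hyper` element supplies the
#'   individual-parameter distributions.
#' @param mp A [mortality_params()].
#' @param n Number of simulated fish.
#' @param seed Optional integer seed.
#' @param point A [geo_point()] for photoperiod at birth.
#' @param label Scenario label (defaults to the series region).
#' @param chunk_size Fish processed per vectorised block (memory control).
#' @return An object of class `catch_distribution`: list with `scenario`,
#'   `fish` (per-fish tibble: birthdate, birth conditions, length at
#'   evaluation, vulnerability dates, survival), `lengths` (cm, surviving
#'   vulnerable fish; empty if there is no catch) and `summary`.
#' @export
simulate_population <- function(sst, pdf, pop, mp = mortality_params(), n,
                                seed = NULL, point = balearic_point(),
                                label = NULL, chunk_size = 10000) {
  validate_sst(sst)
  stopifnot(inherits(pop, "growth_params"), !is.null(pop$hyper), n >= 1)
  if (is.null(label)) label <- sst$region[1]
  year <- as.integer(format(pdf$date[1], "%Y"))
  season <- resolve_season(mp, year)
  if (season$eval > max(sst$date)) {
    stop("SST series must cover the evaluation date", call. = FALSE)
  }
  run <- function() {
    birth <- sample_birthdates(pdf, n)
    hyper <- pop$hyper
    cs <- cumsum(sst$temp_c)
    fish <- purrr::map_dfr(
      split(seq_len(n), ceiling(seq_len(n) / chunk_size)),
      function(ix) simulate_chunk(ix, birth[ix], sst, cs, pop, hyper, mp, season, point)
    )
    caught <- !is.na(fish$length_at_eval_cm) & fish$survived &
      fish$length_at_eval_cm >= mp$vulnerability_fl
    lengths <- fish$length_at_eval_cm[caught]
    summary <- tibble::tibble(
      scenario = label, n_fish = n, n_catch = length(lengths),
      mean_cm = if (length(lengths)) mean(lengths) else NA_real_,
      median_cm = if (length(lengths)) stats::median(lengths) else NA_real_,
      iqr_cm = if (length(lengths)) stats::IQR(lengths) else NA_real_,
      var_cm2 = if (length(lengths) > 1) stats::var(lengths) else NA_real_
    )
    structure(
      list(
        scenario = label, fish = fish, lengths = lengths, summary = summary,
        no_catch = length(lengths) == 0L, mp = mp
      ),
      class = "catch_distribution"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Vectorised daily growth, vulnerability and survival for one block of fish.
simulate_chunk <- function(ids, birth, sst, cs, pop, hyper, mp, season, point) {
  k <- length(ids)
  age_eval <- as.integer(season$eval - birth)
  linf0 <- stats::rnorm(k, hyper$mu_linf0, hyper$sd_linf0)
  b <- exp(stats::rnorm(k, hyper$mu_logb, hyper$sd_logb))
  cc <- exp(stats::rnorm(k, hyper$mu_logc, hyper$sd_logc))
  i0 <- as.integer(birth - sst$date[1]) + 1L
  t_b <- sst$temp_c[i0]
  p_b <- photoperiod_hours(point, birth)
  mult <- pop$beta0 + pop$beta_t * t_b + pop$beta_p * p_b

  alive_now <- age_eval >= 0L
  len_eval <- rep(NA_real_, k)
  reach_date <- as.Date(rep(NA, k))
  dv <- integer(k)
  surv_p <- rep(NA_real_, k)
  survived <- rep(NA, k)
  sel <- which(alive_now)
  if (length(sel)) {
    lens <- age_eval[sel] + 1L
    fi <- rep(seq_along(sel), lens)
    a <- sequence(lens) - 1L
    g_idx <- sel[fi]
    ct <- cs[i0[g_idx] + a] - ifelse(i0[g_idx] > 1L, cs[pmax(i0[g_idx] - 1L, 1L)], 0)
    fl <- (linf0[g_idx] + pop$linf_slope * ct) *
      exp(-b[g_idx] * exp(-cc[g_idx] * a)) * mult[g_idx]
    vuln <- fl >= mp$vulnerability_fl
    if (any(vuln)) {
      first <- tapply(a[vuln], fi[vuln], min)
      reach_date[sel[as.integer(names(first))]] <-
        birth[sel[as.integer(names(first))]] + as.integer(first)
    }
    at_eval <- a == age_eval[sel][fi]
    len_eval[sel[fi[at_eval]]] <- fl[at_eval]
    dv[sel] <- pmax(
      0L,
      as.integer(season$eval - pmax(season$open, reach_date[sel]))
    )
    dv[sel][is.na(reach_date[sel])] <- 0L
    surv_p[sel] <- survival_probability(age_eval[sel], dv[sel], mp)
    survived[sel] <- stats::runif(length(sel)) < surv_p[sel]
  }
  tibble::tibble(
    fish_id = ids, birth_date = birth, t_b_c = t_b, p_b_h = p_b,
    length_at_eval_cm = len_eval, date_reached_vulnerability = reach_date,
    days_vulnerable = dv, survival_prob = surv_p, survived = survived
  )
}

#' @export
print.catch_distribution <- function(x, ...) {
  cat(sprintf("Catch length distribution — scenario `%s`\n", x$scenario))
  if (x$no_catch) {
    cat("  no catch: no surviving fish at or above the vulnerability size\n")
  } else {
    s <- x$summary
    cat(sprintf(
      "  %d of %d simulated fish in the catch; mean %.2f cm, median %.2f cm, IQR %.2f cm\n",
      s$n_catch, s$n_fish, s$mean_cm, s$median_cm, s$iqr_cm
    ))
  }
  invisible(x)
}

#' Percent change in mean length at catch versus a baseline
#'
#' `100 * (mean(dist) - mean(baseline)) / mean(baseline)`.
#'
#' @param dist,baseline `catch_distribution` objects (non-empty).
#' @return Percent change (numeric scalar).
#' @export
percent_change <- function(dist, baseline) {
  stopifnot(
    inherits(dist, "catch_distribution"),
    inherits(baseline, "catch_distribution")
  )
  if (baseline$no_catch) stop("baseline distribution is empty", call. = FALSE)
  if (dist$no_catch) stop("scenario distribution is empty", call. = FALSE)
  100 * (mean(dist$lengths) - mean(baseline$lengths)) / mean(baseline$lengths)
}

#' Run the catch-length experiment over a set of thermal scenarios
#'
#' For each scenario: transform the baseline SST series, rebuild the
#' hatch-date distribution under the transformed series (so phenological
#' shifts are propagated), simulate the population and collect the catch
#' length distribution. All scenarios are compared to the baseline via the
#' percent change in mean length.
#'
#' @param base_sst Baseline `sst_series`.
#' @param scenario_specs Named list of [scenario_spec()]s; must include a
#'   baseline (kind `"baseline"`).
#' @param spawn A [spawning_params()] (or intensity function).
#' @param pop A [growth_params()] with hyperparameters.
#' @param mp A [mortality_params()].
#' @param n Fish per scenario.
#' @param seed Integer seed; per-scenario sub-seeds are derived from it.
#' @param point A [geo_point()].
#' @return An object of class `scenario_experiment`: list with
#'   `distributions` (named list of `catch_distribution`s), `lengths` (long
#'   tibble `scenario`, `fish_id`, `fl_cm`) and `summary` (per-scenario
#'   statistics and `pct_change_mean`).
#' @export
run_scenario_experiment <- function(base_sst, scenario_specs, spawn, pop,
                                    mp = mortality_params(), n = 10000,
                                    seed = 1, point = balearic_point()) {
  stopifnot(is.list(scenario_specs), length(scenario_specs) >= 1)
  if (is.null(names(scenario_specs)) || any(!nzchar(names(scenario_specs)))) {
    names(scenario_specs) <- vapply(scenario_specs, `[[`, character(1), "label")
  }
  kinds <- vapply(scenario_specs, `[[`, character(1), "kind")
  base_idx <- which(kinds == "baseline")[1]
  if (is.na(base_idx)) {
    stop("`scenario_specs` must include a baseline scenario", call. = FALSE)
  }
  sub_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, length(scenario_specs))
  )
  dists <- purrr::imap(scenario_specs, function(spec, nm) {
    i <- match(nm, names(scenario_specs))
    series <- apply_scenario(base_sst, spec)
    pdf <- hatch_date_pdf(series, spawn)
    simulate_population(series, pdf, pop, mp,
      n = n, seed = sub_seeds[i],
      point = point, label = nm
    )
  })
  baseline <- dists[[base_idx]]
  summary <- purrr::map_dfr(dists, function(dd) {
    s <- dd$summary
    s$pct_change_mean <- if (dd$no_catch || baseline$no_catch) {
      NA_real_
    } else {
      percent_change(dd, baseline)
    }
    s
  })
  lengths <- purrr::imap_dfr(dists, function(dd, nm) {
    if (dd$no_catch) {
      return(tibble::tibble(
        scenario = character(), fish_id = integer(),
        fl_cm = numeric()
      ))
    }
    caught <- dd$fish[!is.na(dd$fish$length_at_eval_cm) & dd$fish$survived &
      dd$fish$length_at_eval_cm >= dd$mp$vulnerability_fl, ]
    tibble::tibble(scenario = nm, fish_id = caught$fish_id, fl_cm = caught$length_at_eval_cm)
  })
  structure(
    list(
      distributions = dists, lengths = lengths, summary = summary,
      baseline = names(scenario_specs)[base_idx]
    ),
    class = "scenario_experiment"
  )
}

#' @export
print.scenario_experiment <- function(x, ...) {
  cat(
    "Thermal-scenario catch-length experiment (baseline: `",
    x$baseline, "`)\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Tidy a scenario experiment
#'
#' @param x A `scenario_experiment`.
#' @param ... Unused.
#' @return The per-scenario summary tibble.
#' @exportS3Method generics::tidy
tidy.scenario_experiment <- function(x, ...) x$summary
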