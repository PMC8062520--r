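#' Specification of a synthetic daily SST series
#'
#' Parametric Mediterranean-like seasonal SST: an annual cosine cycle plus
#' AR(1) day-to-day noise, `temp(d) = mean_c + amplitude_c *
#' cos(2*pi*(doy - phase_day)/365.25) + e(d)` with `e` a stationary AR(1)
#' process of marginal standard deviation `noise_sd_c` and lag-1
#' autocorrelation `noise_ar`. Defaults emulate the western Mediterranean:
#' annual mean about 20.5 degrees Celsius, seasonal half-range 7 degrees,
#' maximum in mid-August, modest red noise.
#'
#' @param mean_c Annual mean (degrees Celsius).
#' @param amplitude_c Seasonal half-range (>= 0).
#' @param phase_day Day-of-year of the seasonal maximum.
#' @param noise_sd_c Marginal daily noise scale (>= 0).
#' @param noise_ar Lag-1 autocorrelation of the noise, `|noise_ar| < 1`.
#' @param start First date of the series.
#' @param years Number of (365-day-or-more) calendar years to span.
#' @param region Region label.
#' @return An object of class `sst_gen_spec`.
#' @export
sst_gen_spec <- function(mean_c = 20.5, amplitude_c = 7, phase_day = 227,
                         noise_sd_c = 0.4, noise_ar = 0.8,
                         start = "2003-01-01", years = 2,
                         region = "synthetic-balearic") {
  if (amplitude_c < 0) stop("`amplitude_c` must be >= 0", call. = FALSE)
  if (noise_sd_c < 0) stop("`noise_sd_c` must be >= 0", call. = FALSE)
  if (abs(noise_ar) >= 1) stop("`noise_ar` must satisfy |noise_ar| < 1", call. = FALSE)
  structure(
    list(
      mean_c = mean_c, amplitude_c = amplitude_c, phase_day = phase_day,
      noise_sd_c = noise_sd_c, noise_ar = noise_ar,
      start = as.Date(start), years = years, region = region
    ),
    class = "sst_gen_spec"
  )
}

#' Generate a synthetic daily SST series
#'
#' @param spec An [sst_gen_spec()].
#' @param seed Optional integer seed for the noise; the deterministic seasonal
#'   component is unaffected.
#' @return An `sst_series` tibble.
#' @export
#' @examples
#' sst <- generate_sst(sst_gen_spec(noise_sd_c = 0), seed = 1)
generate_sst <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sst_gen_spec"))
  end <- as.Date(sprintf(
    "%d-12-31",
    as.integer(format(spec$start, "%Y")) + spec$years - 1L
  ))
  dates <- seq(spec$start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- spec$mean_c +
    spec$amplitude_c * cos(2 * pi * (doy - spec$phase_day) / 365.25)
  gen_noise <- function() {
    n <- length(dates)
    if (spec$noise_sd_c == 0) {
      return(numeric(n))
    }
    innov_sd <- spec$noise_sd_c * sqrt(1 - spec$noise_ar^2)
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, spec$noise_sd_c)
    innov <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) e[t] <- spec$noise_ar * e[t - 1] + innov[t - 1]
    e
  }
  noise <- if (is.null(seed)) gen_noise() else withr::with_seed(seed, gen_noise())
  sst_series(dates, seasonal + noise, region = spec$region)
}

#' Mediterranean region presets
#'
#' Named SST generator specs emulating the between-region thermal contrast of
#' the study areas (warmer/cooler annual means, slightly shifted seasonal
#' phase), which is what makes the degree-day slope identifiable from fish
#' grown in different regions.
#'
#' @param start,years Passed to [sst_gen_spec()].
#' @return Named list of `sst_gen_spec` objects.
#' @export
mediterranean_regions <- function(start = "2003-01-01", years = 2) {
  list(
    balearic = sst_gen_spec(
      mean_c = 20.2, amplitude_c = 7.0, phase_day = 227,
      start = start, years = years, region = "balearic"
    ),
    malta = sst_gen_spec(
      mean_c = 21.3, amplitude_c = 6.3, phase_day = 232,
      start = start, years = years, region = "malta"
    ),
    sicily = sst_gen_spec(
      mean_c = 20.8, amplitude_c = 6.6, phase_day = 224,
      start = start, years = years, region = "sicily"
    )
  )
}

#' Ground-truth parameters for synthetic datasets
#'
#' The full set of population-level growth parameters, individual-parameter
#' hyperparameters and spawning parameters used by the generators, chosen to
#' give biologically plausible magnitudes for Mediterranean age-0 dolphinfish:
#' otolith radii of a few hundred to about a thousand micrometers over the
#' first 150 days, and furcal lengths in the fishery size range (upward of
#' 20 cm) at catch. Every generated dataset carries these values so the
#' generate-fit-compare recovery loop is a first-class test fixture.
#'
#' @param linf_slope,beta0,beta_t,beta_p,phi,sigma_oto,sigma_len Population
#'   parameters, see [growth_params()].
#' @param hyper Hyperparameters of the individual-parameter distributions.
#' @param spawn A [spawning_params()].
#' @return List with elements `pop` (a [growth_params()]) and `spawn`.
#' @export
truth_params <- function(linf_slope = 0.15, beta0 = 0.012, beta_t = 5e-4,
                         beta_p = 8e-4, phi = c(0.5, 0.2), sigma_oto = 15,
                         sigma_len = 1.5,
                         hyper = list(
                           mu_linf0 = 500, sd_linf0 = 40,
                           mu_logb = log(4), sd_logb = 0.10,
                           mu_logc = log(0.045), sd_logc = 0.08
                         ),
                         spawn = spawning_params()) {
  list(
    pop = growth_params(
      linf_slope = linf_slope, beta0 = beta0, beta_t = beta_t, beta_p = beta_p,
      phi = phi, sigma_oto = sigma_oto, sigma_len = sigma_len, hyper = hyper
    ),
    spawn = spawn
  )
}

# Draw per-fish Gompertz parameters from the hyper-distributions.
draw_individuals <- function(n, hyper) {
  tibble::tibble(
    linf0 = stats::rnorm(n, hyper$mu_linf0, hyper$sd_linf0),
    b = exp(stats::rnorm(n, hyper$mu_logb, hyper$sd_logb)),
    c = exp(stats::rnorm(n, hyper$mu_logc, hyper$sd_logc))
  )
}

# Sample birthdates whose capture window fits inside the series.
sample_feasible_birthdates <- function(sst, spawn, n, max_age) {
  pdf <- hatch_date_pdf(sst, spawn)
  ok <- pdf$date + max_age <= max(sst$date)
  pdf <- pdf[ok, ]
  if (nrow(pdf) == 0L || sum(pdf$prob) <= 0) {
    stop("SST series too short for the requested capture ages", call. = FALSE)
  }
  pdf$prob <- pdf$prob / sum(pdf$prob)
  pdf$date[sample.int(nrow(pdf), n, replace = TRUE, prob = pdf$prob)]
}

#' Generate a synthetic otolith daily-increment dataset
#'
#' Emulates an otolith biochronology dataset: for each fish a birthdate is
#' drawn from the temperature-driven hatch-date distribution of its region,
#' individual Gompertz parameters are drawn from the population
#' distributions, the expected radius-at-age follows the thermally modulated
#' Gompertz curve, and observed radii add a lag-correlated residual process
#' (coefficients `phi`, innovation scale `sigma_oto`, initialised from zero
#' history at the first increment, matching the fitting likelihood).
#'
#' @param sst An `sst_series`, or a named list of them (one per region; fish
#'   are spread across regions round-robin).
#' @param truth A [truth_params()] list.
#' @param n_fish Number of fish.
#' @param days_range Integer range of capture ages (days); each fish's age at
#'   capture is drawn uniformly in this range and its increments are read at
#'   ages `1..age_at_capture`.
#' @param seed Optional integer seed.
#' @return List of class `otolith_dataset` with elements `readings` (tibble
#'   `fish_id`, `age_days`, `radius_um`, `capture_date`, `region`), `fish`
#'   (per-fish truth: birthdate and individual parameters) and `truth`.
#' @export
generate_otolith_dataset <- function(sst, truth = truth_params(), n_fish = 20,
                                     days_range = c(60, 150), seed = NULL) {
  gen <- function() {
    series <- if (inherits(sst, "data.frame")) list(sst) else sst
    series <- lapply(series, validate_sst)
    regions <- vapply(series, function(s) s$region[1], character(1))
    reg_idx <- rep_len(seq_along(series), n_fish)
    hyper <- truth$pop$hyper
    ind <- draw_individuals(n_fish, hyper)
    ages_at_capture <- sample(days_range[1]:days_range[2], n_fish, replace = TRUE)
    fish <- tibble::tibble(
      fish_id = sprintf("oto-%03d", seq_len(n_fish)),
      region = regions[reg_idx],
      age_at_capture = ages_at_capture,
      linf0 = ind$linf0, b = ind$b, c = ind$c
    )
    fish$birth_date <- as.Date(NA)
    for (r in seq_along(series)) {
      sel <- which(reg_idx == r)
      if (!length(sel)) next
      fish$birth_date[sel] <- sample_feasible_birthdates(
        series[[r]], truth$spawn, length(sel), max(days_range)
      )
    }
    fish$capture_date <- fish$birth_date + fish$age_at_capture
    readings <- purrr::map_dfr(seq_len(n_fish), function(i) {
      s <- series[[reg_idx[i]]]
      traj <- radius_trajectory(
        individual_params(fish$linf0[i], fish$b[i], fish$c[i]),
        truth$pop, s, fish$birth_date[i], fish$age_at_capture[i]
      )
      mu <- traj$radius_um[-1] # increments read at ages 1..A
      nr <- length(mu)
      phi <- truth$pop$phi
      e <- stats::rnorm(nr, 0, truth$pop$sigma_oto)
      r <- numeric(nr)
      for (t in seq_len(nr)) {
        r[t] <- e[t]
        for (k in seq_along(phi)) {
          if (t > k) r[t] <- r[t] + phi[k] * r[t - k]
        }
      }
      tibble::tibble(
        fish_id = fish$fish_id[i],
        age_days = traj$age_days[-1],
        radius_um = mu + r,
        capture_date = fish$capture_date[i],
        region = fish$region[i]
      )
    })
    structure(
      list(readings = readings, fish = fish, truth = truth),
      class = "otolith_dataset"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic catch (length-at-age) dataset
#'
#' Emulates the aged-catch dataset used to calibrate and validate the
#' otolith-to-length conversion: per fish a birthdate from the hatch-date
#' distribution, individual growth parameters from the population
#' distributions, the otolith radius at capture from the thermally modulated
#' Gompertz curve, and a furcal length from the radius and the birth
#' conditions plus observation noise.
#'
#' @param sst An `sst_series` or named list of them.
#' @param truth A [truth_params()] list.
#' @param n_fish Number of fish (the source dataset held 1876).
#' @param age_range Integer range of ages at capture (days).
#' @param point A [geo_point()] for photoperiod at birth.
#' @param seed Optional integer seed.
#' @return List of class `catch_dataset` with elements `records` (tibble
#'   `fish_id`, `fl_cm`, `age_days`, `capture_date`, `region`), `fish`
#'   (per-fish truth incl. birth conditions and true radius) and `truth`.
#' @export
generate_catch_dataset <- function(sst, truth = truth_params(), n_fish = 1876,
                                   age_range = c(60, 150),
                                   point = balearic_point(), seed = NULL) {
  gen <- function() {
    series <- if (inherits(sst, "data.frame")) list(sst) else sst
    series <- lapply(series, validate_sst)
    regions <- vapply(series, function(s) s$region[1], character(1))
    reg_idx <- rep_len(seq_along(series), n_fish)
    ind <- draw_individuals(n_fish, truth$pop$hyper)
    ages <- sample(age_range[1]:age_range[2], n_fish, replace = TRUE)
    birth <- as.Date(rep(NA, n_fish))
    for (r in seq_along(series)) {
      sel <- which(reg_idx == r)
      if (!length(sel)) next
      birth[sel] <- sample_feasible_birthdates(
        series[[r]], truth$spawn, length(sel), max(age_range)
      )
    }
    ct <- t_b <- numeric(n_fish)
    for (r in seq_along(series)) {
      sel <- which(reg_idx == r)
      if (!length(sel)) next
      s <- series[[r]]
      ct[sel] <- vapply(
        sel, function(i) cumulative_temperature(s, birth[i], ages[i]),
        numeric(1)
      )
      t_b[sel] <- s$temp_c[as.integer(birth[sel] - s$date[1]) + 1L]
    }
    p_b <- photoperiod_hours(point, birth)
    linf <- ind$linf0 + truth$pop$linf_slope * ct
    otr <- gompertz_radius(linf, ind$b, ind$c, ages)
    mult <- truth$pop$beta0 + truth$pop$beta_t * t_b + truth$pop$beta_p * p_b
    fl <- otr * mult + stats::rnorm(n_fish, 0, truth$pop$sigma_len)
    fish_id <- sprintf("catch-%04d", seq_len(n_fish))
    structure(
      list(
        records = tibble::tibble(
          fish_id = fish_id, fl_cm = fl, age_days = ages,
          capture_date = birth + ages, region = regions[reg_idx]
        ),
        fish = tibble::tibble(
          fish_id = fish_id, birth_date = birth, region = regions[reg_idx],
          t_b_c = t_b, p_b_h = p_b, otr_um = otr,
          linf0 = ind$linf0, b = ind$b, c = ind$c
        ),
        truth = truth
      ),
      class = "catch_dataset"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Split catch records into calibration and validation sets
#'
#' Seeded random split into disjoint sets whose union is the input,
#' proportioned like the source study (1000 calibration / 876 validation).
#'
#' @param records Catch records tibble (one row per fish).
#' @param n_calibration Number of calibration fish.
#' @param seed Optional integer seed.
#' @return List with tibbles `calibration` and `validation`.
#' @export
split_calibration_validation <- function(records, n_calibration = 1000, seed = NULL) {
  n <- nrow(records)
  if (n_calibration >= n) stop("`n_calibration` must be < nrow(records)", call. = FALSE)
  pick <- function() sort(sample.int(n, n_calibration))
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(calibration = records[idx, ], validation = records[-idx, ])
}

#' Interpolate a weekly SST series to daily resolution
#'
#' Climate-model thermal projections are often supplied at weekly resolution;
#' the growth model steps daily. Linear interpolation between week points,
#' endpoints preserved.
#'
#' @param sst A tibble with columns `date`, `temp_c` (and optionally
#'   `region`) at a uniform 7-day step.
#' @return A daily `sst_series`.
#' @export
weekly_to_daily <- function(sst) {
  stopifnot(is.data.frame(sst), all(c("date", "temp_c") %in% names(sst)))
  d <- as.Date(sst$date)
  if (nrow(sst) < 2L || any(diff(as.integer(d)) != 7L)) {
    stop("input must have a uniform 7-day spacing", call. = FALSE)
  }
  daily <- seq(min(d), max(d), by = "day")
  temp <- stats::approx(as.numeric(d), sst$temp_c, xout = as.numeric(daily))$y
  region <- if ("region" %in% names(sst)) sst$region[1] else "region-1"
  sst_series(daily, temp, region = region)
}

#' Write a generated dataset to plain-text files
#'
#' Writes the readings/records CSV and the ground-truth record as JSON into a
#' directory, so generated fixtures can be shipped or inspected.
#'
#' @param dataset An `otolith_dataset` or `catch_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(dataset, "otolith_dataset")) {
    readr::write_csv(dataset$readings, file.path(dir, "otolith_readings.csv"),
      progress = FALSE
    )
  } else if (inherits(dataset, "catch_dataset")) {
    readr::write_csv(dataset$records, file.path(dir, "catch_records.csv"),
      progress = FALSE
    )
  } else {
    stop("unknown dataset type", call. = FALSE)
  }
  truth <- dataset$truth
  truth$pop$hyper <- as.list(truth$pop$hyper)
  jsonlite::write_json(
    list(
      pop = unclass(truth$pop), spawn = unclass(truth$spawn),
      individuals = dataset$fish
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
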