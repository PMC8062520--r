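# Independent oracles used across tests.

# Day length via the Spencer (Fourier-series) solar declination -- an
# independent route to the same quantity as the package's solar-position
# calculation (which goes through the sun's apparent ecliptic longitude).
oracle_day_length <- function(latitude, date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g) # radians
  lat_r <- latitude * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat_r) * cos(decl)) -
    tan(lat_r) * tan(decl)
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  2 * acos(cos_ha) * 180 / pi / 15
}

# Brute-force day-by-day summation of daily temperatures.
oracle_cumtemp <- function(sst, birth_date, age_days) {
  total <- 0
  for (k in 0:age_days) {
    total <- total + sst$temp_c[sst$date == as.Date(birth_date) + k]
  }
  total
}

# Small constant-temperature series for unit tests.
const_sst <- function(temp = 25, start = "2003-01-01", n = 400, region = "r") {
  sst_series(as.Date(start) + 0:(n - 1), rep(temp, n), region = region)
}

# Deterministic Mediterranean-like series (no noise) spanning two years.
seasonal_sst <- function(seed = 1, noise = 0) {
  generate_sst(sst_gen_spec(noise_sd_c = noise), seed = seed)
}

# Tiny synthetic fit reused by inference tests (cached per session).
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    sst <- seasonal_sst()
    oto <- generate_otolith_dataset(sst,
      n_fish = 8, days_range = c(50, 80),
      seed = 42
    )
    cd <- generate_catch_dataset(sst, n_fish = 80, seed = 43)
    cfg <- fit_config(
      n_chains = 2, n_iterations = 400, burn_in = 200,
      thinning = 1, seed = 7
    )
    tiny_fit_cache$sst <- sst
    tiny_fit_cache$oto <- oto
    tiny_fit_cache$cd <- cd
    tiny_fit_cache$fit <- fit_integral_model(oto, cd, sst, cfg = cfg)
  }
  tiny_fit_cache
}
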