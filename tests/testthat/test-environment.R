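test_that("SST CSV round-trips and rejects gappy or corrupt files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,temp_c", "2003-06-01,22.0", "2003-06-02,22.5",
    "2003-06-03,23.0"
  ), tmp)
  s <- read_sst_csv(tmp)
  expect_equal(nrow(s), 3)
  expect_equal(s$temp_c, c(22, 22.5, 23))

  # round trip of a generated series preserves temperatures exactly
  gen <- seasonal_sst(seed = 3, noise = 0.4)
  out <- withr::local_tempfile(fileext = ".csv")
  write_sst_csv(gen, out)
  back <- read_sst_csv(out)
  expect_equal(back$temp_c, gen$temp_c, tolerance = 1e-12)
  expect_equal(back$date, gen$date)

  writeLines(c("date,temp_c", "2003-06-01,22.0", "2003-06-03,23.0"), tmp)
  expect_error(read_sst_csv(tmp), "2003-06-02")
  writeLines(c("date,temp_c", "2003-06-01,oops"), tmp)
  expect_error(read_sst_csv(tmp), "[Nn]on-numeric")
})

test_that("scenario transforms are additive, local and identity-preserving", {
  s <- const_sst(25)
  up <- apply_scenario(s, scenario_spec("uniform_offset", offset_c = 3))
  expect_equal(up$temp_c, rep(28, nrow(s)))
  expect_equal(
    apply_scenario(s, scenario_spec("uniform_offset", offset_c = 0))$temp_c,
    s$temp_c
  )
  expect_equal(apply_scenario(s, scenario_spec("baseline"))$temp_c, s$temp_c)

  base <- seasonal_sst(seed = 5)
  hw <- scenario_spec("heatwave",
    hw_start = "2003-07-15", hw_end = "2003-08-18",
    hw_intensity_c = 2.5
  )
  out <- apply_scenario(base, hw)
  inside <- base$date >= as.Date("2003-07-15") & base$date <= as.Date("2003-08-18")
  expect_equal(sum(inside), 35)
  expect_equal(out$temp_c[inside] - base$temp_c[inside], rep(2.5, sum(inside)))
  expect_equal(out$temp_c[!inside], base$temp_c[!inside])
  expect_error(
    apply_scenario(s, scenario_spec("heatwave",
      hw_start = "1990-01-01",
      hw_end = "1990-02-15", hw_intensity_c = 2
    )),
    "outside series span"
  )
})

test_that("cumulative temperature counts the birth day and matches brute force", {
  s <- const_sst(25)
  expect_equal(cumulative_temperature(s, "2003-06-01", 2), 75)
  expect_equal(cumulative_temperature(s, "2003-06-01", 0), 25)

  seas <- seasonal_sst(seed = 9, noise = 0.3)
  expect_equal(
    cumulative_temperature(seas, "2003-06-21", 30),
    oracle_cumtemp(seas, "2003-06-21", 30)
  )
  # one-day increments equal the temperature of the added day
  for (a in c(0, 5, 17)) {
    expect_equal(
      cumulative_temperature(seas, "2003-06-21", a + 1) -
        cumulative_temperature(seas, "2003-06-21", a),
      seas$temp_c[seas$date == as.Date("2003-06-21") + a + 1]
    )
  }
  expect_error(cumulative_temperature(s, "2004-01-30", 20), "last covered date")
})

test_that("photoperiod matches an independent solar-geometry oracle", {
  dates <- as.Date("2003-01-05") + seq(0, 360, by = 15)
  lats <- c(-60, -39.5, -15, 0, 15, 36, 39.5, 60, 66)
  for (lat in lats) {
    got <- photoperiod_hours(geo_point(lat), dates)
    want <- oracle_day_length(lat, dates)
    expect_lt(max(abs(got - want)), 0.2)
  }
  # equatorial day length is ~12.1 h under the refraction convention
  expect_equal(photoperiod_hours(geo_point(0), "2003-03-21"), 12.1, tolerance = 0.2)
  # hemispheric seasonality and polar clamps
  expect_gt(
    photoperiod_hours(geo_point(39.5), "2003-06-21"),
    photoperiod_hours(geo_point(39.5), "2003-12-21")
  )
  expect_equal(photoperiod_hours(geo_point(80), "2003-06-21"), 24)
  expect_equal(photoperiod_hours(geo_point(80), "2003-12-21"), 0)
})

test_that("annual photoperiod integrates to ~12 h/day at any latitude", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  for (lat in c(0, 25, 39.5, 55, 70)) {
    total <- sum(photoperiod_hours(geo_point(lat), dates))
    expect_equal(total, 365 * 12, tolerance = 0.02 * 365 * 12)
  }
})

test_that("conditions at birth compose the series lookup and the photoperiod", {
  s <- const_sst(25)
  cb <- conditions_at_birth(s, geo_point(0), "2003-03-21")
  expect_equal(cb$t_b_c, 25)
  expect_equal(cb$p_b_h, 12.1, tolerance = 0.2)
  expect_error(conditions_at_birth(s, geo_point(0), "1999-01-01"), "span")

  seas <- seasonal_sst(seed = 2)
  cb2 <- conditions_at_birth(seas, geo_point(36), "2003-07-15")
  expect_equal(cb2$t_b_c, seas$temp_c[seas$date == as.Date("2003-07-15")])
  expect_equal(cb2$p_b_h, photoperiod_hours(geo_point(36), "2003-07-15"))
})

test_that("weekly series interpolate linearly to daily", {
  wk <- tibble::tibble(
    date = as.Date("2003-01-01") + seq(0, 28, 7),
    temp_c = rep(20, 5)
  )
  expect_equal(unique(weekly_to_daily(wk)$temp_c), 20)

  ramp <- tibble::tibble(
    date = as.Date("2003-01-01") + c(0, 7),
    temp_c = c(20, 27)
  )
  daily <- weekly_to_daily(ramp)
  expect_equal(daily$temp_c, seq(20, 27, by = 1))
  # resampling at the week points recovers the input
  wk2 <- tibble::tibble(
    date = as.Date("2003-01-01") + seq(0, 35, 7),
    temp_c = c(18, 19.5, 22, 21, 20, 19)
  )
  back <- weekly_to_daily(wk2)
  expect_equal(back$temp_c[back$date %in% wk2$date], wk2$temp_c)
  expect_error(weekly_to_daily(tibble::tibble(
    date = as.Date("2003-01-01") + c(0, 7, 13),
    temp_c = 1:3
  )), "7-day")
})
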