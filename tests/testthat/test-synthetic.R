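test_that("SST generator honours its degenerate and seasonal contracts", {
  flat <- generate_sst(sst_gen_spec(amplitude_c = 0, noise_sd_c = 0, mean_c = 21))
  expect_true(all(flat$temp_c == 21))
  expect_equal(diff(as.integer(range(format(flat$date, "%Y")))), 1)

  med <- generate_sst(sst_gen_spec(noise_sd_c = 0))
  y1 <- med[format(med$date, "%Y") == "2003", ]
  expect_equal(format(y1$date[which.max(y1$temp_c)], "%m"), "08")
  expect_equal(format(y1$date[which.min(y1$temp_c)], "%m"), "02")
  expect_identical(
    generate_sst(sst_gen_spec(), seed = 4)$temp_c,
    generate_sst(sst_gen_spec(), seed = 4)$temp_c
  )
})

test_that("SST noise has the requested lag-1 autocorrelation", {
  spec <- sst_gen_spec(noise_ar = 0.8, noise_sd_c = 0.5, years = 10)
  s <- generate_sst(spec, seed = 77)
  doy <- as.integer(format(s$date, "%j"))
  seasonal <- spec$mean_c +
    spec$amplitude_c * cos(2 * pi * (doy - spec$phase_day) / 365.25)
  noise <- s$temp_c - seasonal
  r1 <- stats::cor(noise[-1], noise[-length(noise)])
  expect_equal(r1, 0.8, tolerance = 0.05)
  expect_equal(stats::sd(noise), 0.5, tolerance = 0.05)
})

test_that("otolith generator reduces to the deterministic trajectory without noise", {
  sst <- seasonal_sst(seed = 1, noise = 0)
  truth <- truth_params(phi = c(0, 0), sigma_oto = 1e-12)
  ds <- generate_otolith_dataset(sst,
    truth = truth, n_fish = 3,
    days_range = c(40, 60), seed = 9
  )
  for (i in 1:3) {
    f <- ds$fish[i, ]
    rd <- ds$readings[ds$readings$fish_id == f$fish_id, ]
    traj <- radius_trajectory(
      individual_params(f$linf0, f$b, f$c), truth$pop,
      sst, f$birth_date, f$age_at_capture
    )
    expect_equal(rd$radius_um, traj$radius_um[-1], tolerance = 1e-6)
  }
})

test_that("otolith generator meets its dataset contract and is seeded", {
  sst <- seasonal_sst(seed = 2)
  ds <- generate_otolith_dataset(sst, n_fish = 20, seed = 31)
  counts <- table(ds$readings$fish_id)
  expect_equal(length(counts), 20)
  expect_true(all(counts >= 60 & counts <= 150))
  expect_gte(length(unique(format(ds$fish$birth_date, "%m"))), 3)
  expect_true(all(ds$readings$age_days >= 1))
  ds2 <- generate_otolith_dataset(sst, n_fish = 20, seed = 31)
  expect_identical(ds$readings, ds2$readings)
  # expected radii increase within each fish (positivity of expected growth)
  noiseless <- generate_otolith_dataset(sst,
    truth = truth_params(phi = c(0, 0), sigma_oto = 1e-9),
    n_fish = 5, seed = 8
  )
  for (id in unique(noiseless$readings$fish_id)) {
    expect_true(all(diff(noiseless$readings$radius_um[
      noiseless$readings$fish_id == id
    ]) > 0))
  }
})

test_that("catch generator carries the environmental signal it is given", {
  sst <- seasonal_sst(seed = 3)
  # no environmental effect: FL/OtR ratio flat across birth months
  t0 <- truth_params(beta_t = 0, beta_p = 0, sigma_len = 0.01)
  d0 <- generate_catch_dataset(sst, truth = t0, n_fish = 300, seed = 41)
  ratio <- d0$records$fl_cm / d0$fish$otr_um
  expect_lt(stats::sd(ratio) / mean(ratio), 0.01)

  # positive photoperiod effect: June-born fish longer than September-born
  # at equal radius and birth temperature
  tp <- truth_params(beta_t = 0, beta_p = 8e-4, sigma_len = 0.01)
  dp <- generate_catch_dataset(sst, truth = tp, n_fish = 600, seed = 42)
  mult <- dp$records$fl_cm / dp$fish$otr_um
  mon <- as.integer(format(dp$fish$birth_date, "%m"))
  if (any(mon == 6) && any(mon == 9)) {
    expect_gt(mean(mult[mon == 6]), mean(mult[mon == 9]))
  }
  expect_identical(
    generate_catch_dataset(sst, n_fish = 50, seed = 5)$records,
    generate_catch_dataset(sst, n_fish = 50, seed = 5)$records
  )
})

test_that("calibration/validation split is disjoint, exhaustive and seeded", {
  sst <- seasonal_sst(seed = 4)
  ds <- generate_catch_dataset(sst, n_fish = 1876, seed = 6)
  sp <- split_calibration_validation(ds$records, n_calibration = 1000, seed = 7)
  expect_equal(nrow(sp$calibration), 1000)
  expect_equal(nrow(sp$validation), 876)
  expect_length(intersect(sp$calibration$fish_id, sp$validation$fish_id), 0)
  expect_setequal(
    c(sp$calibration$fish_id, sp$validation$fish_id),
    ds$records$fish_id
  )
  sp2 <- split_calibration_validation(ds$records, n_calibration = 1000, seed = 7)
  expect_identical(sp$calibration$fish_id, sp2$calibration$fish_id)
})

test_that("generated datasets write readings, records and truth to disk", {
  sst <- seasonal_sst(seed = 5)
  ds <- generate_otolith_dataset(sst, n_fish = 3, days_range = c(40, 50), seed = 1)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "otolith_readings.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$pop$linf_slope, truth_params()$pop$linf_slope)
})
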