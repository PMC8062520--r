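pop0 <- growth_params(
  linf_slope = 0.5, beta0 = 0.01, beta_t = 5e-4, beta_p = 8e-4,
  phi = c(0.5, 0.2), sigma_oto = 1, sigma_len = 1
)

test_that("thermally modulated asymptote is linear in accumulated temperature", {
  ind <- individual_params(800, b = 4, c = 0.04)
  expect_equal(linf_at_age(ind, pop0, 0), 800)
  expect_equal(linf_at_age(ind, pop0, 75), 837.5)
  flat <- growth_params(linf_slope = 0, beta0 = 0.01)
  expect_equal(linf_at_age(ind, flat, c(0, 100, 5000)), rep(800, 3))
  expect_error(linf_at_age(ind, pop0, -1), ">= 0")
})

test_that("Gompertz forms match high-precision evaluation and boundary identities", {
  # age 0: both forms give linf * exp(-b)
  expect_equal(gompertz_radius(1000, 5, 0.05, 0), 1000 * exp(-5))
  expect_equal(gompertz_radius(1000, 5, 0.05, 0, form = "literal"), 1000 * exp(-5))
  # frozen 40-digit reference values for (linf=1000, b=5, c=0.05, age=60)
  expect_equal(gompertz_radius(1000, 5, 0.05, 60), 779.6303812215041,
    tolerance = 1e-12
  )
  expect_equal(gompertz_radius(1000, 5, 0.05, 60, form = "literal"),
    338.4337126978006,
    tolerance = 1e-12
  )
  # b = 1 is a fixed point of the literal power form at every age
  ages <- c(0, 1, 10, 100, 1e4)
  expect_equal(
    gompertz_radius(1000, 1, 0.03, ages, form = "literal"),
    rep(1000 * exp(-1), 5)
  )
  # the classic form approaches its asymptote
  expect_equal(gompertz_radius(1000, 5, 0.05, 1e4), 1000, tolerance = 1e-8)
  expect_error(gompertz_radius(1000, -1, 0.05, 10), "`b` must be > 0")
})

test_that("radius trajectories follow the closed form under constant forcing", {
  s <- const_sst(25)
  ind <- individual_params(500, b = 4, c = 0.045)
  traj <- radius_trajectory(ind, pop0, s, "2003-06-01", 40)
  ages <- 0:40
  linf <- 500 + 0.5 * 25 * (ages + 1) # cumtemp = T * (age + 1)
  expect_equal(traj$cumtemp_cday, 25 * (ages + 1))
  expect_equal(traj$radius_um, linf * exp(-4 * exp(-0.045 * ages)))
  expect_equal(nrow(radius_trajectory(ind, pop0, s, "2003-06-01", 0)), 1)

  # birthdate sensitivity under seasonal forcing
  seas <- seasonal_sst(seed = 3, noise = 0)
  t1 <- radius_trajectory(ind, pop0, seas, "2003-06-01", 60)
  t2 <- radius_trajectory(ind, pop0, seas, "2003-07-01", 60)
  expect_false(isTRUE(all.equal(t1$radius_um, t2$radius_um)))
})

test_that("trajectories increase with age and with uniform warming", {
  set.seed(71)
  s <- const_sst(26)
  hyper <- truth_params()$pop$hyper
  for (k in 1:10) {
    ind <- individual_params(
      rnorm(1, hyper$mu_linf0, hyper$sd_linf0),
      exp(rnorm(1, hyper$mu_logb, hyper$sd_logb)),
      exp(rnorm(1, hyper$mu_logc, hyper$sd_logc))
    )
    traj <- radius_trajectory(ind, truth_params()$pop, s, "2003-06-01", 120)
    expect_true(all(diff(traj$radius_um) > 0))
  }
  # warming monotonicity: +2 degrees raises the radius at every age > 0
  seas <- seasonal_sst(seed = 13, noise = 0)
  warm <- apply_scenario(seas, scenario_spec("uniform_offset", offset_c = 2))
  ind <- individual_params(500, 4, 0.045)
  r0 <- radius_trajectory(ind, truth_params()$pop, seas, "2003-06-15", 90)
  r1 <- radius_trajectory(ind, truth_params()$pop, warm, "2003-06-15", 90)
  expect_true(all(r1$radius_um[-1] > r0$radius_um[-1]))
  # and therefore raises the fish length at fixed positive conversion
  expect_gt(
    fish_length(r1$radius_um[91], 25, 14, truth_params()$pop),
    fish_length(r0$radius_um[91], 25, 14, truth_params()$pop)
  )
})

test_that("lag correction reproduces a hand-rolled loop and its identities", {
  expected <- c(10, 12, 15, 19, 24)
  observed <- c(11, 11, 16, 18, 26)
  phi <- c(0.5, 0.2)
  hand <- expected
  resid <- observed - expected
  for (t in seq_along(expected)) {
    for (k in seq_along(phi)) {
      if (t > k) hand[t] <- hand[t] + phi[k] * resid[t - k]
    }
  }
  expect_equal(ar_corrected_expectation(expected, observed, phi), hand)
  expect_equal(ar_corrected_expectation(expected, observed, c(0, 0)), expected)
  expect_equal(ar_corrected_expectation(expected, expected, phi), expected)
  expect_error(ar_corrected_expectation(1:3, 1:4, phi), "same length")
})

test_that("length conversion is multiplicative in radius and reduces cleanly", {
  pop <- growth_params(
    linf_slope = 0.15, beta0 = 0.01, beta_t = 5e-4,
    beta_p = 8e-4
  )
  expect_equal(fish_length(1200, 25, 14.5, pop), 40.92)
  expect_equal(
    fish_length(2400, 25, 14.5, pop),
    2 * fish_length(1200, 25, 14.5, pop)
  )
  noenv <- growth_params(linf_slope = 0.15, beta0 = 0.02)
  expect_equal(fish_length(1200, 25, 14.5, noenv), 1200 * 0.02)
  expect_equal(fish_length(1200, 5, 10, noenv), fish_length(1200, 30, 16, noenv))
  bad <- growth_params(linf_slope = 0.15, beta0 = -1)
  expect_error(fish_length(1200, 25, 14.5, bad), "non-positive")
  expect_error(fish_length(-5, 25, 14.5, pop), "> 0")
})
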