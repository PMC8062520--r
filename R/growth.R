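#' Individual Gompertz growth parameters
#'
#' Per-fish parameters of the otolith radius-at-age model: the intercept of
#' the (thermally modulated) asymptote, and the Gompertz displacement and
#' rate. Units are fixed package-wide: otolith radius in micrometers, age in
#' days, temperature in degrees Celsius, fish length in centimeters.
#'
#' @param linf0 Asymptote intercept (micrometers).
#' @param b Gompertz displacement (> 0, unitless).
#' @param c Gompertz rate (> 0, 1/day).
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(linf0, b, c) {
  if (!all(is.finite(linf0))) stop("`linf0` must be finite", call. = FALSE)
  if (any(b <= 0)) stop("`b` must be > 0", call. = FALSE)
  if (any(c <= 0)) stop("`c` must be > 0", call. = FALSE)
  structure(list(linf0 = linf0, b = b, c = c), class = "individual_params")
}

#' Population-level growth parameters
#'
#' All shared parameters of the two-stage growth model: the degree-day slope
#' of the otolith asymptote, the otolith-to-length regression coefficients
#' (intercept plus temperature-at-birth and photoperiod-at-birth effects),
#' the lag coefficients of the autocorrelated increment residuals, the two
#' observation-noise scales, and the hyperparameters of the individual-level
#' parameter distributions (normal for `linf0`, log-normal for `b` and `c`).
#'
#' @param linf_slope Asymptote slope (micrometers per degree-day).
#' @param beta0 Length per radius unit (cm/um).
#' @param beta_t Length per radius unit per degree Celsius at birth.
#' @param beta_p Length per radius unit per hour of photoperiod at birth.
#' @param phi Numeric vector of lag coefficients for the residual correction
#'   (may be empty).
#' @param sigma_oto Radius observation-noise scale (um), > 0.
#' @param sigma_len Length observation-noise scale (cm), > 0.
#' @param hyper Named list with `mu_linf0`, `sd_linf0`, `mu_logb`, `sd_logb`,
#'   `mu_logc`, `sd_logc` describing the individual-parameter distributions.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(linf_slope, beta0, beta_t = 0, beta_p = 0,
                          phi = numeric(), sigma_oto = 1, sigma_len = 1,
                          hyper = NULL) {
  if (sigma_oto <= 0 || sigma_len <= 0) {
    stop("noise scales must be > 0", call. = FALSE)
  }
  structure(
    list(
      linf_slope = linf_slope, beta0 = beta0, beta_t = beta_t, beta_p = beta_p,
      phi = as.numeric(phi), n_lags = length(phi),
      sigma_oto = sigma_oto, sigma_len = sigma_len, hyper = hyper
    ),
    class = "growth_params"
  )
}

#' Thermally modulated asymptote
#'
#' The otolith asymptote grows linearly with the temperature accumulated from
#' birth: `linf0 + linf_slope * cumtemp`. This is how each fish's thermal
#' history enters the growth curve.
#'
#' @param ind An [individual_params()].
#' @param pop A [growth_params()].
#' @param cumtemp Accumulated temperature (degree-days), >= 0; vectorised.
#' @return Asymptote in micrometers.
#' @export
linf_at_age <- function(ind, pop, cumtemp) {
  stopifnot(inherits(ind, "individual_params"), inherits(pop, "growth_params"))
  if (any(cumtemp < 0)) stop("`cumtemp` must be >= 0", call. = FALSE)
  ind$linf0 + pop$linf_slope * cumtemp
}

#' Gompertz otolith radius at age
#'
#' Expected otolith radius at `age_days` given the current asymptote. The
#' default `"classic"` form is `linf * exp(-b * exp(-c * age))`, the standard
#' Gompertz curve whose value approaches `linf` at large ages. The
#' `"literal"` form `linf * exp(-(b ^ exp(-c * age)))` raises `b` itself to
#' the decaying power; both forms coincide at age 0 (`linf * exp(-b)`).
#'
#' @param linf Asymptote (micrometers); vectorised.
#' @param b Gompertz displacement, > 0.
#' @param c Gompertz rate (1/day), > 0.
#' @param age_days Age in days, >= 0.
#' @param form `"classic"` (default) or `"literal"`.
#' @return Expected radius in micrometers.
#' @export
#' @examples
#' gompertz_radius(1000, b = 4, c = 0.045, age_days = 0:5)
gompertz_radius <- function(linf, b, c, age_days, form = c("classic", "literal")) {
  form <- match.arg(form)
  if (any(b <= 0)) stop("`b` must be > 0 (power of a non-positive base)", call. = FALSE)
  if (any(c <= 0)) stop("`c` must be > 0", call. = FALSE)
  if (any(age_days < 0)) stop("`age_days` must be >= 0", call. = FALSE)
  decay <- exp(-c * age_days)
  if (form == "classic") {
    linf * exp(-b * decay)
  } else {
    linf * exp(-(b^decay))
  }
}

#' Expected otolith radius trajectory under a thermal history
#'
#' Composes the thermally modulated asymptote with the Gompertz curve for each
#' day of life: on day `a` the asymptote uses the temperature accumulated from
#' the birth day through day `a`, so two fish with identical parameters but
#' different birthdates (or regions) follow different trajectories.
#'
#' @param ind An [individual_params()].
#' @param pop A [growth_params()].
#' @param sst An `sst_series` covering `[birth_date, birth_date + n_days]`.
#' @param birth_date Birth date.
#' @param n_days Last age (days) to evaluate; the trajectory has `n_days + 1`
#'   rows for ages `0..n_days`.
#' @param form Gompertz form, see [gompertz_radius()].
#' @return Tibble with columns `age_days`, `date`, `cumtemp_cday`, `linf_um`,
#'   `radius_um`.
#' @export
radius_trajectory <- function(ind, pop, sst, birth_date, n_days,
                              form = c("classic", "literal")) {
  form <- match.arg(form)
  birth_date <- as.Date(birth_date)
  ages <- 0:n_days
  ct <- cumulative_temperature(sst, birth_date, n_days)
  # per-age cumulative temperatures via one cumsum pass
  i0 <- as.integer(birth_date - sst$date[1]) + 1L
  cs <- cumsum(sst$temp_c)
  ct_age <- cs[i0 + ages] - (if (i0 > 1L) cs[i0 - 1L] else 0)
  linf <- linf_at_age(ind, pop, ct_age)
  tibble::tibble(
    age_days = ages,
    date = birth_date + ages,
    cumtemp_cday = ct_age,
    linf_um = linf,
    radius_um = gompertz_radius(linf, ind$b, ind$c, ages, form = form)
  )
}

#' Lag-corrected expected radii
#'
#' Adds to each expected radius a correction proportional to the residuals
#' (observed minus expected) of the preceding days: `corrected[t] =
#' expected[t] + sum_k phi[k] * (observed[t-k] - expected[t-k])`. Lags that
#' fall before the start of the series contribute zero (no residual history
#' exists before the first increment). This correction defines the
#' observation model during fitting; for the forward simulation of new fish
#' no observations exist and the correction is identically zero.
#'
#' @param expected Expected radii per age (numeric).
#' @param observed Observed radii per age, aligned with `expected`.
#' @param phi Lag coefficients (`phi[1]` applies to lag 1, etc.).
#' @return Corrected expected radii, same length as `expected`.
#' @export
ar_corrected_expectation <- function(expected, observed, phi) {
  if (length(expected) != length(observed)) {
    stop("`expected` and `observed` must have the same length", call. = FALSE)
  }
  resid <- observed - expected
  out <- expected
  n <- length(expected)
  for (k in seq_along(phi)) {
    if (k < n) {
      idx <- (k + 1):n
      out[idx] <- out[idx] + phi[k] * resid[idx - k]
    }
  }
  out
}

#' Fish length at catch from otolith radius and birth conditions
#'
#' The otolith-to-length conversion: `FL = OtR * (beta0 + beta_t * T_b +
#' beta_p * P_b)`, multiplicative in the radius with a birth-condition
#' dependent conversion factor. With `beta_t = beta_p = 0` this reduces to
#' the environment-independent proportional model used as the comparison
#' baseline.
#'
#' @param otr_um Otolith radius at catch (micrometers), > 0; vectorised.
#' @param t_b_c Temperature at birth (degrees Celsius).
#' @param p_b_h Photoperiod at birth (hours).
#' @param pop A [growth_params()] carrying `beta0`, `beta_t`, `beta_p`.
#' @return Furcal length in centimeters.
#' @export
#' @examples
#' pop <- growth_params(
#'   linf_slope = 0.15, beta0 = 0.01,
#'   beta_t = 5e-4, beta_p = 8e-4
#' )
#' fish_length(1200, t_b = 25, p_b = 14.5, pop = pop)
fish_length <- function(otr_um, t_b_c, p_b_h, pop) {
  stopifnot(inherits(pop, "growth_params"))
  if (any(otr_um <= 0)) stop("`otr_um` must be > 0", call. = FALSE)
  fl <- otr_um * (pop$beta0 + pop$beta_t * t_b_c + pop$beta_p * p_b_h)
  if (any(fl <= 0)) {
    stop("non-positive predicted length: regression coefficients and birth ",
      "conditions are inconsistent",
      call. = FALSE
    )
  }
  fl
}
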