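#' Temperature-dependent spawning model parameters
#'
#' Parameters of the spawning-intensity curve that maps daily SST to a
#' relative spawning intensity in `[0, 1]`. The default curve is a logistic
#' in temperature, truncated to zero below `t_threshold_c`, with midpoint
#' halfway between threshold and saturation. Defaults are non-canonical
#' stand-ins tuned to Mediterranean dolphinfish phenology (spawning after the
#' onset of summer stratification, roughly above 24 degrees Celsius); they are
#' configurable per region and the whole curve can be swapped for any
#' user-supplied intensity function in [hatch_date_pdf()].
#'
#' @param t_threshold_c Temperature below which spawning intensity is 0.
#' @param t_saturation_c Temperature of near-maximal intensity.
#' @param steepness_per_c Logistic steepness (1/degree Celsius); > 0.
#' @return An object of class `spawning_params`.
#' @export
spawning_params <- function(t_threshold_c = 24, t_saturation_c = 26.5,
                            steepness_per_c = 1.2) {
  if (steepness_per_c <= 0) stop("`steepness_per_c` must be > 0", call. = FALSE)
  if (t_saturation_c < t_threshold_c) {
    stop("`t_saturation_c` must be >= `t_threshold_c`", call. = FALSE)
  }
  structure(
    list(
      t_threshold_c = t_threshold_c, t_saturation_c = t_saturation_c,
      steepness_per_c = steepness_per_c
    ),
    class = "spawning_params"
  )
}

#' Relative spawning intensity at a temperature
#'
#' Logistic rise from the threshold temperature, saturating towards 1 above
#' the saturation temperature, hard-truncated to 0 at or below the threshold.
#' Non-decreasing in temperature.
#'
#' @param temp_c Temperature(s) in degrees Celsius.
#' @param params A [spawning_params()].
#' @return Intensity in `[0, 1]`, same length as `temp_c`.
#' @export
#' @examples
#' spawning_intensity(c(20, 26.5, 32), spawning_params())
spawning_intensity <- function(temp_c, params = spawning_params()) {
  stopifnot(inherits(params, "spawning_params"))
  if (!all(is.finite(temp_c))) stop("`temp_c` must be finite", call. = FALSE)
  mid <- (params$t_threshold_c + params$t_saturation_c) / 2
  s <- 1 / (1 + exp(-params$steepness_per_c * (temp_c - mid)))
  s[temp_c <= params$t_threshold_c] <- 0
  s
}

#' Hatch-date probability density from a thermal scenario
#'
#' Converts one spawning year of daily SST into a daily probability mass of
#' hatch dates: per-day mass proportional to the spawning intensity at that
#' day's temperature, normalised to sum to one. This distribution initialises
#' the individual-based simulation, so phenological shifts under warming
#' (earlier onset, broader window) propagate into the size structure at catch.
#'
#' @param sst An `sst_series` covering the spawning year.
#' @param params A [spawning_params()], or any function mapping a numeric
#'   temperature vector to non-negative intensities.
#' @param year Calendar year to use; defaults to the first year fully covered
#'   by the series (or the only year present).
#' @return A tibble with columns `date` and `prob` (`prob` sums to 1).
#' @export
hatch_date_pdf <- function(sst, params = spawning_params(), year = NULL) {
  validate_sst(sst)
  yrs <- as.integer(format(sst$date, "%Y"))
  if (is.null(year)) {
    full <- unique(yrs)[vapply(unique(yrs), function(y) {
      sum(yrs == y) >= 365
    }, logical(1))]
    year <- if (length(full)) full[1] else unique(yrs)[1]
  }
  sub <- sst[yrs == year, ]
  if (nrow(sub) == 0L) stop("series does not cover year ", year, call. = FALSE)
  intensity <- if (is.function(params)) {
    params(sub$temp_c)
  } else {
    spawning_intensity(sub$temp_c, params)
  }
  if (any(intensity < 0)) stop("intensity function returned negative values", call. = FALSE)
  total <- sum(intensity)
  if (total <= 0) {
    stop("no spawning window: scenario never crosses the spawning threshold",
      call. = FALSE
    )
  }
  tibble::tibble(date = sub$date, prob = intensity / total)
}

#' Summary statistics of a hatch-date distribution
#'
#' Support length (days with non-zero mass), circular standard deviation of
#' the hatch date (treating day-of-year as an angle, so dispersion is
#' well-defined across year boundaries) and the modal date.
#'
#' @param pdf A hatch-date tibble from [hatch_date_pdf()].
#' @return One-row tibble with `support_days`, `circ_sd_days`, `peak_date`.
#' @export
hatch_pdf_stats <- function(pdf) {
  stopifnot(all(c("date", "prob") %in% names(pdf)))
  doy <- as.integer(format(pdf$date, "%j"))
  ang <- 2 * pi * doy / 365.25
  c_bar <- sum(pdf$prob * cos(ang))
  s_bar <- sum(pdf$prob * sin(ang))
  r <- sqrt(c_bar^2 + s_bar^2)
  circ_sd <- sqrt(-2 * log(pmax(r, .Machine$double.eps))) * 365.25 / (2 * pi)
  tibble::tibble(
    support_days = sum(pdf$prob > 0),
    circ_sd_days = circ_sd,
    peak_date = pdf$date[which.max(pdf$prob)]
  )
}

#' Sample birthdates from a hatch-date distribution
#'
#' @param pdf A hatch-date tibble from [hatch_date_pdf()].
#' @param n Number of birthdates to draw.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A `Date` vector of length `n`.
#' @export
sample_birthdates <- function(pdf, n, seed = NULL) {
  stopifnot(all(c("date", "prob") %in% names(pdf)), n >= 1)
  if (abs(sum(pdf$prob) - 1) > 1e-6 || any(pdf$prob < 0)) {
    stop("`pdf$prob` must be a normalised probability vector", call. = FALSE)
  }
  draw <- function() pdf$date[sample.int(nrow(pdf), n, replace = TRUE, prob = pdf$prob)]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read / write a hatch-date distribution as CSV
#'
#' Columns `date`, `prob`.
#'
#' @param path CSV path.
#' @return For `read_hatch_pdf_csv`, the hatch-date tibble.
#' @export
read_hatch_pdf_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(date = as.Date(.data$date))
  if (abs(sum(out$prob) - 1) > 1e-6) {
    stop("probabilities in ", path, " do not sum to 1", call. = FALSE)
  }
  out
}

#' @rdname read_hatch_pdf_csv
#' @param pdf A hatch-date tibble.
#' @export
write_hatch_pdf_csv <- function(pdf, path) {
  readr::write_csv(dplyr::select(pdf, "date", "prob"), path, progress = FALSE)
  invisible(path)
}
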