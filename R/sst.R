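#' Daily sea-surface temperature series
#'
#' An `sst_series` is a tibble with one row per calendar day and columns
#' `date` (class `Date`, strictly increasing, gapless), `temp_c` (finite,
#' degrees Celsius) and `region` (label). It is the forcing signal for every
#' stage of the pipeline: spawning phenology, degree-day accumulation and the
#' conditions experienced at birth.
#'
#' @param dates Vector coercible to `Date`; daily, gapless, increasing.
#' @param temp_c Numeric vector of daily mean SST in degrees Celsius.
#' @param region Single region label.
#'
#' @return A tibble with columns `region`, `date`, `temp_c`.
#' @export
#' @examples
#' sst_series(as.Date("2003-06-01") + 0:2, c(22, 22.5, 23))
sst_series <- function(dates, temp_c, region = "region-1") {
  dates <- as.Date(dates)
  out <- tibble::tibble(
    region = as.character(region),
    date = dates,
    temp_c = as.numeric(temp_c)
  )
  validate_sst(out)
}

#' Validate an SST series
#'
#' Checks the `sst_series` invariants: one temperature per day, dates strictly
#' increasing with a step of exactly one day, all temperatures finite.
#'
#' @param sst A tibble with columns `date` and `temp_c`.
#' @return The input, invisibly usable, after validation.
#' @export
validate_sst <- function(sst) {
  stopifnot(is.data.frame(sst), all(c("date", "temp_c") %in% names(sst)))
  if (nrow(sst) == 0L) stop("SST series is empty", call. = FALSE)
  if (!inherits(sst$date, "Date")) stop("`date` must be a Date column", call. = FALSE)
  if (anyNA(sst$date)) stop("SST series contains missing dates", call. = FALSE)
  steps <- diff(as.integer(sst$date))
  if (any(steps <= 0)) {
    stop("SST dates must be strictly increasing", call. = FALSE)
  }
  if (any(steps != 1L)) {
    gap_at <- sst$date[which(steps != 1L)[1]] + 1L
    stop("SST series has a gap: missing day ", format(gap_at), call. = FALSE)
  }
  if (!all(is.finite(sst$temp_c))) {
    bad <- which(!is.finite(sst$temp_c))[1]
    stop("Non-finite temperature at row ", bad, " (", format(sst$date[bad]), ")",
      call. = FALSE
    )
  }
  sst
}

#' Read a daily SST series from CSV
#'
#' Expects columns `date` (ISO-8601 `YYYY-MM-DD`) and `temp_c`, with an
#' optional `region` column. Rows are sorted by date and the series must be
#' gapless.
#'
#' @param path Path to a CSV file.
#' @return An `sst_series` tibble.
#' @export
read_sst_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("date", "temp_c") %in% names(raw))) {
    stop("SST CSV must have columns `date` and `temp_c`", call. = FALSE)
  }
  if (!is.numeric(raw$temp_c)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$temp_c))))[1]
    stop("Non-numeric temperature at data row ", bad, call. = FALSE)
  }
  if (anyNA(raw$temp_c)) {
    stop("Non-numeric temperature at data row ", which(is.na(raw$temp_c))[1],
      call. = FALSE
    )
  }
  region <- if ("region" %in% names(raw)) raw$region[1] else "region-1"
  out <- raw |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::arrange(.data$date)
  sst_series(out$date, out$temp_c, region = region)
}

#' Write a daily SST series to CSV
#'
#' @param sst An `sst_series` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sst_csv <- function(sst, path) {
  validate_sst(sst)
  readr::write_csv(dplyr::select(sst, "date", "temp_c", "region"), path, progress = FALSE)
  invisible(path)
}

#' Thermal scenario specification
#'
#' Describes a parametric transform of a baseline SST series: `"baseline"`
#' (identity), `"uniform_offset"` (adds `offset_c` to every day, emulating
#' end-of-century mean warming), `"heatwave"` (adds `hw_intensity_c` only
#' inside `[hw_start, hw_end]`, emulating a month-scale marine heatwave), or
#' `"custom"` (an arbitrary `transform` function of the series).
#'
#' @param kind One of `"baseline"`, `"uniform_offset"`, `"heatwave"`, `"custom"`.
#' @param offset_c Uniform offset in degrees Celsius (for `"uniform_offset"`).
#' @param hw_start,hw_end Heatwave window bounds (inclusive), coercible to `Date`.
#' @param hw_intensity_c Heatwave anomaly in degrees Celsius.
#' @param transform For `"custom"`: function taking and returning an `sst_series`.
#' @param label Scenario label; defaults to a description of the transform.
#'
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("uniform_offset", offset_c = 3)
#' scenario_spec("heatwave",
#'   hw_start = "2003-07-15", hw_end = "2003-08-18",
#'   hw_intensity_c = 2.5
#' )
scenario_spec <- function(kind = c("baseline", "uniform_offset", "heatwave", "custom"),
                          offset_c = 0, hw_start = NULL, hw_end = NULL,
                          hw_intensity_c = 0, transform = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform_offset" && !is.finite(offset_c)) {
    stop("`offset_c` must be finite", call. = FALSE)
  }
  if (kind == "heatwave") {
    if (is.null(hw_start) || is.null(hw_end)) {
      stop("heatwave scenario needs `hw_start` and `hw_end`", call. = FALSE)
    }
    hw_start <- as.Date(hw_start)
    hw_end <- as.Date(hw_end)
    if (hw_end <= hw_start) stop("`hw_end` must be after `hw_start`", call. = FALSE)
    if (!is.finite(hw_intensity_c)) stop("`hw_intensity_c` must be finite", call. = FALSE)
  }
  if (kind == "custom" && !is.function(transform)) {
    stop("custom scenario needs a `transform` function", call. = FALSE)
  }
  if (is.null(label)) {
    label <- switch(kind,
      baseline = "baseline",
      uniform_offset = sprintf("uniform%+g°C", offset_c),
      heatwave = sprintf("heatwave%+g°C", hw_intensity_c),
      custom = "custom"
    )
  }
  structure(
    list(
      kind = kind, offset_c = offset_c, hw_start = hw_start, hw_end = hw_end,
      hw_intensity_c = hw_intensity_c, transform = transform, label = label
    ),
    class = "scenario_spec"
  )
}

#' Apply a thermal scenario to a baseline SST series
#'
#' The transform is additive and local: the output differs from the input by
#' exactly the anomaly pattern the spec describes, and dates are unchanged.
#'
#' @param sst Baseline `sst_series`.
#' @param spec A [scenario_spec()].
#' @return An `sst_series` with the anomaly applied.
#' @export
apply_scenario <- function(sst, spec) {
  validate_sst(sst)
  stopifnot(inherits(spec, "scenario_spec"))
  out <- switch(spec$kind,
    baseline = sst,
    uniform_offset = dplyr::mutate(sst, temp_c = .data$temp_c + spec$offset_c),
    heatwave = {
      if (spec$hw_start < min(sst$date) || spec$hw_end > max(sst$date)) {
        stop("heatwave window [", format(spec$hw_start), ", ", format(spec$hw_end),
          "] outside series span",
          call. = FALSE
        )
      }
      inside <- sst$date >= spec$hw_start & sst$date <= spec$hw_end
      dplyr::mutate(sst, temp_c = .data$temp_c + spec$hw_intensity_c * inside)
    },
    custom = validate_sst(spec$transform(sst))
  )
  validate_sst(out)
}

#' Accumulated temperature from birth to age
#'
#' Sums the daily mean SST experienced by a fish from its birth day through
#' day `age_days` (inclusive of the birth day, so `age_days = 0` returns the
#' temperature of the birth day itself). This is the degree-day forcing that
#' enters the asymptote of the otolith growth model.
#'
#' @param sst An `sst_series` covering `[birth_date, birth_date + age_days]`.
#' @param birth_date Birth date (coercible to `Date`).
#' @param age_days Non-negative integer age in days.
#' @return Accumulated temperature in degree-days (numeric scalar; vectorised
#'   over `age_days`).
#' @export
#' @examples
#' s <- sst_series(as.Date("2003-06-01") + 0:9, rep(25, 10))
#' cumulative_temperature(s, "2003-06-01", 2) # 75
cumulative_temperature <- function(sst, birth_date, age_days) {
  validate_sst(sst)
  birth_date <- as.Date(birth_date)
  if (any(age_days < 0)) stop("`age_days` must be non-negative", call. = FALSE)
  i0 <- as.integer(birth_date - sst$date[1]) + 1L
  i1 <- i0 + as.integer(age_days)
  if (i0 < 1L || any(i1 > nrow(sst))) {
    stop("requested range exceeds SST series; last covered date is ",
      format(sst$date[nrow(sst)]),
      call. = FALSE
    )
  }
  cs <- cumsum(sst$temp_c)
  cs[i1] - (if (i0 > 1L) cs[i0 - 1L] else 0)
}

#' Geographic point
#'
#' @param latitude Decimal degrees in `[-90, 90]`.
#' @param longitude Decimal degrees in `[-180, 180]`.
#' @return An object of class `geo_point`.
#' @export
geo_point <- function(latitude, longitude = 0) {
  if (!is.finite(latitude) || abs(latitude) > 90) {
    stop("`latitude` must be in [-90, 90]", call. = FALSE)
  }
  if (!is.finite(longitude) || abs(longitude) > 180) {
    stop("`longitude` must be in [-180, 180]", call. = FALSE)
  }
  structure(list(latitude = latitude, longitude = longitude), class = "geo_point")
}

#' Default study location (Balearic Islands)
#'
#' @return A `geo_point` in the western Mediterranean.
#' @export
balearic_point <- function() geo_point(39.6, 2.9)

#' Hours of daylight from solar geometry
#'
#' Day length from the NOAA solar-position calculation: solar declination from
#' the sun's apparent ecliptic longitude and corrected obliquity, then the
#' hour angle of sunrise at the standard -0.833 degree solar elevation
#' (accounting for refraction and the solar disc radius). Polar day and night
#' clamp to 24 and 0 hours.
#'
#' @param point A [geo_point()] (longitude does not affect day length).
#' @param date Date (coercible to `Date`); vectorised.
#' @return Hours of daylight in `[0, 24]`.
#' @export
#' @examples
#' photoperiod_hours(geo_point(0), "2003-03-21") # ~12.1
photoperiod_hours <- function(point, date) {
  stopifnot(inherits(point, "geo_point"))
  date <- as.Date(date)
  decl <- solar_declination_deg(date)
  lat_r <- point$latitude * pi / 180
  dec_r <- decl * pi / 180
  # hour angle of sunrise at solar elevation -0.833 deg
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat_r) * cos(dec_r)) -
    tan(lat_r) * tan(dec_r)
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  ha_deg <- acos(cos_ha) * 180 / pi
  2 * ha_deg / 15
}

# Solar declination (degrees) per the NOAA solar calculator, evaluated at
# civil noon UTC of the given date.
solar_declination_deg <- function(date) {
  jd <- as.numeric(date) + 2440587.5 + 0.5 # julian day at 12:00 UTC
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eqc <- sin(m * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * deg2rad) * 0.000289
  true_long <- l0 + eqc
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos(omega * deg2rad)
  asin(sin(obl * deg2rad) * sin(app_long * deg2rad)) / deg2rad
}

#' Temperature and photoperiod at birth
#'
#' Looks up the SST on the birth day and computes the photoperiod at the study
#' location on that day. These two quantities modulate the otolith-to-length
#' conversion for every fish (photoperiod as a proxy for larval feeding time).
#'
#' @param sst An `sst_series` covering `birth_date`.
#' @param point A [geo_point()].
#' @param birth_date Birth date (coercible to `Date`); vectorised.
#' @return A tibble with columns `birth_date`, `t_b_c`, `p_b_h`.
#' @export
conditions_at_birth <- function(sst, point, birth_date) {
  validate_sst(sst)
  birth_date <- as.Date(birth_date)
  idx <- as.integer(birth_date - sst$date[1]) + 1L
  if (any(idx < 1L | idx > nrow(sst))) {
    stop("birth_date outside SST series span", call. = FALSE)
  }
  tibble::tibble(
    birth_date = birth_date,
    t_b_c = sst$temp_c[idx],
    p_b_h = photoperiod_hours(point, birth_date)
  )
}
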