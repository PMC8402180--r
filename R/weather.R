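#' Geometric day length
#'
#' Sunrise-to-sunset duration from solar declination and the sunset hour
#' angle.  Declination follows Cooper's formula
#' \eqn{\delta = 23.44^\circ \sin(2\pi (284 + n)/365)}; no atmospheric
#' refraction or twilight is added, so values are slightly shorter than
#' almanac day lengths.
#'
#' @param latitude Site latitude in decimal degrees, in \[-66, 66\]
#'   (polar day/night geometries are rejected).
#' @param day_of_year Integer day of year in \[1, 366\]. Vectorised.
#' @return Day length in seconds.
#' @examples
#' day_length(43.668, 172) / 3600 # midsummer, ~15.3 h
#' @export
day_length <- function(latitude, day_of_year) {
  if (!is.numeric(latitude) || length(latitude) != 1 || !is.finite(latitude)) {
    stop("`latitude` must be a single finite number.", call. = FALSE)
  }
  if (abs(latitude) > 66) {
    stop("`latitude` must lie in [-66, 66]: polar day/night geometry is not supported.",
         call. = FALSE)
  }
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("`day_of_year` must lie in [1, 366].", call. = FALSE)
  }
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  cos_ws <- -tan(phi) * tan(decl)
  # |lat| <= 66 keeps cos_ws inside (-1, 1); clamp guards rounding
  ws <- acos(pmin(1, pmax(-1, cos_ws)))
  86400 * ws / pi
}

#' Growing degree days (Winkler index)
#'
#' Accumulates daily thermal time above a base temperature over the classic
#' Amerine-Winkler window (1 April to 31 October by default).  Daily mean
#' temperature is (tmin + tmax)/2 and negative daily contributions are
#' clamped to zero.
#'
#' @param weather A weather data frame with columns `date`, `tmin`, `tmax`
#'   (see [generate_weather()] or [read_weather()]).
#' @param base Base temperature in deg C (default 10).
#' @param window_start,window_end Window bounds as month-day strings
#'   ("04-01", "10-31") applied in the year(s) the series covers.
#' @return Accumulated degree days (deg C day) as a single number.
#' @examples
#' w <- tibble::tibble(
#'   date = seq(as.Date("2014-04-01"), by = "day", length.out = 10),
#'   tmin = 15, tmax = 25, radiation = 20
#' )
#' gdd_winkler(w) # 10 days x 10 degC above base
#' @export
gdd_winkler <- function(weather, base = 10,
                        window_start = "04-01", window_end = "10-31") {
  weather <- validate_weather(weather)
  yrs <- unique(format(weather$date, "%Y"))
  in_window <- rep(FALSE, nrow(weather))
  for (y in yrs) {
    lo <- as.Date(paste0(y, "-", window_start))
    hi <- as.Date(paste0(y, "-", window_end))
    in_window <- in_window | (weather$date >= lo & weather$date <= hi)
  }
  if (!any(in_window)) {
    stop("Weather series does not overlap the degree-day window.", call. = FALSE)
  }
  if (!all(in_window)) {
    warning("Weather series clipped to the degree-day window.", call. = FALSE)
  }
  w <- weather[in_window, ]
  tmean <- (w$tmin + w$tmax) / 2
  sum(pmax(0, tmean - base))
}

#' Sub-daily irradiance profile
#'
#' Distributes a daily shortwave total over daylight as a half-sine:
#' \eqn{I(t) = \pi S / (2 DL) \, \sin(\pi t / DL)} for t in (0, DL), zero at
#' night.  The profile integrates back to the daily total, which is the
#' property the daily canopy integral depends on.
#'
#' @param radiation Daily total shortwave radiation, MJ m^-2 day^-1.
#' @param day_length Day length in seconds (> 0).
#' @param n_steps Number of sub-daily steps across daylight (>= 4).
#' @return A tibble with columns `time` (s, midpoints of the daylight
#'   intervals), `irradiance` (W m^-2) and `dt` (s, interval width).
#' @examples
#' prof <- irradiance_profile(20, 50000, 48)
#' sum(prof$irradiance * prof$dt) / 1e6 # recovers ~20 MJ
#' @export
irradiance_profile <- function(radiation, day_length, n_steps = 48L) {
  if (!is.finite(day_length) || day_length <= 0) {
    stop("`day_length` must be a positive number of seconds.", call. = FALSE)
  }
  if (n_steps < 4) stop("`n_steps` must be at least 4.", call. = FALSE)
  if (radiation < 0) stop("`radiation` must be non-negative.", call. = FALSE)
  dt <- day_length / n_steps
  t_mid <- (seq_len(n_steps) - 0.5) * dt
  peak <- pi * radiation * 1e6 / (2 * day_length) # W m^-2
  tibble::tibble(
    time = t_mid,
    irradiance = peak * sin(pi * t_mid / day_length),
    dt = dt
  )
}

#' Read a daily weather table
#'
#' Reads a comma-separated table with header
#' `date,tmin,tmax,radiation[,rainfall]` (ISO-8601 dates) and derives the
#' `day_length` column from `latitude` when absent.
#'
#' @param path Path to the CSV file.
#' @param latitude Site latitude in decimal degrees; required to derive
#'   `day_length` when the file does not provide it.
#' @return A validated weather tibble with a `latitude` attribute.
#' @export
read_weather <- function(path, latitude) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$date <- as.Date(raw$date)
  w <- tibble::as_tibble(raw)
  if (!('day_length' %in% names(w))) {
    doy <- as.integer(format(w$date, "%j"))
    w$day_length <- day_length(latitude, doy)
  }
  w <- validate_weather(w)
  attr(w, "latitude") <- latitude
  w
}

# Shared invariant checks for a weather series; returns the tibble with
# day_length guaranteed present when latitude is attached.
validate_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "radiation")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols) > 0) {
    stop("Weather table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(weather) == 0) stop("Weather table is empty.", call. = FALSE)
  d <- as.numeric(diff(weather$date))
  if (length(d) > 0 && any(d != 1)) {
    stop("Weather dates must be strictly increasing with no gaps.", call. = FALSE)
  }
  if (any(weather$tmin > weather$tmax)) {
    stop("Weather violates tmin <= tmax.", call. = FALSE)
  }
  if (any(weather$radiation < 0)) {
    stop("Weather radiation must be non-negative.", call. = FALSE)
  }
  if ('day_length' %in% names(weather) &&
      any(weather$day_length <= 0 | weather$day_length >= 86400)) {
    stop("Day length must lie strictly between 0 and 86,400 s.", call. = FALSE)
  }
  tibble::as_tibble(weather)
}
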