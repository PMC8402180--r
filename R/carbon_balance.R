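#' Carbon-balance parameters
#'
#' Bundles the two sub-module parameter blocks with the CO2-to-dry-matter
#' conversion factor and the sub-daily integration resolution.
#'
#' @param photo A [photosynthesis_params()] block.
#' @param resp A [respiration_params()] block.
#' @param co2_to_dm Conversion factor, g dry matter per g CO2, in (0, 1\].
#'   Default 30/44 (CH2O equivalence: one carbohydrate unit per CO2).
#' @param n_steps Sub-daily integration steps for photosynthesis.
#' @return A list of class `balance_params`.
#' @export
carbon_params <- function(photo = photosynthesis_params(),
                          resp = respiration_params(),
                          co2_to_dm = 30 / 44, n_steps = 48L) {
  stopifnot(inherits(photo, "photo_params"), inherits(resp, "resp_params"))
  if (co2_to_dm <= 0 || co2_to_dm > 1) {
    stop("`co2_to_dm` must lie in (0, 1] g DM per g CO2.", call. = FALSE)
  }
  structure(
    list(photo = photo, resp = resp, co2_to_dm = co2_to_dm,
         n_steps = as.integer(n_steps)),
    class = "balance_params"
  )
}

#' Convert a CO2 mass to dry matter
#'
#' @param co2 Mass of CO2, g (may be negative: a net daily loss).
#' @param factor Conversion factor, g DM per g CO2, in (0, 1\].
#' @return Dry matter, g, sign-preserving.
#' @export
co2_to_dry_matter <- function(co2, factor = 30 / 44) {
  if (factor <= 0 || factor > 1) {
    stop("`factor` must lie in (0, 1].", call. = FALSE)
  }
  co2 * factor
}

#' Simulate a season's daily carbon balance
#'
#' The daily loop: gross canopy photosynthesis minus organ respiration gives
#' the CO2 balance, converted to dry matter and accumulated from sprouting
#' (DAS 0) to harvest.  Negative daily balances are allowed and accumulate —
#' early-season respiration can exceed photosynthesis.
#'
#' @param weather Daily weather tibble (`date`, `tmin`, `tmax`, `radiation`,
#'   `day_length`; a `das` column is derived from row order if absent, the
#'   first row being DAS 0).
#' @param canopy Daily canopy state from [interpolate_canopy()].
#' @param params A [carbon_params()] block.
#' @return A `vine_sim` tibble with per-day columns `das`, `date`,
#'   `p_gross_vine`, `r_total_vine` (g CO2), `co2_balance` (g CO2),
#'   `dm_daily` and `dm_cumulative` (g dry matter); `params` is attached as
#'   an attribute.
#' @export
simulate_season <- function(weather, canopy, params = carbon_params()) {
  stopifnot(inherits(params, "balance_params"))
  weather <- validate_weather(weather)
  if (!('das' %in% names(weather))) weather$das <- seq_len(nrow(weather)) - 1L
  if (!("day_length" %in% names(weather))) {
    stop("Weather must carry a `day_length` column (see read_weather()).",
         call. = FALSE)
  }
  missing_days <- setdiff(weather$das, canopy$das)
  if (length(missing_days) > 0) {
    stop("Canopy state does not cover weather day(s) DAS ",
         paste(utils::head(missing_days, 10), collapse = ", "),
         if (length(missing_days) > 10) ", ...", call. = FALSE)
  }
  st <- canopy[match(weather$das, canopy$das), ]

  p <- vapply(seq_len(nrow(weather)), function(i) {
    daily_photosynthesis(
      tmin = weather$tmin[i], tmax = weather$tmax[i],
      radiation = weather$radiation[i], day_length = weather$day_length[i],
      light_interception = st$light_interception[i],
      params = params$photo, n_steps = params$n_steps
    )
  }, numeric(1))
  r <- daily_respiration(
    tmin = weather$tmin, tmax = weather$tmax,
    day_length = weather$day_length,
    shoot_surface = st$shoot_surface,
    cluster_weight = st$cluster_weight, clusters = st$clusters,
    leaf_area_increment = st$leaf_area_increment,
    params = params$resp
  )
  balance <- p - r
  dm_daily <- co2_to_dry_matter(balance, params$co2_to_dm)
  out <- tibble::tibble(
    das = weather$das, date = weather$date,
    p_gross_vine = p, r_total_vine = r, co2_balance = balance,
    dm_daily = dm_daily, dm_cumulative = cumsum(dm_daily)
  )
  attr(out, "params") <- params
  class(out) <- c("vine_sim", class(out))
  out
}

#' Calibrate the light-saturated rate against measured dry matter
#'
#' One-dimensional least-squares calibration of a multiplicative factor on
#' `pn_max`: the season is re-simulated for each candidate factor and the
#' sum of squared differences between observed and simulated cumulative dry
#' matter at the observation days is minimised over \[0.1, 10\] by Brent's
#' method (golden-section with parabolic steps).
#'
#' @param weather,canopy,params As for [simulate_season()].
#' @param observed_dm Data frame with columns `das` and `dm` (g per vine),
#'   at least 3 rows, all inside the simulated range.
#' @return A list with `factor` (the fitted multiplier), `sse`, and
#'   `params` (the parameter block with the calibrated `pn_max`).
#' @export
calibrate_scale <- function(weather, canopy, params, observed_dm) {
  observed_dm <- tibble::as_tibble(observed_dm)
  if (nrow(observed_dm) < 3) {
    stop("At least 3 dry-matter observations are required.", call. = FALSE)
  }
  sse_of <- function(f) {
    p2 <- params
    p2$photo$pn_max <- params$photo$pn_max * f
    sim <- simulate_season(weather, canopy, p2)
    idx <- match(observed_dm$das, sim$das)
    if (anyNA(idx)) {
      stop("Dry-matter observations fall outside the simulated DAS range.",
           call. = FALSE)
    }
    sum((observed_dm$dm - sim$dm_cumulative[idx])^2)
  }
  opt <- stats::optimize(sse_of, interval = c(0.1, 10), tol = 1e-6)
  if (!is.finite(opt$objective)) {
    stop("Calibration objective is not finite.", call. = FALSE)
  }
  calibrated <- params
  calibrated$photo$pn_max <- params$photo$pn_max * opt$minimum
  list(factor = opt$minimum, sse = opt$objective, params = calibrated)
}
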