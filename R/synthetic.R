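#' Configuration for the synthetic-season generator
#'
#' Defines one synthetic vineyard season: a temperate site at ~43.7 deg N,
#' sprouting on 1 April, ~165 days to harvest, weekly canopy sampling with
#' shoot trimming at 86 DAS, and two trellis profiles that differ exactly
#' where a vertically-positioned and a high-wire free-falling canopy differ
#' in published trials — leaf-area cap, light-interception cap, lateral
#' share, shoot surface and cluster weight.
#'
#' @param seed Integer seed; a fixed seed makes every generated table
#'   byte-identical across runs.
#' @param profile `"vsp"` (vertical shoot positioning-like) or `"shw"`
#'   (single high wire-like).
#' @param season_length Days from sprouting (DAS 0) to harvest (~165,
#'   April-September).
#' @param latitude Site latitude, decimal degrees.
#' @param sprouting Date of DAS 0.
#' @param temp_amplitude Seasonal semi-amplitude of daily mean temperature,
#'   deg C.
#' @param temp_noise_sd Innovation sd of the AR(1) temperature deviations,
#'   deg C (0 gives a smooth sinusoidal season with a constant diurnal
#'   range).
#' @param dm_noise_frac Multiplicative sd of synthetic dry-matter
#'   observations (default 0.05).
#' @param brix_noise_sd Additive sd of synthetic Brix observations,
#'   degrees Brix (default 0.4).
#' @param true_slope,true_intercept The underlying linear sugar-dry matter
#'   relation the Brix observations are drawn from (degrees Brix per g, and
#'   degrees Brix).  Defaults make the must run from ~16 at veraison to
#'   ~23 at harvest over a default season's dry-matter span.
#' @param veraison_das Onset of ripening; Brix sampling starts here
#'   (default 115, late July for an April sprouting).
#' @return A list of class `synth_config`.
#' @export
synthetic_config <- function(seed = 1L, profile = c("vsp", "shw"),
                             season_length = 165L, latitude = 43.668,
                             sprouting = as.Date("2014-04-01"),
                             temp_amplitude = 8.5, temp_noise_sd = 1.5,
                             dm_noise_frac = 0.05, brix_noise_sd = 0.4,
                             true_slope = 0.019, true_intercept = 2.8,
                             veraison_das = 115L) {
  profile <- match.arg(profile)
  if (dm_noise_frac < 0 || brix_noise_sd < 0 || temp_noise_sd < 0) {
    stop("Noise parameters must be non-negative.", call. = FALSE)
  }
  caps <- switch(profile,
    vsp = list(leaf_cap = 3.56, li_cap = 0.16, lateral_cap = 1.65,
               shoot_cap = 0.155, cluster_wt_cap = 246, clusters = 10.4),
    shw = list(leaf_cap = 4.00, li_cap = 0.18, lateral_cap = 1.18,
               shoot_cap = 0.230, cluster_wt_cap = 300, clusters = 9.8)
  )
  structure(
    c(list(seed = as.integer(seed), profile = profile,
           season_length = as.integer(season_length), latitude = latitude,
           sprouting = sprouting, temp_amplitude = temp_amplitude,
           temp_noise_sd = temp_noise_sd, dm_noise_frac = dm_noise_frac,
           brix_noise_sd = brix_noise_sd, true_slope = true_slope,
           true_intercept = true_intercept,
           veraison_das = as.integer(veraison_das),
           trim_das = 86L),
      caps),
    class = "synth_config"
  )
}

# evaluate expr under a derived seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# FAO-style extraterrestrial radiation, MJ m^-2 day^-1
extraterrestrial_radiation <- function(latitude, day_of_year) {
  phi <- latitude * pi / 180
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + day_of_year) / 365)
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Generate a synthetic daily weather season
#'
#' Daily mean temperature follows a seasonal sinusoid plus AR(1) deviations
#' (lag-1 coefficient 0.7); the diurnal range fluctuates around 11 deg C;
#' radiation is a 0.75 clear-sky fraction of extraterrestrial radiation
#' multiplied by a sampled cloudiness factor in (0.15, 1].  Occasional rain
#' days are included for completeness (the model does not consume rainfall).
#'
#' @param config A [synthetic_config()].
#' @return A weather tibble (`date`, `das`, `tmin`, `tmax`, `radiation`,
#'   `rainfall`, `day_length`) with a `latitude` attribute.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    n <- config$season_length
    das <- seq_len(n) - 1L
    dates <- config$sprouting + das
    doy <- as.integer(format(dates, "%j"))

    tmean_smooth <- 16.5 + config$temp_amplitude * cos(2 * pi * (doy - 201) / 365)
    dev <- stats::filter(stats::rnorm(n, 0, config$temp_noise_sd),
                         filter = 0.7, method = "recursive")
    tmean <- tmean_smooth + as.numeric(dev)
    trange <- pmax(2, 11 + stats::rnorm(n, 0, 0.5 * config$temp_noise_sd))
    ra <- extraterrestrial_radiation(config$latitude, doy)
    cloud <- 0.15 + 0.85 * stats::rbeta(n, 4, 1.4)
    rain <- stats::rbinom(n, 1, 0.22) * stats::rgamma(n, shape = 1.2, scale = 6)

    out <- tibble::tibble(
      date = dates, das = das,
      tmin = tmean - trange / 2, tmax = tmean + trange / 2,
      radiation = 0.75 * ra * cloud,
      rainfall = round(rain, 1),
      day_length = day_length(config$latitude, doy)
    )
    attr(out, "latitude") <- config$latitude
    validate_weather(out)
  })
}

#' Generate weekly synthetic canopy observations
#'
#' Leaf area, lateral leaf area and shoot surface follow logistic growth;
#' main leaf area and shoot surface flatten after shoot trimming at 86 DAS.
#' Light interception is proportional to main leaf area, capped at the
#' profile's maximum; cluster fresh weight follows a double sigmoid (two
#' berry growth phases separated by a lag) from ~30 DAS; clusters per vine
#' is constant.  One multiplicative vine-to-vine factor per variable
#' (sd 2%) keeps trajectories monotone while making seasons differ.
#'
#' @param config A [synthetic_config()].
#' @return A tibble of weekly canopy observations (columns as required by
#'   [interpolate_canopy()]).
#' @export
generate_canopy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed + 1L, {
    das <- seq(7, config$season_length - 1, by = 7)
    trim <- config$trim_das
    logi <- function(d, mid, rate) 1 / (1 + exp(-(d - mid) / rate))
    # trimming freezes further main-canopy expansion
    d_main <- pmin(das, trim)

    fac <- exp(stats::rnorm(4, 0, 0.02)) # leaf, lateral, shoot, cluster wt
    leaf <- config$leaf_cap * logi(d_main, 45, 10) * fac[1]
    lateral <- config$lateral_cap * logi(das, 60, 14) * fac[2]
    shoot <- config$shoot_cap * logi(d_main, 45, 10) * fac[3]
    cw_shape <- 0.55 * logi(das, 70, 8) + 0.45 * logi(das, 125, 7)
    cluster_wt <- ifelse(das < 30, 0, config$cluster_wt_cap * cw_shape * fac[4])
    li <- pmin(config$li_cap, config$li_cap * leaf / config$leaf_cap)

    tibble::tibble(
      das = das,
      shoot_surface = shoot,
      leaf_area = leaf,
      lateral_leaf_area = lateral,
      cluster_weight = cluster_wt,
      clusters = config$clusters,
      light_interception = li
    )
  })
}

#' Generate synthetic dry-matter and Brix observations
#'
#' Runs the carbon-balance model on the supplied weather and canopy, then
#' samples it: cumulative dry matter at ~8 dates across the season with
#' multiplicative Gaussian noise, and degrees Brix at ~10 post-veraison
#' dates from the configured true linear sugar-dry matter relation with
#' additive Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @param weather,canopy Daily weather and canopy state covering the season.
#' @param params A [carbon_params()] block.
#' @return A list with `dm_obs` (tibble `das`, `dm`), `brix_obs` (tibble
#'   `das`, `brix`) and the underlying `sim` (`vine_sim` tibble).
#' @export
generate_observations <- function(config, weather, canopy,
                                  params = carbon_params()) {
  stopifnot(inherits(config, "synth_config"))
  sim <- simulate_season(weather, canopy, params)
  with_local_seed(config$seed + 2L, {
    last <- max(sim$das)
    dm_das <- unique(round(seq(30, last, length.out = 8)))
    brix_das <- unique(round(seq(config$veraison_das, last, length.out = 10)))
    dm_true <- sim$dm_cumulative[match(dm_das, sim$das)]
    brix_dm <- sim$dm_cumulative[match(brix_das, sim$das)]
    dm_obs <- tibble::tibble(
      das = dm_das,
      dm = dm_true * (1 + stats::rnorm(length(dm_das), 0, config$dm_noise_frac))
    )
    brix_obs <- tibble::tibble(
      das = brix_das,
      brix = pmin(35, pmax(0, config$true_intercept +
                             config$true_slope * brix_dm +
                             stats::rnorm(length(brix_das), 0, config$brix_noise_sd)))
    )
    list(dm_obs = dm_obs, brix_obs = brix_obs, sim = sim)
  })
}

#' Generate a complete synthetic season
#'
#' Convenience wrapper: weather, weekly canopy observations, daily canopy
#' state, the carbon-balance simulation, and dry-matter and Brix
#' observations, all from one seeded configuration.
#'
#' @param config A [synthetic_config()].
#' @param params A [carbon_params()] block.
#' @return A list with elements `config`, `weather`, `canopy_obs`,
#'   `canopy`, `sim`, `dm_obs`, `brix_obs`.
#' @export
generate_season <- function(config = synthetic_config(),
                            params = carbon_params()) {
  weather <- generate_weather(config)
  canopy_obs <- generate_canopy(config)
  canopy <- interpolate_canopy(canopy_obs,
                               das_range = c(0L, config$season_length - 1L))
  obs <- generate_observations(config, weather, canopy, params)
  list(config = config, weather = weather, canopy_obs = canopy_obs,
       canopy = canopy, sim = obs$sim, dm_obs = obs$dm_obs,
       brix_obs = obs$brix_obs)
}
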