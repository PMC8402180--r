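# Independent numerical oracles, kept deliberately brute-force and separate
# from the implementation paths they check.

# Layered canopy: attenuate irradiance through n thin leaf layers by
# Beer-Lambert and sum the rectangular-hyperbola leaf response of each.
oracle_canopy_layers <- function(irradiance, alpha, pn_max, k, lai,
                                 n_layers = 1000) {
  a <- alpha * 1e-6
  dl <- lai / n_layers
  depth <- (seq_len(n_layers) - 0.5) * dl
  i_leaf <- k * irradiance * exp(-k * depth)
  p_leaf <- a * i_leaf * pn_max / (a * i_leaf + pn_max)
  sum(p_leaf * dl)
}

# Fine-time-step reference for the daily photosynthesis integral.
oracle_daily_photo <- function(tmin, tmax, radiation, day_length, li,
                               params, dt = 10) {
  tt <- seq(dt / 2, day_length - dt / 2, by = dt)
  peak <- pi * radiation * 1e6 / (2 * day_length)
  irr <- peak * sin(pi * tt / day_length)
  lai <- -log(1 - li) / params$k
  pc <- vapply(irr, oracle_canopy_layers, numeric(1),
               alpha = params$quantum_yield, pn_max = params$pn_max,
               k = params$k, lai = lai, n_layers = 200)
  tf_ref <- local({
    tm <- (tmin + tmax) / 2
    if (tm <= params$t_base || tm >= params$t_ceiling) 0
    else if (tm <= params$t_opt) {
      1 - ((tm - params$t_opt) / (params$t_opt - params$t_base))^2
    } else 1 - ((tm - params$t_opt) / (params$t_ceiling - params$t_opt))^2
  })
  params$ground_area * tf_ref * sum(pc * dt)
}

# Closed-form OLS normal equations for a simple regression.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# A tiny fixed canopy-observation table used across tests.
toy_canopy_obs <- function() {
  tibble::tibble(
    das = c(10, 30, 60, 100),
    shoot_surface = c(0.02, 0.08, 0.15, 0.155),
    leaf_area = c(0.4, 1.5, 3.0, 3.4),
    lateral_leaf_area = c(0.05, 0.4, 1.0, 1.3),
    cluster_weight = c(0, 20, 120, 240),
    clusters = 10,
    light_interception = c(0.02, 0.07, 0.14, 0.16)
  )
}

# A short smooth weather table covering a given number of days.
toy_weather <- function(n = 30, start = as.Date("2014-05-01"),
                        tmin = 12, tmax = 26, radiation = 22,
                        latitude = 43.668) {
  dates <- start + seq_len(n) - 1
  doy <- as.integer(format(dates, "%j"))
  tibble::tibble(
    date = dates, das = seq_len(n) - 1L,
    tmin = tmin, tmax = tmax, radiation = radiation,
    day_length = day_length(latitude, doy)
  )
}
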