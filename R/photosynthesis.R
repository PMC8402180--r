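#' Photosynthesis parameters
#'
#' Parameter block for the canopy photosynthesis sub-module.  Units follow
#' the model's mass-based convention: leaf light-saturated rate in
#' g CO2 m^-2 s^-1 and quantum yield in micrograms of CO2 fixed per joule
#' of intercepted shortwave energy.
#'
#' @param pn_max Light-saturated leaf photosynthesis, g CO2 m^-2 s^-1
#'   (in \[0, 0.005\]; vineyard leaves sit near 1e-3).
#' @param quantum_yield Initial slope of the light response, ug CO2 J^-1
#'   (in (0, 10\]).
#' @param k Beer-Lambert light-extinction coefficient (in (0, 1\]).
#' @param ground_area Ground area allotted per vine, m^2.
#' @param t_base,t_opt,t_ceiling Temperature-response anchors, deg C
#'   (must be strictly ordered).  Defaults 10, 27.5, 45.
#' @return A list of class `photo_params`.
#' @export
photosynthesis_params <- function(pn_max = 1e-3, quantum_yield = 2.0,
                                  k = 0.55, ground_area = 3.6,
                                  t_base = 10, t_opt = 27.5, t_ceiling = 45) {
  if (pn_max < 0 || pn_max > 0.005) {
    stop("`pn_max` must lie in [0, 0.005] g CO2 m^-2 s^-1.", call. = FALSE)
  }
  if (quantum_yield <= 0 || quantum_yield > 10) {
    stop("`quantum_yield` must lie in (0, 10] ug CO2 J^-1.", call. = FALSE)
  }
  if (k <= 0 || k > 1) stop("`k` must lie in (0, 1].", call. = FALSE)
  if (ground_area <= 0) stop("`ground_area` must be positive.", call. = FALSE)
  if (!(t_base < t_opt && t_opt < t_ceiling)) {
    stop("Temperature anchors must satisfy t_base < t_opt < t_ceiling.",
         call. = FALSE)
  }
  structure(
    list(pn_max = pn_max, quantum_yield = quantum_yield, k = k,
         ground_area = ground_area, t_base = t_base, t_opt = t_opt,
         t_ceiling = t_ceiling),
    class = "photo_params"
  )
}

#' Leaf-level light response
#'
#' Rectangular hyperbola
#' \eqn{P = \alpha' I P_{max} / (\alpha' I + P_{max})} with
#' \eqn{\alpha'} the quantum yield converted to g CO2 J^-1.  Saturates below
#' `pn_max`; the initial slope is the quantum yield.
#'
#' @param irradiance Irradiance on the leaf, W m^-2. Vectorised.
#' @param alpha Quantum yield, ug CO2 J^-1.
#' @param pn_max Light-saturated rate, g CO2 m^-2 s^-1.
#' @return Leaf photosynthesis, g CO2 m^-2 s^-1.
#' @export
leaf_light_response <- function(irradiance, alpha, pn_max) {
  if (any(irradiance < 0) || alpha < 0 || pn_max < 0) {
    stop("Inputs to the light response must be non-negative.", call. = FALSE)
  }
  a <- alpha * 1e-6 # g CO2 J^-1
  num <- a * irradiance * pn_max
  den <- a * irradiance + pn_max
  ifelse(den > 0, num / den, 0)
}

#' Instantaneous canopy photosynthesis per unit ground area
#'
#' Analytic canopy integral of the rectangular-hyperbola leaf response under
#' Beer-Lambert attenuation.  Measured light interception LI is honoured as
#' data and inverted to an effective leaf-area index
#' \eqn{L = -\ln(1 - LI)/K}; the extinction coefficient K then shapes the
#' within-canopy light profile \eqn{I_l = K I e^{-K l}}, giving
#' \deqn{P_c = (P_{max}/K)\,\ln\!\frac{\alpha' K I + P_{max}}
#'   {\alpha' K I e^{-K L} + P_{max}}.}
#' The result is bounded by the big-leaf limit \eqn{P_{max} L}.
#'
#' @param irradiance Above-canopy irradiance, W m^-2. Vectorised.
#' @param params A [photosynthesis_params()] block.
#' @param light_interception Fraction of light intercepted by the canopy,
#'   in \[0, 1).
#' @return Canopy photosynthesis, g CO2 m^-2 ground s^-1.
#' @export
canopy_instantaneous <- function(irradiance, params, light_interception) {
  stopifnot(inherits(params, "photo_params"))
  if (light_interception < 0 || light_interception >= 1) {
    stop("`light_interception` must lie in [0, 1): LI = 1 implies an infinite canopy.",
         call. = FALSE)
  }
  if (any(irradiance < 0)) stop("`irradiance` must be non-negative.", call. = FALSE)
  k <- params$k
  pmax_ <- params$pn_max
  a <- params$quantum_yield * 1e-6
  lai <- -log(1 - light_interception) / k
  if (lai == 0 || pmax_ == 0) return(rep(0, length(irradiance)))
  x <- a * k * irradiance
  (pmax_ / k) * log((x + pmax_) / (x * exp(-k * lai) + pmax_))
}

#' Temperature factor for daily photosynthesis
#'
#' Piecewise-quadratic response on the daily mean temperature: 0 at or below
#' `t_base`, rising to 1 at `t_opt`, falling back to 0 at `t_ceiling`;
#' continuous everywhere.
#'
#' @param tmean Daily mean temperature, deg C. Vectorised.
#' @param params A [photosynthesis_params()] block (for the anchors).
#' @return Dimensionless factor in \[0, 1\].
#' @export
temperature_factor <- function(tmean, params) {
  stopifnot(inherits(params, "photo_params"))
  tb <- params$t_base; to <- params$t_opt; tc <- params$t_ceiling
  f <- ifelse(
    tmean <= tb | tmean >= tc, 0,
    ifelse(tmean <= to,
           1 - ((tmean - to) / (to - tb))^2,
           1 - ((tmean - to) / (tc - to))^2)
  )
  pmin(1, pmax(0, f))
}

#' Daily gross photosynthesis per vine
#'
#' Integrates the instantaneous canopy rate over the half-sine irradiance
#' profile of one day, scales by the ground area allotted to the vine and
#' by the daily-mean-temperature factor.
#'
#' @param tmin,tmax Daily temperature extremes, deg C.
#' @param radiation Daily shortwave total, MJ m^-2 day^-1.
#' @param day_length Day length, s.
#' @param light_interception Canopy light-interception fraction that day.
#' @param params A [photosynthesis_params()] block.
#' @param n_steps Sub-daily integration steps (default 48).
#' @return Gross photosynthesis, g CO2 vine^-1 day^-1.
#' @export
daily_photosynthesis <- function(tmin, tmax, radiation, day_length,
                                 light_interception, params, n_steps = 48L) {
  stopifnot(inherits(params, "photo_params"))
  if (radiation == 0 || light_interception == 0) return(0)
  prof <- irradiance_profile(radiation, day_length, n_steps)
  pc <- canopy_instantaneous(prof$irradiance, params, light_interception)
  tf <- temperature_factor((tmin + tmax) / 2, params)
  params$ground_area * tf * sum(pc * prof$dt)
}
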