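#' Respiration parameters
#'
#' Parameter block for the organ respiration sub-module.  Shoot and cluster
#' terms are maintenance respiration, referenced to 20 deg C and scaled by an
#' Arrhenius temperature response; the new-leaf-area term is growth
#' respiration, proportional to the daily leaf-area increment and
#' temperature-independent per unit of new tissue.
#'
#' @param r20_shoot Shoot maintenance rate at 20 deg C,
#'   g CO2 m^-2 (shoot surface) day^-1.
#' @param r20_cluster Cluster maintenance rate at 20 deg C,
#'   g CO2 g^-1 fresh weight day^-1.
#' @param growth_coeff Growth respiration, g CO2 per m^2 of new leaf area.
#' @param ea Activation energy, J mol^-1.  The default 51,200 gives a
#'   Q10 of 2 over 20-30 deg C.
#' @param t_ref Reference temperature, K (20 deg C).
#' @return A list of class `resp_params`.
#' @export
respiration_params <- function(r20_shoot = 1.0, r20_cluster = 1e-3,
                               growth_coeff = 5.0, ea = 51200,
                               t_ref = 293.15) {
  if (r20_shoot < 0 || r20_cluster < 0 || growth_coeff < 0 || ea < 0) {
    stop("Respiration rates and activation energy must be non-negative.",
         call. = FALSE)
  }
  structure(
    list(r20_shoot = r20_shoot, r20_cluster = r20_cluster,
         growth_coeff = growth_coeff, ea = ea, t_ref = t_ref),
    class = "resp_params"
  )
}

#' Arrhenius temperature factor
#'
#' \eqn{\exp[(E_a/R)(1/T_{ref} - 1/T)]} with R = 8.314 J mol^-1 K^-1;
#' equals 1 at the reference temperature.
#'
#' @param t Temperature, deg C (> -273.15). Vectorised.
#' @param ea Activation energy, J mol^-1.
#' @param t_ref Reference temperature, K.
#' @return Dimensionless rate multiplier.
#' @examples
#' arrhenius_factor(30, 51200) / arrhenius_factor(20, 51200) # Q10 ~ 2
#' @export
arrhenius_factor <- function(t, ea = 51200, t_ref = 293.15) {
  if (any(t <= -273.15)) stop("Temperature below absolute zero.", call. = FALSE)
  tk <- t + 273.15
  exp((ea / 8.314) * (1 / t_ref - 1 / tk))
}

#' Daily total respiration per vine
#'
#' Maintenance respiration of shoot and clusters is weighted between a
#' day-time temperature (tmax + tmean)/2 and a night-time temperature
#' (tmin + tmean)/2 by the day-length fraction of the 24 h cycle, each
#' through the Arrhenius factor; growth respiration adds
#' `growth_coeff` x the daily leaf-area increment.
#'
#' @param tmin,tmax Daily temperature extremes, deg C.
#' @param day_length Day length, s.
#' @param shoot_surface Shoot surface, m^2 per vine.
#' @param cluster_weight Fresh weight per cluster, g.
#' @param clusters Clusters per vine (may be fractional: block mean).
#' @param leaf_area_increment New main leaf area that day, m^2.
#' @param params A [respiration_params()] block.
#' @return Respiration, g CO2 vine^-1 day^-1.
#' @export
daily_respiration <- function(tmin, tmax, day_length, shoot_surface,
                              cluster_weight, clusters, leaf_area_increment,
                              params) {
  stopifnot(inherits(params, "resp_params"))
  tmean <- (tmin + tmax) / 2
  t_day <- (tmax + tmean) / 2
  t_night <- (tmin + tmean) / 2
  fday <- day_length / 86400
  w <- fday * arrhenius_factor(t_day, params$ea, params$t_ref) +
    (1 - fday) * arrhenius_factor(t_night, params$ea, params$t_ref)
  maint <- params$r20_shoot * shoot_surface +
    params$r20_cluster * cluster_weight * clusters
  maint * w + params$growth_coeff * leaf_area_increment
}
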