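#' Interpolate weekly canopy observations to a daily state
#'
#' Vine-description measurements are taken roughly weekly; the carbon-balance
#' model runs daily.  Continuous quantities (surfaces, leaf areas, cluster
#' weight, light interception) are interpolated piecewise-linearly between
#' observations; before the first observation they ramp linearly from zero at
#' DAS 0, and after the last they are held constant.  Cluster count is held
#' piecewise-constant at the nearest prior observation (counts do not
#' interpolate physically).  The daily increment of main leaf area (clamped
#' at zero) is appended as `leaf_area_increment`.
#'
#' @param observations Data frame with columns `das`, `shoot_surface`,
#'   `leaf_area`, `lateral_leaf_area`, `cluster_weight`, `clusters`,
#'   `light_interception` (strictly increasing `das`, at least 2 rows).
#' @param das_range Integer vector `c(first, last)` DAS to cover;
#'   defaults to 0 through the last observation.
#' @return A tibble with one row per DAS in the range, the interpolated
#'   columns above, and `leaf_area_increment` (m^2 day^-1).
#' @examples
#' obs <- tibble::tibble(
#'   das = c(20, 30), shoot_surface = c(0.05, 0.1),
#'   leaf_area = c(0.5, 1), lateral_leaf_area = c(0.1, 0.3),
#'   cluster_weight = c(0, 50), clusters = 10, light_interception = c(0.04, 0.08)
#' )
#' interpolate_canopy(obs)[26, ] # DAS 25: leaf_area 0.75
#' @export
interpolate_canopy <- function(observations, das_range = NULL) {
  obs <- tibble::as_tibble(observations)
  need <- c("das", "shoot_surface", "leaf_area", "lateral_leaf_area",
            "cluster_weight", "clusters", "light_interception")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols) > 0) {
    stop("Canopy observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(obs) < 2) stop("At least 2 canopy observations are required.", call. = FALSE)
  if (any(diff(obs$das) <= 0)) {
    stop("Canopy observation `das` must be strictly increasing (no duplicates).",
         call. = FALSE)
  }
  linear_cols <- setdiff(need, c("das", "clusters"))
  if (any(as.matrix(obs[linear_cols]) < 0)) {
    stop("Canopy sizes must be non-negative.", call. = FALSE)
  }
  if (any(obs$light_interception > 1)) {
    stop("`light_interception` must lie in [0, 1].", call. = FALSE)
  }
  if (is.null(das_range)) das_range <- c(0L, max(obs$das))
  das <- seq(das_range[1], das_range[2])

  # anchor a ramp from zero at DAS 0 unless an observation sits at/before it
  interp_one <- function(values) {
    x <- obs$das; y <- values
    if (min(x) > 0) { x <- c(0, x); y <- c(0, y) }
    stats::approx(x, y, xout = das, rule = 2)$y
  }
  out <- tibble::tibble(das = das)
  for (col in linear_cols) out[[col]] <- interp_one(obs[[col]])
  # stepwise: value of the nearest prior observation (first obs before it)
  step_idx <- findInterval(das, obs$das)
  out$clusters <- obs$clusters[pmax(1L, step_idx)]
  out$leaf_area_increment <- pmax(0, c(0, diff(out$leaf_area)))
  class(out) <- c("canopy_state", class(out))
  out
}

#' Daily leaf-area increment
#'
#' First difference of the daily main leaf-area series, clamped at zero
#' (leaf loss does not count as negative growth).  Already included in
#' [interpolate_canopy()] output; exposed for use on external daily series.
#'
#' @param leaf_area Numeric daily leaf-area series (m^2).
#' @return Numeric series of the same length, m^2 day^-1, first value 0.
#' @export
leaf_area_increment <- function(leaf_area) {
  if (length(leaf_area) == 0) return(numeric(0))
  pmax(0, c(0, diff(leaf_area)))
}

#' Allometric total leaf area from main-vein lengths
#'
#' Estimates whole-vine leaf area from leaf main-vein lengths via the
#' quadratic allometry \eqn{A = \sum c L_i^2} with a user-supplied,
#' cultivar-calibrated coefficient (cm^2 of blade per cm^2 of squared vein
#' length).  The coefficient is a required calibration input: no universal
#' default exists.
#'
#' @param main_vein_lengths Numeric vector of vein lengths, cm (>= 0).
#' @param coefficient Allometric coefficient, cm^2 cm^-2 (> 0).
#' @return Total leaf area in m^2.
#' @examples
#' estimate_total_leaf_area(c(10, 10), coefficient = 2) # 0.04 m^2
#' @export
estimate_total_leaf_area <- function(main_vein_lengths, coefficient) {
  if (!is.numeric(coefficient) || coefficient <= 0) {
    stop("`coefficient` must be a positive number.", call. = FALSE)
  }
  if (any(main_vein_lengths < 0)) {
    stop("Vein lengths must be non-negative.", call. = FALSE)
  }
  sum(coefficient * main_vein_lengths^2) / 1e4
}

#' Read a weekly vine-description table
#'
#' Comma-separated, header
#' `das,shoot_surface,leaf_area,lateral_leaf_area,cluster_weight,clusters,light_interception[,shoot_length]`,
#' one file per trellis system and season.
#'
#' @param path Path to the CSV file.
#' @return A tibble of canopy observations ordered by `das`.
#' @export
read_canopy <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
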