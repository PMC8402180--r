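#' Plot a seasonal carbon-balance simulation
#'
#' Cumulative dry matter over the season, with the daily gross
#' photosynthesis and respiration fluxes in a lower panel-style overlay.
#'
#' @param object A `vine_sim` tibble from [simulate_season()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vine_sim
#' @export
autoplot.vine_sim <- function(object, ...) {
  fluxes <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "das", "p_gross_vine",
                  "r_total_vine"),
    cols = -"das", names_to = "flux", values_to = "g_co2"
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$das)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dm_cumulative),
                       linewidth = 0.8) +
    ggplot2::geom_line(
      data = fluxes,
      ggplot2::aes(y = .data$g_co2 * 10, colour = .data$flux),
      alpha = 0.6
    ) +
    ggplot2::scale_y_continuous(
      name = "Cumulative dry matter (g/vine)",
      sec.axis = ggplot2::sec_axis(~ . / 10, name = "Daily flux (g CO2/vine)")
    ) +
    ggplot2::labs(x = "Days after sprouting", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sugar-dry matter regression
#'
#' Observed degrees Brix against simulated cumulative dry matter with the
#' fitted line and its equation.
#'
#' @param object A `brix_fit` from [fit_brix_dm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brix_fit
#' @export
autoplot.brix_fit <- function(object, ...) {
  eq <- sprintf("Brix = %.2f + %.4f DM   R2 = %.3f",
                object$intercept, object$slope, object$r2)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dm, y = .data$brix)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(x = "Estimated dry matter (g/vine)",
                  y = "Sugar content (°Brix)", subtitle = eq) +
    ggplot2::theme_minimal()
}

#' Plot cluster-number sugar scenarios
#'
#' Predicted Brix trajectories for each cluster-count scenario; the
#' baseline (observed cluster load) is drawn dashed.
#'
#' @param object A `brix_scenarios` tibble from [run_cluster_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brix_scenarios
#' @export
autoplot.brix_scenarios <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    scenario = ifelse(is.na(.data$clusters), "baseline",
                      paste(.data$clusters, "clusters"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$das, y = .data$brix,
                                   colour = .data$scenario,
                                   linetype = is.na(.data$clusters))) +
    ggplot2::geom_line() +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "Days after sprouting",
                  y = "Predicted sugar content (°Brix)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
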