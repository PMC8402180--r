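#' Mean cluster weight of a vine
#'
#' Yield divided by cluster number on a per-vine basis, in grams.
#'
#' @param yield Yield per vine, kg.
#' @param cluster_count Clusters per vine (> 0; may be fractional when the
#'   input is a block mean). Vectorised.
#' @return Cluster weight, g.
#' @export
cluster_weight <- function(yield, cluster_count) {
  if (any(yield < 0)) stop("`yield` must be non-negative.", call. = FALSE)
  if (any(cluster_count <= 0)) {
    stop("`cluster_count` must be positive.", call. = FALSE)
  }
  1000 * yield / cluster_count
}

#' Ravaz index
#'
#' Yield-to-pruning-weight ratio, the classic crop-load balance indicator;
#' values around 5-10 indicate balanced vines.
#'
#' @param yield Yield per vine, kg.
#' @param pruning_weight Winter pruning weight, kg (> 0). Vectorised.
#' @return Dimensionless ratio.
#' @export
ravaz_index <- function(yield, pruning_weight) {
  if (any(yield < 0)) stop("`yield` must be non-negative.", call. = FALSE)
  if (any(is.na(pruning_weight)) || any(pruning_weight <= 0)) {
    stop("`pruning_weight` must be present and positive.", call. = FALSE)
  }
  yield / pruning_weight
}

#' Signed percent difference between treatment means
#'
#' \eqn{100 (treatment - reference)/reference}.
#'
#' @param treatment_mean,reference_mean Means to compare; the reference must
#'   be non-zero. Vectorised.
#' @return Percent difference, signed.
#' @examples
#' percent_difference(2.89, 2.63) # +9.9%
#' @export
percent_difference <- function(treatment_mean, reference_mean) {
  if (any(reference_mean == 0)) {
    stop("`reference_mean` must be non-zero.", call. = FALSE)
  }
  100 * (treatment_mean - reference_mean) / reference_mean
}

#' Summarise per-vine yield records by treatment
#'
#' Computes cluster weight and Ravaz index per vine, then averages within
#' treatment groups.  Per-vine ratios are averaged (rather than ratios of
#' group means) because ratio-of-means and mean-of-ratios differ whenever
#' vines vary; set `from_means = TRUE` to get the ratio-of-means variant.
#'
#' @param records Data frame with columns `vine`, `yield` (kg), `clusters`,
#'   optionally `pruning_weight` (kg) and a grouping column `treatment`.
#' @param from_means Compute ratios from group means instead of averaging
#'   per-vine ratios (default FALSE).
#' @return A tibble with one row per treatment: mean yield, mean cluster
#'   count, cluster weight (g) and Ravaz index (when pruning weights are
#'   present).
#' @export
vine_yield_summary <- function(records, from_means = FALSE) {
  records <- tibble::as_tibble(records)
  if (!('treatment' %in% names(records))) records$treatment <- "all"
  has_pruning <- ('pruning_weight' %in% names(records)) &&
    !anyNA(records$pruning_weight)
  # per-vine ratios first: summarise() would otherwise see the group means
  records$.cw <- cluster_weight(records$yield, records$clusters)
  records$.rv <- if (has_pruning) {
    ravaz_index(records$yield, records$pruning_weight)
  } else NA_real_
  records |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_yield = mean(.data$yield),
      mean_clusters = mean(.data$clusters),
      cluster_wt = if (from_means) {
        cluster_weight(mean(.data$yield), mean(.data$clusters))
      } else {
        mean(.data$.cw)
      },
      ravaz = if (!has_pruning) NA_real_ else if (from_means) {
        ravaz_index(mean(.data$yield), mean(.data$pruning_weight))
      } else {
        mean(.data$.rv)
      },
      .groups = "drop"
    )
}
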