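#' Regress berry sugar content on simulated dry matter
#'
#' Ordinary least squares of measured degrees Brix on the simulated
#' cumulative dry matter at the matching days after sprouting.  Sampling is
#' expected between veraison and harvest (roughly weekly, ~10 points per
#' season), but any >= 3 in-range observations are accepted.
#'
#' @param brix_obs Data frame with columns `das` and `brix` (degrees Brix,
#'   in \[0, 35\]).
#' @param result A `vine_sim` tibble from [simulate_season()].
#' @return An object of class `brix_fit`: a list with `slope`
#'   (Brix per g DM), `intercept` (Brix), `r2` (squared Pearson
#'   correlation), `n`, and the underlying `lm` fit as `model`.
#' @examples
#' \dontrun{
#' fit <- fit_brix_dm(brix_obs, sim)
#' tidy(fit); glance(fit)
#' }
#' @export
fit_brix_dm <- function(brix_obs, result) {
  brix_obs <- tibble::as_tibble(brix_obs)
  if (any(brix_obs$brix < 0 | brix_obs$brix > 35)) {
    stop("`brix` must lie in [0, 35] degrees Brix.", call. = FALSE)
  }
  if (nrow(brix_obs) < 3) {
    stop("At least 3 Brix observations are required.", call. = FALSE)
  }
  idx <- match(brix_obs$das, result$das)
  if (anyNA(idx)) {
    stop("Brix observation(s) at DAS ",
         paste(brix_obs$das[is.na(idx)], collapse = ", "),
         " fall outside the simulated range.", call. = FALSE)
  }
  dm <- result$dm_cumulative[idx]
  if (stats::sd(dm) == 0) {
    stop("Simulated dry matter is constant at the observation days; ",
         "the regression is undefined.", call. = FALSE)
  }
  df <- tibble::tibble(das = brix_obs$das, dm = dm, brix = brix_obs$brix)
  model <- stats::lm(brix ~ dm, data = df)
  r2 <- if (stats::sd(df$brix) == 0) 0 else stats::cor(df$dm, df$brix)^2
  structure(
    list(slope = unname(stats::coef(model)[2]),
         intercept = unname(stats::coef(model)[1]),
         r2 = r2, n = nrow(df), model = model, data = df),
    class = "brix_fit"
  )
}

#' Predict a sugar trajectory from dry matter
#'
#' Applies the fitted linear map Brix = intercept + slope x DM to a
#' cumulative dry-matter trajectory, clamping predictions at zero.
#'
#' @param fit A `brix_fit` from [fit_brix_dm()].
#' @param dm_trajectory Numeric cumulative dry-matter series, g per vine.
#' @return Numeric degrees-Brix series of the same length.
#' @export
predict_brix <- function(fit, dm_trajectory) {
  stopifnot(inherits(fit, "brix_fit"))
  pmax(0, fit$intercept + fit$slope * dm_trajectory)
}

#' Sugar trajectories under cluster-number scenarios
#'
#' Re-simulates the season with the per-vine cluster count overridden
#' throughout, then predicts the Brix trajectory from the fitted sugar-DM
#' regression.  Cluster number acts through cluster maintenance respiration
#' only — the model's single crop-load pathway — so with a positive cluster
#' respiration rate and a positive regression slope, predicted Brix is
#' pointwise non-increasing in cluster count: fewer clusters, sweeter
#' berries.
#'
#' @param weather,canopy,params As for [simulate_season()].
#' @param fit A `brix_fit` from [fit_brix_dm()].
#' @param cluster_counts Numeric vector of clusters-per-vine scenarios
#'   (>= 0; e.g. `c(6, 12)`).
#' @return A `brix_scenarios` tibble with columns `clusters`, `das`,
#'   `dm_cumulative`, `brix`, one block per scenario plus the baseline
#'   (`clusters = NA`, the observed trajectory).
#' @export
run_cluster_scenarios <- function(weather, canopy, params, fit,
                                  cluster_counts) {
  stopifnot(inherits(fit, "brix_fit"))
  if (any(cluster_counts < 0)) {
    stop("`cluster_counts` must be non-negative.", call. = FALSE)
  }
  one_run <- function(count) {
    cn <- canopy
    if (!is.na(count)) cn$clusters <- count
    sim <- simulate_season(weather, cn, params)
    tibble::tibble(
      clusters = count, das = sim$das,
      dm_cumulative = sim$dm_cumulative,
      brix = predict_brix(fit, sim$dm_cumulative)
    )
  }
  out <- dplyr::bind_rows(
    one_run(NA_real_), # baseline: observed cluster counts
    purrr::map_dfr(cluster_counts, one_run)
  )
  class(out) <- c("brix_scenarios", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy brix_fit
#' @export
tidy.brix_fit <- function(x, ...) {
  broom_like <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "dm_cumulative"),
    estimate = unname(broom_like[, "Estimate"]),
    std.error = unname(broom_like[, "Std. Error"]),
    statistic = unname(broom_like[, "t value"]),
    p.value = unname(broom_like[, "Pr(>|t|)"])
  )
}

#' @method glance brix_fit
#' @export
glance.brix_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    slope = x$slope,
    intercept = x$intercept,
    sigma = summary(x$model)$sigma,
    nobs = x$n
  )
}

#' @export
print.brix_fit <- function(x, ...) {
  cat("Sugar-dry matter regression (OLS)\n")
  cat(sprintf("  Brix = %.4f + %.5f x DM (g/vine)\n", x$intercept, x$slope))
  cat(sprintf("  R^2 = %.3f on n = %d observations\n", x$r2, x$n))
  invisible(x)
}
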