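#' Goodness-of-fit statistics for model evaluation
#'
#' Compares observed values with model predictions using the four standard
#' crop-model indicators:
#' \itemize{
#'   \item `r2` — squared Pearson correlation;
#'   \item `mae` — mean absolute error, in the units of the variable;
#'   \item `rrmse` — root-mean-square error divided by the observed mean
#'     (dimensionless);
#'   \item `pbias` — percentage bias,
#'     \eqn{100 \sum (O_i - P_i) / \sum O_i}.  The sign convention makes
#'     under-prediction positive: a model that runs low on a positive
#'     variable has pbias > 0.
#' }
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2).
#'   `observed` must have non-zero variance (for r2) and a non-zero mean
#'   (for rrmse and pbias).
#' @return A `gof_report` tibble with one row and columns `r2`, `mae`,
#'   `rrmse`, `pbias`, `n`.
#' @examples
#' evaluate_fit(c(1, 2, 3), c(2, 2, 2)) # mae 2/3, rrmse 0.408, pbias 0
#' @export
evaluate_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have the same length.", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("At least 2 paired values are required.", call. = FALSE)
  if (stats::sd(observed) == 0) {
    stop("`observed` has zero variance: r2 is undefined.", call. = FALSE)
  }
  if (mean(observed) == 0) {
    stop("`observed` has zero mean: rrmse and pbias are undefined.",
         call. = FALSE)
  }
  r2 <- if (stats::sd(predicted) == 0) 0 else
    stats::cor(observed, predicted)^2
  err <- predicted - observed
  out <- tibble::tibble(
    r2 = r2,
    mae = mean(abs(err)),
    rrmse = sqrt(mean(err^2)) / mean(observed),
    pbias = 100 * sum(observed - predicted) / sum(observed),
    n = n
  )
  class(out) <- c("gof_report", class(out))
  out
}

#' @method glance gof_report
#' @export
glance.gof_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
print.gof_report <- function(x, ...) {
  cat("Model evaluation\n")
  cat(sprintf("  R^2 = %.3f  MAE = %.4g  RRMSE = %.3f  PBIAS = %+.2f%%  (n = %d)\n",
              x$r2, x$mae, x$rrmse, x$pbias, x$n))
  invisible(x)
}
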