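#' Forecast accuracy metrics
#'
#' Computes the five error measures used to judge residue forecasts: mean
#' squared error, its square root, mean absolute error, and the two
#' percentage errors
#' \deqn{MAPE = \frac{100}{n} \sum |(\hat y_i - y_i)/y_i|, \quad
#'       SMAPE = \frac{100}{n} \sum \frac{|\hat y_i - y_i|}{(|\hat y_i| + |y_i|)/2}.}
#' Terms that are 0/0 contribute 0. A zero observation with a nonzero
#' prediction makes MAPE infinite; this is reported as `Inf` with a warning
#' rather than an error.
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values, same length.
#' @return An object of class `metrics_report`: list with `mse`, `rmse`,
#'   `mae`, `mape_pct`, `smape_pct`.
#' @examples
#' evaluate_metrics(c(1, 2), c(2, 2))
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) == 0L) stop("empty input")
  err <- y_pred - y_true
  mse <- mean(err^2)
  mae <- mean(abs(err))

  ape <- abs(err) / abs(y_true)
  ape[abs(err) == 0 & y_true == 0] <- 0
  if (any(is.infinite(ape) | (y_true == 0 & abs(err) > 0))) {
    ape[y_true == 0 & abs(err) > 0] <- Inf
    warning("zero observation with nonzero prediction: MAPE is infinite")
  }
  denom <- (abs(y_pred) + abs(y_true)) / 2
  sape <- abs(err) / denom
  sape[denom == 0] <- 0

  structure(list(mse = mse, rmse = sqrt(mse), mae = mae,
                 mape_pct = 100 * mean(ape),
                 smape_pct = 100 * mean(sape)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 5, ...) {
  cat("Forecast accuracy:\n")
  cat(sprintf("  MSE   %.*g\n  RMSE  %.*g\n  MAE   %.*g\n  MAPE  %.*g %%\n  SMAPE %.*g %%\n",
              digits, x$mse, digits, x$rmse, digits, x$mae,
              digits, x$mape_pct, digits, x$smape_pct))
  invisible(x)
}

#' Persistence (naive last-value) baseline forecast
#'
#' Repeats the last observed concentration of a forecast window for every
#' horizon step. Serves as the reference point a trained forecaster has to
#' beat.
#'
#' @param window A forecast window from [make_windows()].
#' @param horizon Number of steps to forecast (defaults to the window's
#'   target length).
#' @return Numeric vector of length `horizon`, mg/kg.
#' @export
persistence_baseline <- function(window, horizon = length(window$target)) {
  stopifnot(inherits(window, "forecast_window"))
  rep(window$conc[length(window$conc)], horizon)
}
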