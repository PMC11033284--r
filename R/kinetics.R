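#' First-order degradation fit and half-life
#'
#' Standard residue-dissipation kinetics: ordinary least squares of
#' `ln C = ln C0 - k t` over the strictly positive observations, with the
#' half-life `t_half = ln(2) / k`. The R-squared of the log-linear fit is
#' reported so lack of fit (e.g. bi-phasic decay) is visible.
#'
#' @param series A `residue_series`, or anything with `days` and `conc`
#'   components.
#' @param max_day Restrict the fit to observations at `day <= max_day`.
#'   `Inf` (the default) uses the whole series; fitting only the initial
#'   dissipation phase (e.g. the first week) avoids the bias a late plateau
#'   induces on the slope of a bi-phasic curve.
#' @return An object of class `kinetic_fit`: list with `C0_hat`, `k_hat`
#'   (per day), `t_half` (days), `r_squared`, `n_used`.
#' @examples
#' s <- residue_series("x", 25, 65, 0:10, 4 * exp(-0.2 * (0:10)))
#' fit_first_order(s)  # k_hat = 0.2, t_half = log(2) / 0.2
#' @export
fit_first_order <- function(series, max_day = Inf) {
  t <- series$days
  c_obs <- series$conc
  keep <- is.finite(c_obs) & c_obs > 0 & t <= max_day
  if (sum(keep) < 3L)
    stop("need at least 3 strictly positive concentrations, got ", sum(keep))
  t <- t[keep]; y <- log(c_obs[keep])
  fit <- stats::lm(y ~ t)
  k_hat <- -unname(stats::coef(fit)[2])
  sst <- sum((y - mean(y))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= .Machine$double.eps) 1 else 1 - ssr / sst
  if (k_hat <= 1e-12) {
    warning("non-positive degradation rate estimate; half-life reported as Inf")
    t_half <- Inf
  } else {
    t_half <- log(2) / k_hat
  }
  structure(list(C0_hat = exp(unname(stats::coef(fit)[1])), k_hat = k_hat,
                 t_half = t_half, r_squared = r2, n_used = sum(keep)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> k = %.4g /day, t1/2 = %.4g days, C0 = %.4g mg/kg, R^2 = %.4f (n = %d)\n",
              x$k_hat, x$t_half, x$C0_hat, x$r_squared, x$n_used))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(C0 = object$C0_hat, k = object$k_hat, t_half = object$t_half)
}

#' Predicted first-order decay curve
#'
#' @param object A `kinetic_fit`.
#' @param newdata Numeric vector of days (defaults to 0..30).
#' @param ... Unused.
#' @return Predicted concentrations, mg/kg.
#' @export
predict.kinetic_fit <- function(object, newdata = 0:30, ...) {
  object$C0_hat * exp(-object$k_hat * as.numeric(newdata))
}
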