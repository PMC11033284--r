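#' Coded factor levels for the storage response surface
#'
#' Maps temperature and relative humidity onto the coded units of the
#' two-factor design: level -1 is 30 degC / 70 %, level 0 is 35 degC / 75 %
#' and level +1 is 40 degC / 80 %, i.e. `A = (T - 35)/5`, `B = (H - 75)/5`.
#'
#' @param temperature_C Temperature(s), degC.
#' @param rh_pct Relative humidity(ies), %.
#' @return Data frame with columns `A` and `B`.
#' @examples
#' coded_levels(30, 70)  # A = -1, B = -1
#' @export
coded_levels <- function(temperature_C, rh_pct) {
  data.frame(A = (temperature_C - 35) / 5, B = (rh_pct - 75) / 5)
}

#' Full two-factor three-level factorial in coded units
#'
#' @return Data frame of the 9 coded design points.
#' @export
factorial_design_3x3 <- function() {
  expand.grid(A = c(-1, 0, 1), B = c(-1, 0, 1))
}

#' Quadratic response-surface fit on coded factors
#'
#' Least squares fit of
#' \deqn{y = \beta_0 + \beta_1 A + \beta_2 B + \beta_3 AB + \beta_4 A^2 +
#'  \beta_5 B^2}
#' to a response (typically the degradation half-life in days) observed on a
#' coded two-factor design. The fit exposes an evaluator over the coded
#' square and the stationary point of the quadratic.
#'
#' @param design Data frame with columns `A` and `B` (>= 6 points spanning
#'   >= 3 distinct levels per factor).
#' @param response Numeric response vector, one value per design row.
#' @return An object of class `surface_fit`: list with `beta` (named length
#'   6), `residual_sd`, `stationary` (coded coordinates and whether they lie
#'   in the unit square), and `fitted`.
#' @export
response_surface_fit <- function(design, response) {
  if (!all(c("A", "B") %in% names(design))) stop("design needs columns A and B")
  if (nrow(design) != length(response)) stop("design/response size mismatch")
  if (nrow(design) < 6L)
    stop("need at least 6 design points to identify 6 coefficients")
  if (length(unique(design$A)) < 3L || length(unique(design$B)) < 3L)
    stop("each factor needs at least 3 distinct levels (quadratic terms)")
  X <- cbind(1, design$A, design$B, design$A * design$B,
             design$A^2, design$B^2)
  colnames(X) <- c("intercept", "A", "B", "AB", "A2", "B2")
  qr_x <- qr(X)
  if (qr_x$rank < 6L) {
    bad <- colnames(X)[setdiff(seq_len(6L), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("rank-deficient design; unidentifiable terms: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, response)
  fitted <- as.vector(X %*% beta)
  dfr <- nrow(X) - 6L
  residual_sd <- if (dfr > 0) sqrt(sum((response - fitted)^2) / dfr) else 0

  # stationary point: solve the gradient system of the quadratic
  Hm <- matrix(c(2 * beta["A2"], beta["AB"], beta["AB"], 2 * beta["B2"]), 2)
  stat <- tryCatch({
    sp <- solve(Hm, -c(beta["A"], beta["B"]))
    ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
    list(A = sp[1], B = sp[2],
         inside = all(abs(sp) <= 1),
         type = if (all(ev > 0)) "minimum" else if (all(ev < 0)) "maximum"
                else "saddle")
  }, error = function(e) NULL)

  structure(list(beta = beta, residual_sd = residual_sd, stationary = stat,
                 fitted = fitted, design = design, response = response),
            class = "surface_fit")
}

#' @export
coef.surface_fit <- function(object, ...) object$beta

#' Evaluate a fitted response surface
#'
#' @param object A `surface_fit`.
#' @param newdata Data frame with coded columns `A` and `B` (defaults to the
#'   design the surface was fitted on).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.surface_fit <- function(object, newdata = object$design, ...) {
  b <- object$beta
  as.vector(b[1] + b[2] * newdata$A + b[3] * newdata$B +
              b[4] * newdata$A * newdata$B + b[5] * newdata$A^2 +
              b[6] * newdata$B^2)
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Quadratic response surface (coded factors):\n")
  print(round(x$beta, 5))
  cat(sprintf("  residual sd = %.4g\n", x$residual_sd))
  if (!is.null(x$stationary))
    cat(sprintf("  stationary point: A = %.3f, B = %.3f (%s, %s the unit square)\n",
                x$stationary$A, x$stationary$B, x$stationary$type,
                if (x$stationary$inside) "inside" else "outside"))
  invisible(x)
}
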