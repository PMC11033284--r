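#' Slide forecast windows over residue series
#'
#' Cuts each series into overlapping windows of `input_len` consecutive
#' observations plus the following `horizon` observations as the target,
#' stride 1. A series of length L contributes `L - input_len - horizon + 1`
#' windows; series too short to contribute any are skipped with a warning.
#'
#' @param series A `residue_series` or a list of them (see
#'   [split_series()]).
#' @param input_len Number of observed steps fed to the model.
#' @param horizon Number of future steps to predict.
#' @return List of `forecast_window` objects, each holding the raw input
#'   concentrations (`conc`), the storage covariates, the raw `target`, the
#'   series id and the anchor day (day index of the first input element).
#' @export
make_windows <- function(series, input_len = 7, horizon = 1) {
  if (inherits(series, "residue_series")) series <- list(series)
  stopifnot(input_len >= 1, horizon >= 1)
  out <- list()
  skipped <- 0L
  for (s in series) {
    n <- length(s$conc)
    n_win <- n - input_len - horizon + 1L
    if (n_win < 1L) { skipped <- skipped + 1L; next }
    sid <- paste(s$pesticide, s$temperature_C, s$rh_pct,
                 if (!is.null(s$arm)) s$arm else "", sep = "/")
    for (a in seq_len(n_win)) {
      idx_in <- a:(a + input_len - 1L)
      idx_tg <- (a + input_len):(a + input_len + horizon - 1L)
      out[[length(out) + 1L]] <- structure(
        list(series_id = sid, anchor = s$days[a],
             conc = s$conc[idx_in],
             temperature_C = s$temperature_C, rh_pct = s$rh_pct,
             target = s$conc[idx_tg], target_days = s$days[idx_tg]),
        class = "forecast_window")
    }
  }
  if (skipped > 0L)
    warning(skipped, " series shorter than input_len + horizon were skipped")
  if (length(out) == 0L) stop("no series long enough to window")
  out
}

#' Chronological train/validation/test split of forecast windows
#'
#' Splits the windows of every series by anchor order: the earliest
#' `floor(f_train * n)` go to training, the next `floor(f_val * n)` to
#' validation and the remainder to test, so no training window ever contains
#' information from after a test window of the same series.
#' Standardization statistics (concentration, temperature, humidity) are
#' computed on the training windows only and attached to the result.
#'
#' @param windows List of windows from [make_windows()].
#' @param fractions Length-3 non-negative vector summing to 1.
#' @return An object of class `window_split`: list with `train`, `val`,
#'   `test` (window lists) and `scaler` (see [standardize_window()]).
#' @export
split_windows <- function(windows, fractions = c(0.7, 0.1, 0.2)) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  ids <- vapply(windows, function(w) w$series_id, character(1))
  train <- val <- test <- list()
  for (sid in unique(ids)) {
    w <- windows[ids == sid]
    w <- w[order(vapply(w, function(x) x$anchor, numeric(1)))]
    n <- length(w)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    train <- c(train, w[seq_len(n_tr)])
    val <- c(val, if (n_va > 0) w[n_tr + seq_len(n_va)] else list())
    if (n_tr + n_va < n) test <- c(test, w[(n_tr + n_va + 1L):n])
  }
  if (length(train) == 0L || length(val) == 0L || length(test) == 0L)
    stop("empty train, validation or test partition; adjust fractions")
  scaler <- fit_scaler(train)
  structure(list(train = train, val = val, test = test, scaler = scaler),
            class = "window_split")
}

fit_scaler <- function(train_windows) {
  conc <- unlist(lapply(train_windows, function(w) c(w$conc, w$target)))
  tmp <- vapply(train_windows, function(w) w$temperature_C, numeric(1))
  rh <- vapply(train_windows, function(w) w$rh_pct, numeric(1))
  safe_sd <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12) 1 else s
  }
  list(conc_mean = mean(conc), conc_sd = safe_sd(conc),
       temp_mean = mean(tmp), temp_sd = safe_sd(tmp),
       rh_mean = mean(rh), rh_sd = safe_sd(rh))
}

#' Standardize a forecast window into a model input matrix
#'
#' @param window A `forecast_window`.
#' @param scaler Scaler list from [split_windows()].
#' @return List with `x` (input_len x 3 matrix: standardized concentration,
#'   scaled temperature, scaled humidity) and `y` (standardized target).
#' @export
standardize_window <- function(window, scaler) {
  x <- cbind((window$conc - scaler$conc_mean) / scaler$conc_sd,
             rep((window$temperature_C - scaler$temp_mean) / scaler$temp_sd,
                 length(window$conc)),
             rep((window$rh_pct - scaler$rh_mean) / scaler$rh_sd,
                 length(window$conc)))
  list(x = x, y = (window$target - scaler$conc_mean) / scaler$conc_sd)
}

#' Map standardized concentrations back to mg/kg
#'
#' @param z Standardized values.
#' @param scaler Scaler list from [split_windows()].
#' @return Values on the original mg/kg scale.
#' @export
destandardize_conc <- function(z, scaler) z * scaler$conc_sd + scaler$conc_mean

#' Split a long residue table into residue series
#'
#' @param df Data frame with columns `pesticide`, `temperature_C`, `rh_pct`,
#'   `day`, `conc_mgkg` and optionally `arm`.
#' @return Named list of `residue_series` objects, grouped by pesticide,
#'   condition and (when present) arm.
#' @export
split_series <- function(df) {
  req <- c("pesticide", "temperature_C", "rh_pct", "day", "conc_mgkg")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  has_arm <- "arm" %in% names(df)
  key <- paste(df$pesticide, df$temperature_C, df$rh_pct,
               if (has_arm) df$arm else "", sep = "/")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- df[idx, , drop = FALSE]
    g <- g[order(g$day), , drop = FALSE]
    if (anyDuplicated(g$day))
      stop("duplicate day within series ", key[idx[1]])
    s <- residue_series(g$pesticide[1], g$temperature_C[1], g$rh_pct[1],
                        g$day, g$conc_mgkg)
    if (has_arm) s$arm <- g$arm[1]
    s
  })
  out[order(names(out))]
}
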