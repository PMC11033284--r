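#' Storage condition
#'
#' A temperature / relative-humidity pair describing one controlled-climate
#' storage chamber setting.
#'
#' @param temperature_C Storage temperature in degrees Celsius, in (0, 60).
#' @param rh_pct Relative humidity in percent, in (0, 100].
#' @return An object of class `storage_condition` (a named list).
#' @examples
#' storage_condition(25, 65)
#' @export
storage_condition <- function(temperature_C, rh_pct) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(rh_pct), length(rh_pct) == 1L)
  if (!is.finite(temperature_C) || temperature_C <= 0 || temperature_C >= 60)
    stop("temperature_C must lie in (0, 60) degrees C, got ", temperature_C)
  if (!is.finite(rh_pct) || rh_pct <= 0 || rh_pct > 100)
    stop("rh_pct must lie in (0, 100] percent, got ", rh_pct)
  structure(list(temperature_C = as.numeric(temperature_C),
                 rh_pct = as.numeric(rh_pct)),
            class = "storage_condition")
}

#' Pesticide dissipation profile
#'
#' Parameterizes the bi-exponential (two-compartment) decay of one pesticide
#' in stored grain, together with a unimodal Gaussian response of the fast
#' rate constant to temperature and humidity.
#'
#' The noiseless residue curve is
#' \deqn{C(t) = C_0 [ f e^{-k_f t} + (1 - f) e^{-k_{slow} t} ]}
#' where the fast rate \eqn{k_f} depends on the storage condition through
#' [degradation_rate()]. A single-exponential profile is the `fast_fraction
#' = 1` special case.
#'
#' @param name Pesticide identifier.
#' @param C0 Initial concentration, mg/kg, > 0.
#' @param fast_fraction Fraction of the residue pool in the fast compartment,
#'   in (0, 1].
#' @param k_base Peak fast rate constant (per day) attained at the optimal
#'   temperature/humidity.
#' @param k_slow Slow-compartment rate constant (per day), 0 < k_slow < k_base.
#' @param T_opt,sigma_T Centre (deg C) and width of the Gaussian temperature
#'   response of the fast rate.
#' @param H_opt,sigma_H Centre (% RH) and width of the Gaussian humidity
#'   response.
#' @param noise_sd Relative (lognormal) measurement noise standard deviation.
#' @return An object of class `pesticide_profile`.
#' @export
pesticide_profile <- function(name, C0, fast_fraction, k_base, k_slow,
                              T_opt, sigma_T, H_opt, sigma_H,
                              noise_sd = 0.05) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(C0) || C0 <= 0) stop("C0 must be > 0")
  if (!is.finite(fast_fraction) || fast_fraction <= 0 || fast_fraction > 1)
    stop("fast_fraction must lie in (0, 1]")
  if (!is.finite(k_base) || !is.finite(k_slow) || k_slow <= 0 || k_slow >= k_base)
    stop("need 0 < k_slow < k_base")
  if (!is.finite(sigma_T) || sigma_T <= 0) stop("sigma_T must be > 0")
  if (!is.finite(sigma_H) || sigma_H <= 0) stop("sigma_H must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, C0 = as.numeric(C0),
                 fast_fraction = as.numeric(fast_fraction),
                 k_base = as.numeric(k_base), k_slow = as.numeric(k_slow),
                 T_opt = as.numeric(T_opt), sigma_T = as.numeric(sigma_T),
                 H_opt = as.numeric(H_opt), sigma_H = as.numeric(sigma_H),
                 noise_sd = as.numeric(noise_sd)),
            class = "pesticide_profile")
}

#' Default pesticide profiles
#'
#' Profiles for the five pesticides followed during storage: imidacloprid,
#' carbaryl, fenitrothion, chlorpyrifos-methyl and deltamethrin. Initial
#' residues (4--7 mg/kg) are typical post-application levels; fast-rate
#' constants are chosen so that dissipation curves flatten after roughly one
#' week at the mildest condition, except chlorpyrifos-methyl whose smaller
#' fast rate delays the flattening to about the fifteenth day. All rates peak
#' at 38 deg C / 78 % RH so that both the temperature and the humidity
#' response are unimodal over the 25--40 deg C / 65--80 % study range.
#'
#' @param noise_sd Relative measurement noise applied to every profile.
#' @return Named list of [pesticide_profile()] objects.
#' @export
default_profiles <- function(noise_sd = 0.05) {
  mk <- function(name, C0, f, kb, ks)
    pesticide_profile(name, C0 = C0, fast_fraction = f, k_base = kb,
                      k_slow = ks, T_opt = 38, sigma_T = 18,
                      H_opt = 78, sigma_H = 22, noise_sd = noise_sd)
  list(
    imidacloprid          = mk("imidacloprid",          5.0, 0.85, 0.55, 0.010),
    carbaryl              = mk("carbaryl",              5.5, 0.82, 0.50, 0.012),
    fenitrothion          = mk("fenitrothion",          7.0, 0.85, 0.60, 0.010),
    `chlorpyrifos-methyl` = mk("chlorpyrifos-methyl",   6.0, 0.88, 0.28, 0.008),
    deltamethrin          = mk("deltamethrin",          4.0, 0.80, 0.45, 0.012)
  )
}

#' Study design for the storage experiment
#'
#' Two one-factor arms: a temperature sweep at a reference humidity and a
#' humidity sweep at a reference temperature, each condition followed daily.
#' The reference condition (25 deg C / 65 % RH) belongs to both arms and is
#' counted as two condition series, giving 8 series per pesticide and, with
#' the defaults (5 pesticides, 30 days), 5 x 8 x 30 = 1200 records.
#'
#' @param temperatures Temperatures (deg C) swept at `ref_rh`.
#' @param humidities Humidities (% RH) swept at `ref_temperature`.
#' @param ref_temperature,ref_rh The reference levels held fixed in the
#'   opposite arm.
#' @param days Number of daily samples per series (day 0 .. days - 1).
#' @param profiles List of [pesticide_profile()] objects.
#' @return An object of class `study_design`.
#' @export
study_design <- function(temperatures = c(25, 30, 35, 40),
                         humidities = c(65, 70, 75, 80),
                         ref_temperature = 25, ref_rh = 65,
                         days = 30, profiles = default_profiles()) {
  if (length(profiles) == 0L) stop("profiles must contain at least one pesticide")
  if (!all(vapply(profiles, inherits, logical(1), "pesticide_profile")))
    stop("profiles must be a list of pesticide_profile objects")
  if (days < 2) stop("days must be >= 2")
  if (!(ref_temperature %in% temperatures))
    stop("ref_temperature must appear in temperatures")
  if (!(ref_rh %in% humidities))
    stop("ref_rh must appear in humidities")
  structure(list(temperatures = as.numeric(temperatures),
                 humidities = as.numeric(humidities),
                 ref_temperature = as.numeric(ref_temperature),
                 ref_rh = as.numeric(ref_rh),
                 days = as.integer(days), profiles = profiles),
            class = "study_design")
}

#' Condition table of a study design
#'
#' @param design A [study_design()].
#' @return Data frame with columns `arm`, `temperature_C`, `rh_pct`, one row
#'   per condition series (the reference condition appears in both arms).
#' @export
design_conditions <- function(design) {
  stopifnot(inherits(design, "study_design"))
  data.frame(
    arm = c(rep("temperature", length(design$temperatures)),
            rep("humidity", length(design$humidities))),
    temperature_C = c(design$temperatures,
                      rep(design$ref_temperature, length(design$humidities))),
    rh_pct = c(rep(design$ref_rh, length(design$temperatures)),
               design$humidities),
    stringsAsFactors = FALSE
  )
}

#' Condition-dependent fast degradation rate
#'
#' The fast rate constant responds unimodally to both storage factors:
#' \deqn{k_f(T, H) = k_{base} \exp(-(T - T_{opt})^2 / 2\sigma_T^2)
#'                          \exp(-(H - H_{opt})^2 / 2\sigma_H^2).}
#' The rate rises with temperature up to a critical temperature `T_opt` and
#' falls beyond it, and likewise in humidity, which makes fitted half-life
#' surfaces over (T, H) non-monotone with an interior extremum.
#'
#' @param profile A [pesticide_profile()].
#' @param condition A [storage_condition()].
#' @return The fast rate constant, per day (strictly positive scalar).
#' @examples
#' p <- default_profiles()$imidacloprid
#' degradation_rate(p, storage_condition(38, 78))  # the peak, = k_base
#' @export
degradation_rate <- function(profile, condition) {
  stopifnot(inherits(profile, "pesticide_profile"))
  if (!inherits(condition, "storage_condition"))
    condition <- do.call(storage_condition, as.list(condition)[c("temperature_C", "rh_pct")])
  dT <- condition$temperature_C - profile$T_opt
  dH <- condition$rh_pct - profile$H_opt
  profile$k_base * exp(-dT^2 / (2 * profile$sigma_T^2)) *
    exp(-dH^2 / (2 * profile$sigma_H^2))
}

#' Noiseless residue decay curve
#'
#' @param profile A [pesticide_profile()].
#' @param condition A [storage_condition()].
#' @param t Numeric vector of days (>= 0).
#' @return Concentrations C(t), mg/kg.
#' @export
decay_curve <- function(profile, condition, t) {
  kf <- degradation_rate(profile, condition)
  f <- profile$fast_fraction
  profile$C0 * (f * exp(-kf * t) + (1 - f) * exp(-profile$k_slow * t))
}

#' Simulate one residue dissipation series
#'
#' Daily observations on day 0 .. days-1 from the bi-exponential mean curve,
#' perturbed by multiplicative lognormal noise (`noise_sd` on the log scale)
#' and clipped at zero. The noiseless curve is strictly decreasing; day 0
#' equals the initial concentration exactly when `noise_sd = 0`.
#'
#' @param profile A [pesticide_profile()].
#' @param condition A [storage_condition()].
#' @param days Number of daily samples, >= 2.
#' @param seed Non-negative integer seed; identical seeds give identical
#'   series.
#' @param noise_sd Relative noise; defaults to the profile's value.
#' @return An object of class `residue_series`: list with `pesticide`,
#'   `temperature_C`, `rh_pct`, `days` (integer vector), `conc` (mg/kg).
#' @export
simulate_series <- function(profile, condition, days = 30, seed = 1,
                            noise_sd = profile$noise_sd) {
  stopifnot(inherits(profile, "pesticide_profile"))
  if (days < 2) stop("days must be >= 2")
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != floor(seed))
    stop("seed must be a non-negative integer")
  t <- 0:(days - 1)
  mu <- decay_curve(profile, condition, t)
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
    conc <- pmax(mu * exp(stats::rnorm(days, 0, noise_sd)), 0)
  } else {
    conc <- mu
  }
  residue_series(profile$name, condition$temperature_C, condition$rh_pct,
                 t, conc)
}

#' Construct a residue series object
#'
#' @param pesticide Pesticide identifier.
#' @param temperature_C,rh_pct Storage condition.
#' @param days Strictly increasing integer day indices.
#' @param conc Non-negative concentrations (mg/kg), same length as `days`.
#' @return An object of class `residue_series`.
#' @export
residue_series <- function(pesticide, temperature_C, rh_pct, days, conc) {
  days <- as.integer(days)
  if (length(days) != length(conc)) stop("days and conc lengths differ")
  if (length(days) > 1L && any(diff(days) <= 0L))
    stop("days must be strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  structure(list(pesticide = as.character(pesticide),
                 temperature_C = as.numeric(temperature_C),
                 rh_pct = as.numeric(rh_pct),
                 days = days, conc = as.numeric(conc)),
            class = "residue_series")
}

#' @export
print.residue_series <- function(x, ...) {
  cat(sprintf("<residue_series> %s at %.4g degC / %.4g %%RH, %d days, C0 ~ %.3g mg/kg\n",
              x$pesticide, x$temperature_C, x$rh_pct, length(x$days), x$conc[1]))
  invisible(x)
}

# Deterministic per-series sub-seed below 2^31, derived from the root seed and
# the (pesticide, arm, condition) position so subsets reproduce bit-exactly.
series_subseed <- function(seed, pesticide_idx, series_idx) {
  as.integer((as.double(seed) * 48271 + pesticide_idx * 10007 +
                series_idx * 101) %% 2147483629)
}

#' Generate the full storage study dataset
#'
#' Simulates every pesticide under every condition series of the design. The
#' reference condition is simulated once per arm (two independent series), so
#' the default design yields 5 pesticides x 8 series x 30 days = 1200
#' records.
#'
#' @param design A [study_design()].
#' @param seed Root integer seed; per-series sub-seeds are derived
#'   deterministically from it.
#' @param noise_sd Optional override of every profile's relative noise (e.g.
#'   0 for noiseless curves).
#' @param dedupe_reference If `TRUE`, the reference condition is emitted only
#'   once (7 series per pesticide).
#' @return Long-format data frame with columns `pesticide`, `arm`,
#'   `temperature_C`, `rh_pct`, `day`, `conc_mgkg`.
#' @examples
#' d <- generate_study_dataset(seed = 1)
#' nrow(d)  # 1200
#' @export
generate_study_dataset <- function(design = study_design(), seed = 1,
                                   noise_sd = NULL, dedupe_reference = FALSE) {
  stopifnot(inherits(design, "study_design"))
  if (length(design$profiles) == 0L) stop("design has no pesticides")
  conds <- design_conditions(design)
  if (dedupe_reference) {
    dup <- conds$arm == "humidity" &
      conds$temperature_C == design$ref_temperature &
      conds$rh_pct == design$ref_rh
    conds <- conds[!dup, , drop = FALSE]
  }
  out <- vector("list", length(design$profiles) * nrow(conds))
  m <- 0L
  for (p in seq_along(design$profiles)) {
    prof <- design$profiles[[p]]
    if (!is.null(noise_sd)) prof$noise_sd <- noise_sd
    for (ci in seq_len(nrow(conds))) {
      cond <- storage_condition(conds$temperature_C[ci], conds$rh_pct[ci])
      s <- simulate_series(prof, cond, days = design$days,
                           seed = series_subseed(seed, p, ci))
      m <- m + 1L
      out[[m]] <- data.frame(pesticide = prof$name, arm = conds$arm[ci],
                             temperature_C = cond$temperature_C,
                             rh_pct = cond$rh_pct, day = s$days,
                             conc_mgkg = s$conc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate tiered measured/predicted residue pairs
#'
#' Clustering fixture: draws (current, predicted) residue pairs around each
#' tier centre. The current residue is Normal(centre, tier_sd) truncated at
#' zero; the predicted residue is the current one scaled by Uniform(0.85, 1),
#' reflecting that the forecast of a decaying residue does not exceed the
#' present value.
#'
#' @param tier_centers Distinct tier centres, mg/kg.
#' @param tier_sd Within-tier spread, > 0.
#' @param n_per_tier Samples per tier, >= 1.
#' @param seed Integer seed.
#' @return Data frame with columns `d_current`, `d_predicted`, `tier`.
#' @export
generate_tiered_m_samples <- function(tier_centers, tier_sd, n_per_tier,
                                      seed = 1) {
  if (anyDuplicated(tier_centers)) stop("tier_centers must be distinct")
  if (!is.finite(tier_sd) || tier_sd <= 0) stop("tier_sd must be > 0")
  if (n_per_tier < 1) stop("n_per_tier must be >= 1")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  rows <- lapply(seq_along(tier_centers), function(i) {
    cur <- pmax(stats::rnorm(n_per_tier, tier_centers[i], tier_sd), 0)
    pred <- cur * stats::runif(n_per_tier, 0.85, 1.0)
    data.frame(d_current = cur, d_predicted = pred, tier = i)
  })
  do.call(rbind, rows)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
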