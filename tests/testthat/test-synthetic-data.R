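test_that("degradation rate follows the unimodal temperature/humidity response", {
  p <- pesticide_profile("x", C0 = 5, fast_fraction = 0.8, k_base = 0.3,
                         k_slow = 0.01, T_opt = 38, sigma_T = 8,
                         H_opt = 78, sigma_H = 12)
  peak <- degradation_rate(p, storage_condition(38, 78))
  expect_equal(peak, 0.3)
  expect_equal(degradation_rate(p, storage_condition(30, 78)),
               0.3 * exp(-0.5), tolerance = 1e-12)
  r <- vapply(c(34, 38, 42), function(tc)
    degradation_rate(p, storage_condition(tc, 78)), numeric(1))
  expect_true(r[2] > r[1] && r[2] > r[3])
  h <- vapply(c(70, 78, 86), function(rh)
    degradation_rate(p, storage_condition(38, rh)), numeric(1))
  expect_true(h[2] > h[1] && h[2] > h[3])
  expect_error(storage_condition(-5, 65), "temperature")
  expect_error(storage_condition(25, 0), "rh_pct")
})

test_that("simulated series match the bi-exponential closed form", {
  p <- pesticide_profile("x", C0 = 5, fast_fraction = 0.8, k_base = 0.4,
                         k_slow = 0.01, T_opt = 30, sigma_T = 5,
                         H_opt = 70, sigma_H = 8, noise_sd = 0)
  s <- simulate_series(p, storage_condition(30, 70), days = 10, seed = 1)
  expect_equal(s$conc[1], 5)  # t = 0 gives C0 exactly
  expect_equal(s$conc[8], 5 * (0.8 * exp(-2.8) + 0.2 * exp(-0.07)),
               tolerance = 1e-12)
  expect_true(all(diff(s$conc) < 0))
  expect_true(all(s$conc > 0 & s$conc <= 5))
  expect_error(simulate_series(p, storage_condition(30, 70), days = 1),
               "days")
  expect_error(simulate_series(p, storage_condition(30, 70), seed = -1),
               "seed")
})

test_that("identical seeds reproduce series bit-exactly", {
  p <- default_profiles()$carbaryl
  cond <- storage_condition(35, 65)
  s1 <- simulate_series(p, cond, seed = 7)
  s2 <- simulate_series(p, cond, seed = 7)
  s3 <- simulate_series(p, cond, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$conc, s3$conc))
})

test_that("the default study design emits 5 x 8 x 30 = 1200 records", {
  d <- generate_study_dataset(seed = 1)
  expect_identical(nrow(d), 1200L)
  expect_true(all(d$conc_mgkg >= 0))
  keys <- unique(d[, c("pesticide", "arm", "temperature_C", "rh_pct")])
  expect_identical(nrow(keys), 40L)
  # reference condition appears once per arm
  ref <- keys[keys$temperature_C == 25 & keys$rh_pct == 65, ]
  expect_identical(nrow(ref), 10L)  # 5 pesticides x 2 arms
  d2 <- generate_study_dataset(seed = 1, dedupe_reference = TRUE)
  expect_identical(nrow(d2), 5L * 7L * 30L)
})

test_that("custom designs emit the product of their dimensions", {
  des <- study_design(temperatures = 25, humidities = 65, days = 10,
                      profiles = default_profiles()[1])
  d <- generate_study_dataset(des, seed = 1)
  expect_identical(nrow(d), 20L)  # 1 pesticide x 2 series x 10 days
  expect_error(study_design(profiles = list()), "at least one")
})

test_that("log-linear fit on a noiseless single-exponential recovers the rate", {
  p <- mono_profile(k = 0.31)
  s <- simulate_series(p, storage_condition(25, 65), days = 5, seed = 1)
  fit <- lm(log(s$conc) ~ s$days)
  expect_equal(unname(-coef(fit)[2]), 0.31, tolerance = 1e-8)
})

test_that("chlorpyrifos-methyl flattens later than the other pesticides", {
  profs <- default_profiles()
  cond <- storage_condition(25, 65)
  kf <- vapply(profs, degradation_rate, numeric(1), condition = cond)
  expect_lt(kf[["chlorpyrifos-methyl"]], min(kf[setdiff(names(kf),
                                                        "chlorpyrifos-methyl")]))
})

test_that("tiered index samples have the requested structure", {
  m <- generate_tiered_m_samples(c(0.3, 1.0, 2.0), tier_sd = 0.05,
                                 n_per_tier = 50, seed = 1)
  expect_identical(nrow(m), 150L)
  expect_true(all(m$d_predicted <= m$d_current))
  expect_true(all(m$d_predicted >= 0.85 * m$d_current - 1e-12))
  # vanishing spread pins samples to their centres
  m0 <- generate_tiered_m_samples(c(0.3, 1.0), tier_sd = 1e-12,
                                  n_per_tier = 5, seed = 1)
  expect_equal(m0$d_current, rep(c(0.3, 1.0), each = 5), tolerance = 1e-9)
  # separation/sd >= 6 gives clearly separated tiers
  m6 <- generate_tiered_m_samples(c(0.5, 1.1, 1.7), tier_sd = 0.1,
                                  n_per_tier = 40, seed = 2)
  sil <- silhouette_index(as.matrix(m6[, c("d_current", "d_predicted")]),
                          m6$tier)
  expect_gt(sil, 0.7)
  expect_error(generate_tiered_m_samples(c(1, 2), tier_sd = 0, 5), "tier_sd")
  expect_error(generate_tiered_m_samples(c(1, 1), 0.1, 5), "distinct")
  expect_identical(generate_tiered_m_samples(c(1, 2), 0.1, 5, seed = 3),
                   generate_tiered_m_samples(c(1, 2), 0.1, 5, seed = 3))
})
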