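test_that("first-order fits recover noiseless kinetics exactly", {
  t <- 0:10
  s <- residue_series("x", 25, 65, t, 4 * exp(-0.2 * t))
  fit <- fit_first_order(s)
  expect_equal(fit$k_hat, 0.2, tolerance = 1e-10)
  expect_equal(fit$C0_hat, 4, tolerance = 1e-9)
  expect_equal(fit$t_half, log(2) / 0.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$t_half * fit$k_hat, log(2), tolerance = 1e-12)
  s2 <- residue_series("x", 25, 65, t, 3 * exp(-log(2) * t))
  expect_equal(fit_first_order(s2)$t_half, 1, tolerance = 1e-9)
  sc <- residue_series("x", 25, 65, t, rep(2, 11))
  expect_warning(fc <- fit_first_order(sc), "half-life")
  expect_identical(fc$t_half, Inf)
  expect_error(fit_first_order(residue_series("x", 25, 65, 0:1, c(1, 0.5))),
               "at least 3")
})

test_that("rate recovery stays within 10 % median error at 5 % noise", {
  p <- mono_profile(k = 0.15, noise_sd = 0.05)
  errs <- vapply(1:50, function(seed) {
    s <- simulate_series(p, storage_condition(25, 65), days = 31, seed = seed)
    abs(fit_first_order(s)$k_hat - 0.15) / 0.15
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("Duncan letters separate what the data separate", {
  # equal means share one letter
  r <- duncan_mrt(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(unique(r$groups$letters), "a")
  # widely separated groups receive distinct letters
  r2 <- duncan_mrt(list(lo = c(-0.1, 0, 0.1), hi = c(9.9, 10, 10.1)))
  expect_setequal(r2$groups$letters, c("a", "b"))
  expect_true(any_difference(r2))
  # all observations identical: single letter despite zero error variance
  r3 <- duncan_mrt(list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)))
  expect_identical(unique(r3$groups$letters), "a")
  # zero variance with unequal means: everything differs
  r4 <- duncan_mrt(list(a = rep(1, 3), b = rep(2, 3), c = rep(3, 3)))
  expect_identical(anyDuplicated(r4$groups$letters), 0L)
  expect_error(duncan_mrt(list(a = 1:3)), "2 groups")
  expect_error(duncan_mrt(list(a = 1, b = 1:3)), "at least 2 observations")
})

test_that("growing the separation between two groups never hides a difference", {
  set.seed(51)
  base <- rnorm(30)
  noise <- rnorm(30)
  found_at <- NA
  declared <- logical(0)
  for (gap in seq(0, 3, by = 0.25)) {
    r <- duncan_mrt(list(a = base, b = noise + gap))
    declared <- c(declared, any_difference(r))
  }
  first <- which(declared)[1]
  if (!is.na(first)) expect_true(all(declared[first:length(declared)]))
})

test_that("Duncan critical ranges use the protected studentized-range quantiles", {
  set.seed(52)
  g <- lapply(1:4, function(i) rnorm(10, i * 0.1))
  r <- duncan_mrt(g, alpha = 0.05)
  for (p in 2:4) {
    alpha_p <- 1 - 0.95^(p - 1)
    expect_equal(unname(r$critical_ranges[paste0("R", p)]),
                 qtukey(1 - alpha_p, p, r$df_error) *
                   sqrt(r$ms_error / 10),
                 tolerance = 1e-12)
  }
})

test_that("coded levels map the design temperatures and humidities", {
  expect_equal(unlist(coded_levels(30, 70)), c(A = -1, B = -1))
  expect_equal(unlist(coded_levels(35, 75)), c(A = 0, B = 0))
  expect_equal(unlist(coded_levels(40, 80)), c(A = 1, B = 1))
  expect_equal(unlist(coded_levels(42.5, 77.5)), c(A = 1.5, B = 0.5))
})

test_that("quadratic surfaces are recovered exactly from factorial data", {
  des <- factorial_design_3x3()
  beta <- c(10, -1.5, 0.8, 0.3, 1.2, -0.4)
  y <- beta[1] + beta[2] * des$A + beta[3] * des$B + beta[4] * des$A * des$B +
    beta[5] * des$A^2 + beta[6] * des$B^2
  fit <- response_surface_fit(des, y)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-9)
  expect_equal(predict(fit, data.frame(A = 0, B = 0)), beta[1],
               tolerance = 1e-9)
  fitc <- response_surface_fit(des, rep(3, 9))
  expect_equal(unname(fitc$beta), c(3, 0, 0, 0, 0, 0), tolerance = 1e-9)
  expect_error(response_surface_fit(des[1:4, ], rep(1, 4)), "at least 6")
  bad <- data.frame(A = c(-1, 0, 1, -1, 0, 1), B = c(-1, 0, 1, -1, 0, 1))
  expect_error(response_surface_fit(bad, rnorm(6)), "rank-deficient")
})

test_that("default-generator half-lives form a non-monotone surface with an interior minimum", {
  prof <- default_profiles()$fenitrothion
  des <- factorial_design_3x3()
  th <- vapply(seq_len(nrow(des)), function(i) {
    cond <- storage_condition(35 + 5 * des$A[i], 75 + 5 * des$B[i])
    s <- simulate_series(prof, cond, days = 30, seed = 0, noise_sd = 0)
    fit_first_order(s, max_day = 7)$t_half
  }, numeric(1))
  fit <- response_surface_fit(des, th)
  expect_false(is.null(fit$stationary))
  expect_true(fit$stationary$inside)
  expect_identical(fit$stationary$type, "minimum")
  # positive curvature in both coded factors
  expect_gt(unname(fit$beta["A2"]), 0)
  expect_gt(unname(fit$beta["B2"]), 0)
})
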