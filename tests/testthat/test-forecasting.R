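make_test_series <- function(n_series = 2, len = 30, k = 0.25) {
  lapply(seq_len(n_series), function(i) {
    t <- 0:(len - 1)
    residue_series(paste0("p", i), 20 + 5 * i, 65, t, 5 * exp(-k * t / i))
  })
}

test_that("window construction counts and alignment follow the sliding rule", {
  s <- make_test_series(1, len = 30)
  w <- make_windows(s, input_len = 7, horizon = 1)
  expect_length(w, 23L)  # 30 - 7 - 1 + 1
  for (i in c(1, 10, 23)) {
    expect_equal(w[[i]]$target, s[[1]]$conc[i + 7])
    expect_equal(w[[i]]$conc, s[[1]]$conc[i:(i + 6)])
  }
  w8 <- make_windows(make_test_series(1, len = 8), 7, 1)
  expect_length(w8, 1L)
  expect_warning(
    make_windows(c(make_test_series(1, len = 30),
                   make_test_series(1, len = 5)), 7, 1),
    "skipped")
  expect_error(suppressWarnings(make_windows(make_test_series(1, len = 5), 7, 1)),
               "no series")
})

test_that("chronological splits avoid leakage and standardize from training only", {
  w <- make_windows(make_test_series(2), 7, 1)
  sp <- split_windows(w)
  expect_length(sp$train, 32L)  # 16 per series
  expect_length(sp$val, 4L)
  expect_length(sp$test, 10L)
  ids <- function(lst) vapply(lst, function(x) x$series_id, character(1))
  anchors <- function(lst) vapply(lst, function(x) x$anchor, numeric(1))
  for (sid in unique(ids(sp$train))) {
    expect_lt(max(anchors(sp$train)[ids(sp$train) == sid]),
              min(anchors(sp$test)[ids(sp$test) == sid]))
  }
  expect_error(split_windows(w, c(1, 0, 0)), "empty")
  # scaler round trip
  z <- standardize_window(sp$train[[1]], sp$scaler)
  expect_equal(destandardize_conc(z$x[, 1], sp$scaler), sp$train[[1]]$conc,
               tolerance = 1e-12)
  expect_equal(destandardize_conc(z$y, sp$scaler), sp$train[[1]]$target,
               tolerance = 1e-12)
})

test_that("the five forecast metrics match an independent direct-formula oracle", {
  m <- evaluate_metrics(c(1, 2), c(2, 2))
  expect_equal(m$mse, 0.5)
  expect_equal(m$rmse, sqrt(0.5), tolerance = 1e-12)
  expect_equal(m$mae, 0.5)
  expect_equal(m$mape_pct, 50)
  expect_equal(m$smape_pct, 100 / 3, tolerance = 1e-9)
  set.seed(11)
  for (i in seq_len(100)) {
    y <- rnorm(100, 2, 1)
    yh <- y + rnorm(100, 0, 0.5)
    got <- evaluate_metrics(y, yh)
    want <- metrics_oracle(y, yh)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                         tolerance = 1e-10)
    expect_equal(got$rmse, sqrt(got$mse), tolerance = 1e-12)
    expect_lte(got$mae, got$rmse + 1e-12)
    expect_lte(got$smape_pct, 200)
  }
  perfect <- evaluate_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(unlist(perfect) == 0))
  expect_equal(evaluate_metrics(0, 0)$mape_pct, 0)
  expect_warning(m0 <- evaluate_metrics(c(0, 1), c(1, 1)), "infinite")
  expect_identical(m0$mape_pct, Inf)
})

test_that("the persistence baseline repeats the last observation", {
  w <- make_windows(make_test_series(1), 7, 1)
  expect_equal(persistence_baseline(w[[1]]), w[[1]]$conc[7])
  # constant series: zero error
  sc <- residue_series("c", 25, 65, 0:14, rep(2, 15))
  wc <- make_windows(list(sc), 7, 1)
  err <- vapply(wc, function(x) x$target - persistence_baseline(x), numeric(1))
  expect_true(all(err == 0))
  # strictly decreasing noiseless decay: bias equals the one-step decrement
  k <- 0.2
  sd1 <- residue_series("d", 25, 65, 0:14, 4 * exp(-k * (0:14)))
  wd <- make_windows(list(sd1), 7, 1)
  for (x in wd) {
    bias <- persistence_baseline(x) - x$target
    expect_equal(bias, x$conc[7] * (1 - exp(-k)), tolerance = 1e-12)
  }
})

test_that("training is seeded-deterministic and tracks the loss decomposition", {
  s <- make_test_series(1, len = 16)
  ctl <- quatformer_control(d_model = 8, n_heads = 2, memory_len = 2,
                            input_len = 5, label_len = 2, d_ff = 8,
                            epochs = 3, seed = 9)
  f1 <- quatformer(s, ctl)
  f2 <- quatformer(s, ctl)
  expect_equal(f1$history, f2$history, tolerance = 1e-14)
  expect_equal(f1$history$total,
               f1$history$l_pred + 0.01 * f1$history$l_omega +
                 0.01 * f1$history$l_theta,
               tolerance = 1e-10)
  ctl0 <- quatformer_control(d_model = 8, n_heads = 2, memory_len = 2,
                             input_len = 5, label_len = 2, d_ff = 8,
                             epochs = 2, lambda1 = 0, lambda2 = 0, seed = 9)
  f0 <- quatformer(s, ctl0)
  expect_equal(f0$history$total, f0$history$l_pred, tolerance = 1e-12)
})

test_that("a noiseless constant series is learned to high accuracy", {
  s <- list(residue_series("c", 25, 65, 0:15, rep(1.4, 16)))
  ctl <- quatformer_control(d_model = 8, n_heads = 2, memory_len = 2,
                            input_len = 5, label_len = 2, d_ff = 8,
                            epochs = 50, patience = 50, seed = 3)
  fit <- quatformer(s, ctl)
  expect_lt(fit$history$l_pred[nrow(fit$history)], 1e-3)
  pred <- predict(fit, s[[1]])
  expect_equal(as.numeric(pred), 1.4, tolerance = 0.02 * 1.4)
})

test_that("untrained models warn and linear-head structure holds", {
  s <- make_test_series(1, len = 16)
  ctl <- quatformer_control(d_model = 8, n_heads = 2, memory_len = 2,
                            input_len = 5, label_len = 2, d_ff = 8,
                            epochs = 1, seed = 2)
  fit <- quatformer(s, ctl)
  fit$trained <- FALSE
  expect_warning(predict(fit, s[[1]]), "not been trained")
  fit$trained <- TRUE
  # zeroed output head: prediction is the de-standardized bias
  fit$params$Wout[] <- 0
  fit$params$bout[] <- 0.25
  pred <- predict(fit, fit$split$test)
  expect_equal(as.vector(pred),
               rep(destandardize_conc(0.25, fit$scaler), length(fit$split$test)),
               tolerance = 1e-10)
  expect_identical(ncol(pred), 1L)  # horizon 1 -> length-1 forecasts
})
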