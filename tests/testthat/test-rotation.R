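test_that("pair rotation acts as a complex rotation and preserves norms", {
  expect_equal(rotate_pairs(matrix(c(1, 0), 1), matrix(0)), matrix(c(1, 0), 1))
  expect_equal(rotate_pairs(matrix(c(1, 0), 1), matrix(pi / 2)),
               matrix(c(0, 1), 1), tolerance = 1e-12)
  set.seed(1)
  x <- matrix(rnorm(6 * 8), 6, 8)
  ang <- matrix(runif(4 * 6, -pi, pi), 4, 6)
  y <- rotate_pairs(x, ang)
  expect_equal(sqrt(rowSums(y^2)), sqrt(rowSums(x^2)), tolerance = 1e-9)
  # oracle: complex multiplication per plane
  z <- complex(real = x[3, c(1, 3, 5, 7)], imaginary = x[3, c(2, 4, 6, 8)]) *
    exp(1i * ang[, 3])
  expect_equal(y[3, c(1, 3, 5, 7)], Re(z), tolerance = 1e-12)
  expect_equal(y[3, c(2, 4, 6, 8)], Im(z), tolerance = 1e-12)
  expect_error(rotate_pairs(matrix(rnorm(9), 3, 3), matrix(0, 1, 3)), "even")
})

test_that("learned frequencies respect the Nyquist range and replicate padding", {
  st <- rotation_state(8, seed = 4)
  set.seed(2)
  x <- matrix(rnorm(10 * 8), 10, 8)
  rp <- learn_rotation_params(x, st)
  expect_identical(dim(rp$omega), c(4L, 10L))
  expect_identical(dim(rp$theta), c(4L, 10L))
  expect_true(all(rp$omega >= 0 & rp$omega <= 0.5))
  expect_true(all(abs(rp$theta) < pi))
  # constant-in-time input: every convolution window is identical
  xc <- matrix(rep(rnorm(8), each = 7), 7, 8)
  rpc <- learn_rotation_params(xc, st)
  expect_equal(rpc$omega, rpc$omega[, c(1, 1, 1, 1, 1, 1, 1)])
  expect_equal(rpc$theta, rpc$theta[, rep(1, 7)])
})

test_that("rotated softmax-kernel scores reduce to and extend the dot-product kernel", {
  # zero vectors score exp(0) = 1 everywhere
  s <- lra_scores(matrix(0, 3, 4), matrix(0, 5, 4))
  expect_equal(s, matrix(1, 3, 5))
  # quarter-turn frequency makes aligned unit vectors orthogonal
  q <- rbind(c(1, 0), c(1, 0))
  k <- matrix(c(1, 0), 1)
  rp_q <- rotation_params(matrix(0.25, 1, 2), matrix(0, 1, 2))
  s <- lra_scores(q, k, rp_q = rp_q)
  expect_equal(s[2, 1], 1, tolerance = 1e-12)  # angle pi/2 at position m=1
  # shared constant frequency, zero phase: scores depend on m - n only
  set.seed(3)
  vec <- rnorm(4)
  q <- matrix(vec, 6, 4, byrow = TRUE)
  k <- matrix(vec, 6, 4, byrow = TRUE)
  rp <- rotation_params(matrix(0.11, 2, 6), matrix(0, 2, 6))
  s <- lra_scores(q, k, rp, rp)
  for (d in -2:2) {
    on_diag <- s[cbind(3:4, 3:4 - d)]
    expect_equal(on_diag[1], on_diag[2], tolerance = 1e-10)
  }
})

test_that("zero-rotation attention equals plain scaled dot-product attention", {
  set.seed(4)
  q <- matrix(rnorm(7 * 8), 7, 8)
  k <- matrix(rnorm(9 * 8), 9, 8)
  v <- matrix(rnorm(9 * 8), 9, 8)
  out <- lra_attention(q, k, v)
  expect_equal(out, plain_attention(q, k, v), tolerance = 1e-6)
  # attention weights are probability rows
  s <- lra_scores(q, k)
  w <- s / rowSums(s)
  expect_true(all(w > 0))
  expect_equal(rowSums(w), rep(1, 7), tolerance = 1e-9)
  # degenerate cases
  expect_equal(lra_attention(q, k[1, , drop = FALSE], v[1, , drop = FALSE]),
               matrix(v[1, ], 7, 8, byrow = TRUE), tolerance = 1e-12)
  vsame <- matrix(rep(rnorm(8), each = 9), 9, 8)
  expect_equal(lra_attention(q, k, vsame), vsame[rep(1, 7), ],
               tolerance = 1e-9)
  expect_error(lra_attention(q, k[0, ], v[0, ]), "empty")
})

test_that("decoupled attention is linear in sequence length", {
  set.seed(5)
  q <- matrix(rnorm(10 * 4), 10, 4)
  kv <- matrix(rnorm(10 * 4), 10, 4)
  mem <- matrix(rnorm(4 * 4), 4, 4)
  lra_score_reset()
  out <- decoupled_lra(q, kv, mem)
  expect_equal(lra_score_count(), 80)  # N*c + c*L = 10*4 + 4*10
  expect_identical(dim(out$H), c(10L, 4L))
  expect_identical(dim(out$M_prime), c(4L, 4L))
  # c = 1: every query sees the same single compressed slot
  out1 <- decoupled_lra(q, kv, mem[1, , drop = FALSE])
  expect_equal(out1$H, out1$M_prime[rep(1, 10), ], tolerance = 1e-9)
  expect_error(decoupled_lra(q, kv, mem[0, , drop = FALSE]), "c >= 1")
  # linearity at other sizes
  for (sz in c(5L, 20L)) {
    lra_score_reset()
    decoupled_lra(matrix(rnorm(sz * 4), sz, 4),
                  matrix(rnorm(sz * 4), sz, 4), mem)
    expect_equal(lra_score_count(), sz * 4 + 4 * sz)
  }
})

test_that("trend normalization detrends and restores linear structure", {
  n <- 9
  slope_in <- c(0.5, -1, 2)
  x <- outer(seq_len(n), slope_in) + rep(c(1, 2, 3), each = n)
  dim(x) <- c(n, 3)
  expect_equal(trend_normalize(x, gamma = 1, beta = 0, rho = 1), x,
               tolerance = 1e-6)
  xc <- matrix(2.5, 6, 2)
  expect_equal(trend_normalize(xc), xc, tolerance = 1e-6)
  set.seed(6)
  h <- matrix(rnorm(12 * 4), 12, 4)
  out <- trend_normalize(h, gamma = 1.3, beta = 0.2, rho = 0.7)
  tr <- ricestor:::trend_projector(12) %*% h
  resid <- out - 0.7 * tr
  slopes <- apply(resid, 2, function(col) coef(lm(col ~ seq_len(12)))[2])
  expect_equal(unname(slopes), rep(0, 4), tolerance = 1e-8)
  expect_error(trend_normalize(h[1, , drop = FALSE]), "2 positions")
})

test_that("rotation regularizers match their hand-computed values", {
  expect_equal(omega_regularizer(matrix(c(0, 1, 3), 1)), 2.5)
  expect_equal(omega_regularizer(matrix(c(0, 1, 0, 2), 2, byrow = TRUE)), 2.5)
  expect_equal(omega_regularizer(matrix(0.3, 4, 6)), 0)
  expect_error(omega_regularizer(matrix(1, 2, 1)), "2 positions")
  expect_equal(theta_regularizer(matrix(c(1, -1), 1)), 1)
  expect_equal(theta_regularizer(matrix(c(2, -4), 2, 1)), 3)
  expect_equal(theta_regularizer(matrix(0, 3, 4)), 0)
  expect_error(theta_regularizer(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("the total loss decomposes into prediction and regularizer terms", {
  expect_equal(total_loss(c(1, 2), c(2, 2), lambda1 = 0, lambda2 = 0), 0.5)
  om <- matrix(c(0, 1, 3), 1)   # L_omega = 2.5
  th <- matrix(c(1, -1), 1)     # L_theta = 1
  l <- total_loss(c(0, 0), c(1, 1), list(om), list(th),
                  lambda1 = 0.5, lambda2 = 0.1)
  expect_equal(l, 1 + 0.5 * 2.5 + 0.1 * 1, tolerance = 1e-12)
  expect_equal(total_loss(1:3, 1:3, list(matrix(0, 1, 2)),
                          list(matrix(0, 1, 2))), 0)
  expect_error(total_loss(1:3, 1:2), "length")
  # decomposition identity on random inputs
  set.seed(7)
  for (i in 1:5) {
    pred <- rnorm(6); tgt <- rnorm(6)
    oms <- list(matrix(runif(8, 0, 0.5), 2, 4))
    ths <- list(matrix(rnorm(8), 2, 4))
    l1 <- total_loss(pred, tgt, oms, ths, 0.3, 0.7)
    l0 <- total_loss(pred, tgt, lambda1 = 0, lambda2 = 0)
    expect_equal(l1 - l0,
                 0.3 * omega_regularizer(oms[[1]]) +
                   0.7 * theta_regularizer(ths[[1]]),
                 tolerance = 1e-12)
  }
})
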