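test_that("Lloyd iterations reach the known optimum on the worked example", {
  pts <- cbind(c(0, 0.1, 5, 5.1), 0)
  km <- kmeans_lloyd(pts, 2, seed = 1)
  expect_equal(sort(km$centers[, 1]), c(0.05, 5.05))
  expect_equal(km$inertia, 0.01, tolerance = 1e-12)
  km1 <- kmeans_lloyd(pts, 1, seed = 1)
  expect_equal(km1$centers[1, ], colMeans(pts))
  kmn <- kmeans_lloyd(pts, 4, seed = 1)
  expect_equal(kmn$inertia, 0)
  expect_error(kmeans_lloyd(pts, 5, seed = 1), "exceeds")
  expect_error(kmeans_lloyd(pts, 0, seed = 1), "K must be")
})

test_that("restarted Lloyd attains the exhaustive-partition optimum on small sets", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    pts <- cbind(rnorm(n), rnorm(n))
    for (K in 2:3) {
      km <- kmeans_lloyd(pts, K, seed = rep, restarts = 10)
      opt <- kmeans_exhaustive(pts, K)
      expect_equal(km$inertia, opt, tolerance = 1e-9)
    }
  }
})

test_that("inertia is non-increasing over Lloyd iterations", {
  set.seed(22)
  pts <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
  km <- kmeans_lloyd(pts, 3, seed = 5, restarts = 3)
  hist <- ricestor:::lloyd_once(pts, 3, 300)$inertia_history
  expect_true(all(diff(hist) <= 1e-9))
})

test_that("the silhouette matches its definition-level oracle", {
  pts <- cbind(c(0, 0.1, 5, 5.1), 0)
  lab <- c(1, 1, 2, 2)
  s <- silhouette_index(pts, lab)
  expect_equal(s, silhouette_oracle(pts, lab), tolerance = 1e-12)
  expect_equal(s, 0.98, tolerance = 1e-3)
  set.seed(23)
  for (rep in 1:5) {
    pts <- matrix(rnorm(24), 12, 2)
    lab <- sample(1:3, 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_index(pts, lab), silhouette_oracle(pts, lab),
                 tolerance = 1e-12)
  }
  # coincident clusters at distinct locations: perfect separation
  pts2 <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_equal(silhouette_index(pts2, rep(1:2, each = 3)), 1)
  # all points coincident: 0/0 convention
  expect_equal(silhouette_index(matrix(0, 4, 2), c(1, 1, 2, 2)), 0)
  expect_error(silhouette_index(pts2, rep(1, 6)), "single cluster")
})

test_that("silhouette-based selection recovers planted tier counts", {
  m3 <- generate_tiered_m_samples(c(0.4, 1.2, 2.0), tier_sd = 0.06,
                                  n_per_tier = 40, seed = 31)
  sel <- select_k(as.matrix(m3[, 1:2]), 3:7, seed = 1)
  expect_identical(sel$best_k, 3L)
  m7 <- generate_tiered_m_samples(seq(0.5, 6.5, by = 1), tier_sd = 0.08,
                                  n_per_tier = 25, seed = 32)
  sel7 <- select_k(as.matrix(m7[, 1:2]), 3:7, seed = 1)
  expect_identical(sel7$best_k, 7L)
  expect_error(select_k(matrix(rnorm(10), 5, 2), 3:7), "at most n - 1")
  expect_error(select_k(matrix(rnorm(20), 10, 2), integer(0)), "non-empty")
})

test_that("grades order clusters by residue level with midpoint breakpoints", {
  cur <- c(0.5, 0.6, 1.0, 1.1, 2.0)
  samples <- build_m_index(cur, cur * 0.9, "testpest")
  km <- kmeans_lloyd(as.matrix(samples[, 1:2]), 3, seed = 1)
  gm <- grade_clusters(km, samples)
  expect_equal(gm$breakpoints, c(0.8, 1.55))
  expect_identical(gm$grades, c("High", "Medium", "Low"))
  expect_identical(gm$intervals$interval,
                   c("(0, 0.8)", "[0.8, 1.55]", "(1.55, +Inf)"))
  expect_true(all(diff(gm$clusters$d_current) > 0))
  expect_identical(gm$clusters$n, c(2L, 2L, 1L))
  # grade from intervals agrees with grade from cluster membership
  expect_identical(predict(gm, cur), gm$labels)
  # breakpoint values land in the closed middle interval
  expect_identical(predict(gm, c(0.8, 1.55)), c("Medium", "Medium"))
  # K = 2 generalization
  km2 <- kmeans_lloyd(as.matrix(samples[, 1:2]), 2, seed = 1)
  gm2 <- grade_clusters(km2, samples)
  expect_identical(gm2$grades, c("High", "Low"))
  expect_length(gm2$breakpoints, 1L)
})

test_that("the residue index pairs pass through unchanged", {
  m <- build_m_index(1.2, 1.1, "imidacloprid")
  expect_equal(unlist(m[1, 1:2], use.names = FALSE), c(1.2, 1.1))
  expect_equal(unlist(build_m_index(0, 0)[1, 1:2], use.names = FALSE), c(0, 0))
  expect_error(build_m_index(-0.1, 0.5), ">= 0")
  expect_error(build_m_index(0.5, -0.1), ">= 0")
})

test_that("grade models fitted end-to-end retain monotone grade means", {
  m <- generate_tiered_m_samples(c(0.3, 1.0, 2.2), tier_sd = 0.07,
                                 n_per_tier = 30, seed = 41)
  gm <- grade_model(build_m_index(m$d_current, m$d_predicted, "x"),
                    k_range = 3:5, seed = 1)
  expect_identical(gm$K, 3L)
  means <- tapply(m$d_current, gm$labels, mean)
  expect_lt(means[["High"]], means[["Medium"]])
  expect_lt(means[["Medium"]], means[["Low"]])
})
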