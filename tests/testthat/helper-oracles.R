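# Independent oracles used across the suite. These deliberately re-derive
# quantities from their definitions, not through the package's code paths.

# Plain scaled dot-product attention (softmax formulation).
plain_attention <- function(q, k, v) {
  s <- q %*% t(k) / sqrt(ncol(q))
  w <- exp(s)
  w <- w / rowSums(w)
  w %*% v
}

# Direct-formula forecast metrics.
metrics_oracle <- function(y, yhat) {
  n <- length(y)
  mse <- sum((yhat - y)^2) / n
  ape <- ifelse(y == 0 & yhat == y, 0, abs((yhat - y) / y))
  sden <- (abs(yhat) + abs(y)) / 2
  sape <- ifelse(sden == 0, 0, abs(yhat - y) / sden)
  list(mse = mse, rmse = sqrt(mse), mae = sum(abs(yhat - y)) / n,
       mape_pct = 100 * sum(ape) / n, smape_pct = 100 * sum(sape) / n)
}

# Definition-level silhouette, looping over samples and clusters.
silhouette_oracle <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  ed <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  vals <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { vals[i] <- 0; next }
    a <- mean(vapply(same, function(j) ed(i, j), numeric(1)))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == k)
      b <- min(b, mean(vapply(mem, function(j) ed(i, j), numeric(1))))
    }
    vals[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(vals)
}

# Exhaustive K-means optimum: minimum inertia over every assignment of n
# points to K labeled clusters (empty clusters allowed to be skipped).
kmeans_exhaustive <- function(points, K) {
  points <- as.matrix(points)
  n <- nrow(points)
  best <- Inf
  grid <- rep(list(seq_len(K)), n)
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    lab <- as.integer(combos[r, ])
    if (length(unique(lab)) < K) next
    inertia <- 0
    for (k in unique(lab)) {
      m <- points[lab == k, , drop = FALSE]
      ctr <- colMeans(m)
      inertia <- inertia + sum(sweep(m, 2, ctr)^2)
    }
    if (inertia < best) best <- inertia
  }
  best
}

# Noiseless single-compartment profile for kinetics checks.
mono_profile <- function(k = 0.2, C0 = 4, noise_sd = 0) {
  pesticide_profile("test", C0 = C0, fast_fraction = 1, k_base = k,
                    k_slow = k / 100 + 1e-9, T_opt = 25, sigma_T = 1e6,
                    H_opt = 65, sigma_H = 1e6, noise_sd = noise_sd)
}
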