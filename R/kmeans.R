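#' Lloyd's K-means with k-means++ seeding
#'
#' Implements the classical iteration: assign every point to the nearest
#' centroid by Euclidean distance (ties broken towards the lowest centroid
#' index), recompute each centroid as the coordinate mean of its members,
#' and repeat until assignments are unchanged or `max_iter` is reached.
#' Initial centroids come from k-means++ sampling; an emptied cluster is
#' re-seeded to the point farthest from its current centroid. The best of
#' `restarts` runs by within-cluster sum of squares (inertia) is returned.
#'
#' @param points n x d numeric matrix (rows are samples).
#' @param K Number of clusters, 1 <= K <= n.
#' @param seed Integer seed (each restart derives its own sub-seed).
#' @param restarts Number of independent initializations.
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `kmeans_lloyd`: list with `K`, `labels`
#'   (1-based), `centers` (K x d), `inertia`, `iter`.
#' @export
kmeans_lloyd <- function(points, K, seed = 1, restarts = 10, max_iter = 300) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of points (", n, ")")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer((seed * 131 + r) %% 2147483647))
    run <- lloyd_once(points, K, max_iter)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  structure(c(best, list(K = as.integer(K))), class = "kmeans_lloyd")
}

# squared Euclidean distances from every point to every center
sqdist_to <- function(points, centers) {
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") -
    2 * points %*% t(centers)
  pmax(d2, 0)
}

kmeanspp_init <- function(points, K) {
  n <- nrow(points)
  centers <- matrix(0, K, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  if (K > 1) for (j in 2:K) {
    d2 <- apply(sqdist_to(points, centers[seq_len(j - 1), , drop = FALSE]),
                1, min)
    if (sum(d2) == 0) {
      centers[j, ] <- points[sample.int(n, 1), ]
    } else {
      centers[j, ] <- points[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

lloyd_once <- function(points, K, max_iter) {
  n <- nrow(points)
  centers <- kmeanspp_init(points, K)
  labels <- rep(0L, n)
  inertia_history <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to(points, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    inertia_history <- c(inertia_history,
                         sum(d2[cbind(seq_len(n), new_labels)]))
    for (j in seq_len(K)) {
      members <- which(new_labels == j)
      if (length(members) == 0L) {
        # re-seed an emptied cluster to the globally farthest point
        far <- which.max(apply(d2, 1, min))
        new_labels[far] <- j
        members <- far
      }
      centers[j, ] <- colMeans(points[members, , drop = FALSE])
    }
    if (identical(new_labels, labels)) { labels <- new_labels; break }
    labels <- new_labels
  }
  d2 <- sqdist_to(points, centers)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia, iter = it,
       inertia_history = inertia_history)
}

#' @export
print.kmeans_lloyd <- function(x, ...) {
  cat(sprintf("<kmeans_lloyd> K=%d, inertia=%.6g, sizes: %s\n", x$K,
              x$inertia, paste(tabulate(x$labels, x$K), collapse = "/")))
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For sample i with mean within-cluster distance a(i) and mean distance
#' b(i) to the nearest other cluster, the silhouette is
#' `(b(i) - a(i)) / max(a(i), b(i))`; the score is the average over all
#' samples. A sample alone in its cluster contributes 0, as does a sample
#' with `a(i) = b(i) = 0` (coincident points).
#'
#' @param points n x d matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette undefined for a single cluster")
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / n_own
    b <- min(vapply(ks[ks != labels[i]], function(k)
      mean(dm[i, labels == k]), numeric(1)))
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs [kmeans_lloyd()] for each candidate K and returns the K with the
#' highest mean silhouette, ties broken towards the smaller K.
#'
#' @param points n x d matrix.
#' @param k_range Candidate cluster counts (default 3..7).
#' @param seed,restarts Passed to [kmeans_lloyd()].
#' @return List with `best_k`, `silhouettes` (named by K) and `fits` (the
#'   `kmeans_lloyd` objects).
#' @export
select_k <- function(points, k_range = 3:7, seed = 1, restarts = 10) {
  points <- as.matrix(points)
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (max(k_range) > nrow(points) - 1L)
    stop("largest candidate K (", max(k_range),
         ") must be at most n - 1 = ", nrow(points) - 1L)
  fits <- lapply(k_range, function(k)
    kmeans_lloyd(points, k, seed = seed + k, restarts = restarts))
  sil <- vapply(seq_along(k_range), function(i)
    silhouette_index(points, fits[[i]]$labels), numeric(1))
  names(sil) <- k_range
  best <- k_range[which.max(sil)]  # which.max takes the first (smallest K)
  list(best_k = as.integer(best), silhouettes = sil, fits = fits)
}
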