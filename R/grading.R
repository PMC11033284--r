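#' Build the paired residue quality index
#'
#' The clustering feature for quality grading pairs the measured residue of
#' a pesticide with its model-predicted next-step residue: `M = [d_current,
#' d_predicted]`. Both components stay on the mg/kg scale; no scaling is
#' applied at this stage.
#'
#' @param current Measured residue(s), mg/kg, >= 0.
#' @param predicted Predicted residue(s), mg/kg, >= 0; same length.
#' @param pesticide Pesticide identifier (recycled).
#' @return Data frame with columns `d_current`, `d_predicted`, `pesticide`.
#' @export
build_m_index <- function(current, predicted, pesticide = "pesticide") {
  if (length(current) != length(predicted))
    stop("current and predicted must have the same length")
  if (any(!is.finite(current)) || any(current < 0) ||
      any(!is.finite(predicted)) || any(predicted < 0))
    stop("residue values must be finite and >= 0")
  data.frame(d_current = as.numeric(current),
             d_predicted = as.numeric(predicted),
             pesticide = rep_len(as.character(pesticide), length(current)),
             stringsAsFactors = FALSE)
}

grade_names <- function(K) {
  if (K == 2L) c("High", "Low")
  else if (K == 3L) c("High", "Medium", "Low")
  else paste0("Grade ", seq_len(K))
}

#' Turn a clustering of the quality index into a grade model
#'
#' Clusters are ordered by ascending centre residue (`d_current`) and
#' assigned grades from best (lowest residue) to worst. The breakpoint
#' between adjacent grades is the midpoint of the largest `d_current` in the
#' better cluster and the smallest in the worse cluster, giving
#' concentration intervals `(0, b1)` for the best grade, closed intervals
#' `[b_i, b_i+1]` in between, and `(b_K-1, +Inf)` for the worst.
#'
#' @param result A [kmeans_lloyd()] fit of the index samples (K >= 2).
#' @param samples The clustered samples: data frame with `d_current` and
#'   `d_predicted` (as from [build_m_index()]).
#' @param pesticide Optional identifier stored with the model.
#' @return An object of class `grade_model`: list with `K`, `grades`,
#'   `breakpoints`, `intervals` (grade interval table), `clusters`
#'   (per-grade centres and sample sizes), `labels` (per-sample grades) and
#'   `silhouette`.
#' @export
grade_clusters <- function(result, samples, pesticide = NULL) {
  stopifnot(inherits(result, "kmeans_lloyd"))
  if (result$K < 2L) stop("grading needs at least 2 clusters")
  if (nrow(samples) != length(result$labels))
    stop("samples and clustering disagree in size")
  K <- result$K
  ord <- order(result$centers[, 1])
  rank_of <- match(seq_len(K), ord)

  lim <- t(vapply(seq_len(K), function(j) {
    v <- samples$d_current[result$labels == j]
    c(min(v), max(v))
  }, numeric(2)))
  lim <- lim[ord, , drop = FALSE]  # best (lowest residue) first

  breakpoints <- numeric(K - 1L)
  for (i in seq_len(K - 1L)) {
    breakpoints[i] <- (lim[i, 2] + lim[i + 1, 1]) / 2
  }
  if (K > 2L && any(diff(breakpoints) <= 0)) {
    bad <- which(diff(breakpoints) <= 0)[1]
    stop("clusters overlap on d_current: breakpoints between grades ",
         bad, "-", bad + 1L, " and ", bad + 1L, "-", bad + 2L,
         " are non-increasing")
  }
  grades <- grade_names(K)

  lo <- c(0, breakpoints)
  hi <- c(breakpoints, Inf)
  bracket <- vapply(seq_len(K), function(i) {
    if (i == 1L) sprintf("(0, %.4g)", hi[1])
    else if (i == K) sprintf("(%.4g, +Inf)", lo[K])
    else sprintf("[%.4g, %.4g]", lo[i], hi[i])
  }, character(1))

  labels_grade <- grades[rank_of[result$labels]]
  centers_sorted <- result$centers[ord, , drop = FALSE]
  clusters <- data.frame(
    grade = grades,
    d_current = centers_sorted[, 1],
    d_predicted = centers_sorted[, 2],
    n = as.integer(tabulate(result$labels, K)[ord]),
    stringsAsFactors = FALSE)
  intervals <- data.frame(grade = grades, interval = bracket,
                          lower = lo, upper = hi, stringsAsFactors = FALSE)

  structure(list(K = K, grades = grades, breakpoints = breakpoints,
                 intervals = intervals, clusters = clusters,
                 labels = labels_grade,
                 silhouette = silhouette_index(
                   as.matrix(samples[, c("d_current", "d_predicted")]),
                   result$labels),
                 pesticide = pesticide, kmeans = result),
            class = "grade_model")
}

#' Fit a quality grade model to index samples
#'
#' Convenience wrapper: clusters the (measured, predicted) residue pairs
#' with [kmeans_lloyd()], choosing K by silhouette over `k_range` unless `k`
#' is given, and converts the result into grade intervals with
#' [grade_clusters()].
#'
#' @param samples Data frame from [build_m_index()] (one pesticide).
#' @param k Fixed number of grades, or `NULL` to select by silhouette.
#' @param k_range Candidate K values when `k` is `NULL`.
#' @param seed,restarts Passed to the clustering.
#' @return A `grade_model`; when K was selected, the per-K silhouettes are
#'   attached as `$selection`.
#' @export
grade_model <- function(samples, k = NULL, k_range = 3:7, seed = 1,
                        restarts = 10) {
  pts <- as.matrix(samples[, c("d_current", "d_predicted")])
  sel <- NULL
  if (is.null(k)) {
    sel <- select_k(pts, k_range, seed = seed, restarts = restarts)
    fit <- sel$fits[[match(sel$best_k, k_range)]]
  } else {
    fit <- kmeans_lloyd(pts, k, seed = seed, restarts = restarts)
  }
  gm <- grade_clusters(fit, samples,
                       pesticide = if ("pesticide" %in% names(samples))
                         samples$pesticide[1] else NULL)
  gm$selection <- if (is.null(sel)) NULL else sel$silhouettes
  gm
}

#' Assign grades to residue concentrations from the fitted intervals
#'
#' Values below the first breakpoint take the best grade, values above the
#' last take the worst; a value exactly on a breakpoint goes to the closed
#' (middle) interval that carries it.
#'
#' @param object A `grade_model`.
#' @param newdata Numeric residue concentrations (mg/kg), or a data frame
#'   with a `d_current` column.
#' @param ... Unused.
#' @return Character vector of grades.
#' @export
predict.grade_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$d_current else as.numeric(newdata)
  bp <- object$breakpoints
  K <- object$K
  idx <- vapply(x, function(v) {
    on_bp <- which(v == bp)
    if (length(on_bp)) {
      i <- on_bp[1]
      if (K == 2L) 2L else min(i + 1L, K - 1L)
    } else {
      sum(v > bp) + 1L
    }
  }, integer(1))
  object$grades[idx]
}

#' @export
print.grade_model <- function(x, ...) {
  cat(sprintf("<grade_model>%s K=%d, silhouette=%.4f\n",
              if (!is.null(x$pesticide)) paste0(" ", x$pesticide) else "",
              x$K, x$silhouette))
  tab <- merge(x$clusters, x$intervals[, c("grade", "interval")],
               by = "grade", sort = FALSE)
  print(tab, row.names = FALSE)
  if (!is.null(x$selection)) {
    cat("silhouette by K: ",
        paste(sprintf("%s=%.3f", names(x$selection), x$selection),
              collapse = ", "), "\n")
  }
  invisible(x)
}
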