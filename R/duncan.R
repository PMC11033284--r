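#' Duncan's multiple range test with compact letter display
#'
#' Post-hoc comparison of group means after one-way ANOVA. Means are ranked
#' and a span of `p` consecutive ranked means is declared homogeneous when
#' its range does not exceed the critical range
#' \deqn{R_p = q(\alpha_p, p, df_e) \sqrt{MS_e / n},}
#' with Duncan's protection level `alpha_p = 1 - (1 - alpha)^(p - 1)`, `q`
#' the studentized-range quantile, `MS_e` and `df_e` the ANOVA error mean
#' square and degrees of freedom, and `n` the (harmonic mean) group size.
#' Testing proceeds from the widest span downwards; a span inside a
#' non-significant wider span is never declared significant. The result is
#' the usual letter display: groups sharing a letter do not differ at level
#' `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level.
#' @return An object of class `duncan_mrt`: list with a `groups` data frame
#'   (`group`, `mean`, `sd`, `n`, `letters`), `ms_error`, `df_error`,
#'   `alpha`, and the critical ranges used.
#' @examples
#' duncan_mrt(list(a = c(-0.1, 0, 0.1), b = c(9.9, 10, 10.1)))
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("G", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  n_tot <- sum(ns)
  ms_error <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                         numeric(1))) / (n_tot - k)
  df_error <- n_tot - k
  n_h <- k / sum(1 / ns)  # harmonic mean group size (equal n: n itself)

  ord <- order(means, decreasing = TRUE)  # ranked means, largest first
  m_sorted <- means[ord]

  crit <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df_error) * sqrt(ms_error / n_h)
  }, numeric(1))
  names(crit) <- paste0("R", 2:k)

  # step-down range testing: a span failing to exceed its critical range is
  # homogeneous, and its sub-spans are protected (never re-tested).
  homog <- matrix(FALSE, k, k)
  test_span <- function(i, j) {
    if (j <= i) return(invisible(NULL))
    p <- j - i + 1L
    r_p <- if (ms_error == 0) 0 else crit[p - 1L]
    if (m_sorted[i] - m_sorted[j] <= r_p) {
      homog[i:j, i:j] <<- TRUE
    } else {
      test_span(i, j - 1L)
      test_span(i + 1L, j)
    }
  }
  test_span(1L, k)
  diag(homog) <- TRUE

  # insert-and-absorb: letters are the maximal homogeneous runs
  runs <- list()
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && homog[i, j + 1L]) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
    i <- i + 1L
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs)) {
    if (a != b && keep[a] && all(runs[[a]] %in% runs[[b]])) keep[a] <- FALSE
  }
  runs <- runs[keep]
  letter_sets <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(runs, function(r) g %in% r, logical(1)))],
           collapse = "")
  }, character(1))

  tab <- data.frame(group = names(groups)[ord], mean = m_sorted,
                    sd = sds[ord], n = as.integer(ns[ord]),
                    letters = letter_sets, stringsAsFactors = FALSE)
  structure(list(groups = tab, ms_error = ms_error, df_error = df_error,
                 alpha = alpha, critical_ranges = crit),
            class = "duncan_mrt")
}

#' Are any two groups declared different?
#'
#' @param x A `duncan_mrt` result.
#' @return `TRUE` if at least one pair of groups shares no letter.
#' @export
any_difference <- function(x) {
  stopifnot(inherits(x, "duncan_mrt"))
  ls <- strsplit(x$groups$letters, "")
  k <- length(ls)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!length(intersect(ls[[i]], ls[[j]]))) return(TRUE)
  }
  FALSE
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, MS_error = %.4g, df = %d)\n",
              x$alpha, x$ms_error, x$df_error))
  with(x$groups, cat(sprintf("  %-20s %.3g +/- %.3g ^%s (n=%d)\n",
                             group, mean, sd, letters, n), sep = ""))
  invisible(x)
}
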