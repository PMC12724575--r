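#' Normality-gated two-sample comparison
#'
#' Compares two independent samples the way sex-based cohort differences
#' in activity metrics are assessed: Shapiro-Wilk normality on each group
#' at `alpha_norm`; when both groups pass, a two-sided Welch two-sample
#' t-test (unequal variances, Welch-Satterthwaite degrees of freedom);
#' otherwise a two-sided Mann-Whitney U test, exact when the combined
#' sample size is at most 20 and there are no ties, else the normal
#' approximation with continuity and tie correction. Constant samples
#' (normality undefined) fall through to Mann-Whitney.
#'
#' @param x,y Numeric samples, each of size >= 3.
#' @param alpha_norm Normality-gate level (default 0.05).
#' @param metric Label carried on the result.
#' @return An object of class `comparison_result`: `metric`, `test_used`
#'   (`"welch_t"` or `"mann_whitney_u"`), `statistic`, `p_value`,
#'   `group_summaries` (mean, sd, n per group), `normality_p`.
#' @export
compare_groups <- function(x, y, alpha_norm = 0.05, metric = "metric") {
  x <- as.double(x); y <- as.double(y)
  if (length(x) < 3L || length(y) < 3L) {
    vz_validation_error("each sample must contain at least 3 values")
  }
  norm_p <- vapply(list(x, y), function(s) {
    if (length(unique(s)) < 2L) return(NA_real_)  # constant: undefined
    stats::shapiro.test(s)$p.value
  }, numeric(1))
  both_normal <- all(!is.na(norm_p)) && all(norm_p >= alpha_norm)
  if (both_normal) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test_used <- "welch_t"
  } else {
    exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
    test_used <- "mann_whitney_u"
  }
  structure(
    list(
      metric = metric,
      test_used = test_used,
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      group_summaries = data.frame(
        group = c("x", "y"),
        mean = c(mean(x), mean(y)),
        sd = c(stats::sd(x), stats::sd(y)),
        n = c(length(x), length(y))
      ),
      normality_p = norm_p
    ),
    class = "comparison_result"
  )
}

#' Welch t-test from summary statistics
#'
#' Computes the Welch two-sample t statistic, Welch-Satterthwaite degrees
#' of freedom and two-sided p-value from group means, standard deviations
#' and sizes alone, so published mean +/- SD tables can be re-tested
#' without raw data.
#'
#' @param mean1,sd1,n1 First group summary; `sd1 > 0`, `n1 >= 2`.
#' @param mean2,sd2,n2 Second group summary.
#' @param metric Label carried on the result.
#' @return A `comparison_result` (with `df` added and `normality_p = NA`).
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, metric = "metric") {
  if (n1 < 2 || n2 < 2) vz_validation_error("group sizes must be at least 2")
  if (sd1 <= 0 || sd2 <= 0) vz_validation_error("standard deviations must be positive")
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(
      metric = metric,
      test_used = "welch_t",
      statistic = t_stat,
      df = df,
      p_value = p,
      group_summaries = data.frame(
        group = c("x", "y"), mean = c(mean1, mean2),
        sd = c(sd1, sd2), n = c(n1, n2)
      ),
      normality_p = c(NA_real_, NA_real_)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  marker <- if (x$test_used == "mann_whitney_u") " (μ)" else ""
  g <- x$group_summaries
  cat(sprintf(
    "%s%s: %.2f ± %.2f (n=%d) vs %.2f ± %.2f (n=%d), p = %s\n",
    x$metric, marker, g$mean[1], g$sd[1], g$n[1], g$mean[2], g$sd[2], g$n[2],
    format.pval(x$p_value, digits = 3, eps = 0.001)
  ))
  invisible(x)
}

#' Compare two cohorts metric by metric
#'
#' Runs the normality-gated comparison for every shared numeric metric of
#' two cohort profile tables (as produced by [cohort_profiles()]).
#'
#' @param profiles_x,profiles_y Data frames of per-match profiles.
#' @param metrics Character vector of column names to compare; defaults to
#'   all shared numeric columns.
#' @param alpha_norm Normality-gate level.
#' @param p_adjust `"none"` (default, per-metric reporting) or any
#'   [stats::p.adjust()] method such as `"holm"`.
#' @return A data frame: metric, per-group mean/sd/n, test used,
#'   statistic, p-value (and adjusted p when requested).
#' @export
compare_cohorts <- function(profiles_x, profiles_y, metrics = NULL,
                            alpha_norm = 0.05, p_adjust = "none") {
  if (is.null(metrics)) {
    shared <- intersect(names(profiles_x), names(profiles_y))
    metrics <- shared[vapply(shared, function(m) is.numeric(profiles_x[[m]]), logical(1))]
  }
  rows <- lapply(metrics, function(m) {
    res <- compare_groups(profiles_x[[m]], profiles_y[[m]], alpha_norm, metric = m)
    g <- res$group_summaries
    data.frame(
      metric = m,
      mean_x = g$mean[1], sd_x = g$sd[1], n_x = g$n[1],
      mean_y = g$mean[2], sd_y = g$sd[2], n_y = g$n[2],
      test = res$test_used, statistic = res$statistic, p_value = res$p_value
    )
  })
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
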