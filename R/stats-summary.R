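# Group comparisons reconstructable from published summary statistics.
#
# One-way ANOVA, the Scheffe post hoc contrasts and the pooled two-sample t
# are computed directly from (n, mean, sd) triples, so that printed cohort
# tables can be re-analysed without patient-level data. The summary-based
# ANOVA is algebraically identical to a raw-data one-way ANOVA on any
# dataset with those summaries.

#' Group summary triple
#'
#' @param label Group label.
#' @param n Group size (>= 1; >= 2 for variance-based tests).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_lcshift("group n must be >= 1")
  if (!is_scalar_number(mean)) stop_lcshift("group mean must be a number")
  if (!is_scalar_number(sd) || sd < 0) stop_lcshift("group sd must be >= 0")
  structure(list(label = as.character(label), n = n, mean = mean, sd = sd),
            class = "group_summary")
}

check_groups <- function(groups, min_k = 2L) {
  if (inherits(groups, "group_summary")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, logical(1L), "group_summary")))
  if (length(groups) < min_k)
    stop_lcshift("need at least ", min_k, " groups")
  n <- vapply(groups, `[[`, integer(1L), "n")
  if (any(n < 2L))
    stop_lcshift("every group needs n >= 2 for variance-based tests")
  list(n = n,
       mean = vapply(groups, `[[`, numeric(1L), "mean"),
       sd = vapply(groups, `[[`, numeric(1L), "sd"),
       label = vapply(groups, `[[`, character(1L), "label"))
}

#' Pearson chi-square test for a contingency table
#'
#' Pearson statistic without continuity correction, with
#' df = (r - 1)(c - 1) and an upper-tail chi-square p-value.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_test <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop_lcshift("contingency table must contain nonnegative integer counts")
  if (sum(m) <= 0) stop_lcshift("contingency table is empty")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_lcshift("zero marginal row/column: chi-square test undefined")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs between/within sums of squares from per-group (n, mean, sd):
#' SSW = sum((n_i - 1) sd_i^2), SSB = sum(n_i (m_i - grand mean)^2).
#'
#' @param groups List of [group_summary()] objects (>= 2, each n >= 2).
#' @return List with `F`, `df1`, `df2`, `p_value`, `grand_mean`.
#' @export
anova_from_summary <- function(groups) {
  g <- check_groups(groups)
  N <- sum(g$n); k <- length(g$n)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, df1 = k - 1, df2 = N - k,
       p_value = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       grand_mean = grand)
}

#' Scheffe post hoc pairwise comparisons from summaries
#'
#' For each pair (i, j) the Scheffe-adjusted p-value is the upper tail of
#' F(k - 1, N - k) at the pairwise contrast statistic divided by (k - 1).
#' Every pairwise p is >= the overall ANOVA p.
#'
#' @inheritParams anova_from_summary
#' @return Symmetric matrix of adjusted p-values with group labels.
#' @export
scheffe_posthoc <- function(groups) {
  g <- check_groups(groups)
  N <- sum(g$n); k <- length(g$n)
  msw <- sum((g$n - 1) * g$sd^2) / (N - k)
  p <- matrix(1, k, k, dimnames = list(g$label, g$label))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      fij <- (g$mean[i] - g$mean[j])^2 /
        (msw * (1 / g$n[i] + 1 / g$n[j])) / (k - 1)
      p[i, j] <- p[j, i] <- stats::pf(fij, k - 1, N - k, lower.tail = FALSE)
    }
  }
  p
}

#' Two-sample t test from summaries
#'
#' Pooled-variance Student t by default (`pooled = FALSE` gives the Welch
#' variant), two-sided p-value.
#'
#' @param a,b [group_summary()] objects with n >= 2.
#' @param pooled Use the pooled-variance (Student) test (default `TRUE`).
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  g <- check_groups(list(a, b))
  n1 <- g$n[1L]; n2 <- g$n[2L]; m1 <- g$mean[1L]; m2 <- g$mean[2L]
  v1 <- g$sd[1L]^2; v2 <- g$sd[2L]^2
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
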