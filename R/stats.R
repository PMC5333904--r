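#' Paired-test result objects
#'
#' Lightweight container for the paired tests used by the evaluation
#' protocol: fields `test`, `statistic`, `p_two_tailed`, `effect_size`
#' (Wilcoxon r or Cohen's q, `NA` otherwise), `n_pairs`, `df` (`NA` where
#' not applicable).
#'
#' @name paired_test
NULL

new_paired_test <- function(test, statistic, p, effect_size = NA_real_,
                            n_pairs = NA_integer_, df = NA_real_, extra = NULL) {
  out <- structure(list(test = test, statistic = statistic,
                        p_two_tailed = p, effect_size = effect_size,
                        n_pairs = n_pairs, df = df),
                   class = "paired_test")
  out[names(extra)] <- extra
  out
}

#' @export
print.paired_test <- function(x, ...) {
  lab <- switch(x$test,
                wilcoxon = sprintf("Wilcoxon signed-rank: Z = %.2f, p = %.3g, r = %.2f (N = %d)",
                                   x$statistic, x$p_two_tailed, x$effect_size, 2L * x$n_pairs),
                pitman_morgan = sprintf("Pitman-Morgan: t(%d) = %.2f, p = %.3g",
                                        x$df, x$statistic, x$p_two_tailed),
                steiger = sprintf("Steiger's Z = %.2f, p = %.3g, Cohen's q = %.2f (%s)",
                                  x$statistic, x$p_two_tailed, x$effect_size,
                                  x$q_magnitude %||% ""),
                sprintf("%s: statistic = %.3f, p = %.3g", x$test, x$statistic,
                        x$p_two_tailed))
  cat(lab, "\n")
  invisible(x)
}

#' @export
as.data.frame.paired_test <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic,
             p_two_tailed = x$p_two_tailed, effect_size = x$effect_size,
             n_pairs = x$n_pairs, df = x$df, stringsAsFactors = FALSE)
}

#' Two-tailed Wilcoxon signed-rank test with normal approximation
#'
#' The convention used throughout the evaluation tables: zero differences
#' are dropped; ranks of tied absolute differences are averaged; the
#' standard normal deviate is
#' `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' with no continuity correction (the only convention under which n = 20
#' one-signed untied pairs give the saturated |Z| = 3.92); the two-tailed p
#' comes from the normal, and the effect size is `r = Z / sqrt(N)` with
#' `N = 2 * n_pairs` observations. Z is positive when `x` tends to exceed
#' `y`.
#'
#' @param x,y Paired numeric samples (at least 5 non-zero differences).
#' @return A [paired_test] with `statistic` = Z and `effect_size` = r.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n < 5L) stop("need at least 5 non-zero pairs, got ", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  if (sigma2 <= 0) stop("degenerate variance (all differences tied at one rank)")
  Z <- (W - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(Z))
  new_paired_test("wilcoxon", Z, p, effect_size = Z / sqrt(2 * n),
                  n_pairs = n)
}

#' Pitman-Morgan test for variances of two correlated samples
#'
#' Tests equality of the variances of paired samples via the correlation of
#' their sums and differences: with `r = cor(x + y, x - y)`,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-tailed. t is positive when `x` is more variable than `y`.
#'
#' @param x,y Paired numeric samples, `n >= 3`, each with non-zero variance.
#' @return A [paired_test] with `statistic` = t and `df` = n - 2.
#' @export
pitman_morgan <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the samples")
  if (stats::sd(x - y) < 1e-12 * (stats::sd(x) + stats::sd(y))) {
    # y is a pure shift of x: the variances are equal by construction
    return(new_paired_test("pitman_morgan", 0, 1, n_pairs = n, df = n - 2L))
  }
  r <- stats::cor(x + y, x - y)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  new_paired_test("pitman_morgan", tstat, p, n_pairs = n, df = n - 2L)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Tests `H0: rho(j,1) = rho(j,2)` where both correlations share the index
#' variable j (here: subject age against a volume series before and after
#' standardisation), using Fisher-transformed correlations and the pooled-r
#' asymptotic covariance (Steiger's common-index Z* with mean r):
#' `Z = (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * s)` where `s` is the
#' covariance of the two Fisher z's implied by `r_12`, the correlation of
#' the two non-shared variables. The effect size is Cohen's
#' `q = |z(r_j1) - z(r_j2)|`, graded small/medium/large at 0.10/0.30/0.50.
#'
#' @param r_j1,r_j2 Correlations of the shared variable with series 1 and 2,
#'   both strictly inside (-1, 1).
#' @param r_12 Correlation between series 1 and 2.
#' @param n Number of subjects (>= 4).
#' @return A [paired_test] with `statistic` = Z, `effect_size` = q, and an
#'   extra `q_magnitude` grade.
#' @export
steiger_dependent_correlations <- function(r_j1, r_j2, r_12, n) {
  for (r in c(r_j1, r_j2, r_12))
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations must lie strictly inside (-1, 1)")
  if (n < 4L) stop("need n >= 4")
  z1 <- atanh(r_j1); z2 <- atanh(r_j2)
  rbar <- (r_j1 + r_j2) / 2
  # pooled-r covariance of the dependent correlations
  psi <- r_12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_12^2)
  s <- psi / (1 - rbar^2)^2
  s <- min(max(s, -1), 1)
  Z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * s)
  p <- 2 * stats::pnorm(-abs(Z))
  q <- abs(z1 - z2)
  grade <- if (q < 0.10) "negligible" else if (q < 0.30) "small"
           else if (q < 0.50) "medium" else "large"
  new_paired_test("steiger", Z, p, effect_size = q, n_pairs = as.integer(n),
                  extra = list(q_magnitude = grade, r_j1 = r_j1, r_j2 = r_j2,
                               r_12 = r_12))
}

#' Cohen's q for a difference of correlations
#'
#' `q = |atanh(r1) - atanh(r2)|`; 0.10 / 0.30 / 0.50 are the conventional
#' small / medium / large benchmarks.
#'
#' @param r1,r2 Correlations strictly inside (-1, 1).
#' @return Numeric q.
#' @export
cohens_q <- function(r1, r2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must be inside (-1, 1)")
  abs(atanh(r1) - atanh(r2))
}

#' Test-retest intra-class correlation, ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measures ICC for two rating
#' runs of the same rater: `(MS_subjects - MS_error) / (MS_subjects +
#' (k - 1) MS_error)` from the two-way ANOVA without interaction (k = 2
#' runs). Consistency ICC is 1 for `run2 = run1 + constant`.
#'
#' @param run1,run2 Paired rating vectors, length >= 3, with between-subject
#'   variance.
#' @return ICC in \[-1, 1\].
#' @export
icc_test_retest <- function(run1, run2) {
  if (length(run1) != length(run2)) stop("runs must be paired")
  n <- length(run1)
  if (n < 3L) stop("need at least 3 subjects")
  Y <- cbind(run1, run2)
  if (stats::var(rowMeans(Y)) == 0)
    stop("zero variance across subjects; ICC undefined")
  k <- 2L
  subj_means <- rowMeans(Y)
  run_means <- colMeans(Y)
  grand <- mean(Y)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_run <- n * sum((run_means - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_run
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}

#' Maintenance of the volume-age correlation under standardisation
#'
#' Biological variance in tissue volumes must survive intensity
#' standardisation: the Pearson correlation between per-subject tissue
#' volumes and subject age should be unchanged after standardising and
#' re-segmenting. Computes `r(age, before)`, `r(age, after)` and
#' `r(before, after)` and applies [steiger_dependent_correlations()]; a
#' significant change (p < alpha) flags the standardisation as having
#' altered the biological pattern.
#'
#' @param volumes_before,volumes_after Per-subject volumes (mm^3), aligned.
#' @param age Per-subject ages (years).
#' @param alpha Significance level for the change flag (default 0.05).
#' @return List: `r_before`, `r_after`, `r_volumes`, `test` (a
#'   [paired_test]), `changed` (logical flag).
#' @export
correlation_maintenance <- function(volumes_before, volumes_after, age,
                                    alpha = 0.05) {
  n <- length(age)
  if (length(volumes_before) != n || length(volumes_after) != n)
    stop("subject vectors must be aligned")
  if (n < 4L) stop("need at least 4 subjects")
  for (v in list(volumes_before, volumes_after, age))
    if (stats::sd(v) == 0) stop("constant vector: correlation undefined")
  r_before <- stats::cor(age, volumes_before)
  r_after <- stats::cor(age, volumes_after)
  r_vol <- stats::cor(volumes_before, volumes_after)
  if (isTRUE(all.equal(volumes_before, volumes_after))) {
    test <- new_paired_test("steiger", 0, 1, effect_size = 0,
                            n_pairs = as.integer(n),
                            extra = list(q_magnitude = "negligible",
                                         r_j1 = r_before, r_j2 = r_after,
                                         r_12 = 1))
  } else {
    test <- steiger_dependent_correlations(r_before, r_after, r_vol, n)
  }
  list(r_before = r_before, r_after = r_after, r_volumes = r_vol,
       test = test, changed = test$p_two_tailed < alpha)
}
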