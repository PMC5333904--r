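test_that("the saturated Wilcoxon Z at n = 20 is 3.92", {
  x <- 1:20 + 10
  y <- x - seq(1, 20)   # distinct, all-positive differences: no ties, one sign
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(abs(w$statistic), 3.92, tolerance = 0.005)
  expect_equal(round(w$effect_size, 2), 0.62)
  expect_equal(w$n_pairs, 20L)
  # reversing the samples flips the sign only
  w2 <- wilcoxon_signed_rank(y, x)
  expect_equal(w2$statistic, -w$statistic)
})

test_that("Wilcoxon conventions: zero-drop, tie correction, no continuity correction", {
  set.seed(21)
  x <- rnorm(18); y <- x + c(rep(0, 3), rnorm(15))
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$n_pairs, 15L)  # zeros dropped
  # cross-check p against the reference implementation without correction
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(w$p_two_tailed, ref$p.value, tolerance = 1e-10)
  # tie-corrected variance: duplicate magnitudes must not error
  xt <- c(1, 2, 2, 3, 3, 4, 5, 6)
  wt <- wilcoxon_signed_rank(xt, rep(0, 8))
  reft <- suppressWarnings(wilcox.test(xt, rep(0, 8), paired = TRUE,
                                       exact = FALSE, correct = FALSE))
  expect_equal(wt$p_two_tailed, reft$p.value, tolerance = 1e-10)

  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), "zero")
  expect_error(wilcoxon_signed_rank(1:4, c(2, 3, 4, 5)), "at least 5")
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0, 1, 2, 3, 4, 5),
                                    c(0, 0, 0, 0, 1, 2, 3, 4, 5) - c(rep(0, 8), 1)),
               "at least 5")
})

test_that("effect size r = Z / sqrt(2 n)", {
  x <- 1:20 + rep(c(2, -1), 10) * seq(0.1, 2, length.out = 20)
  w <- wilcoxon_signed_rank(x, 1:20)
  expect_equal(w$effect_size, w$statistic / sqrt(40))
})

test_that("Pitman-Morgan compares correlated variances on n - 2 df", {
  set.seed(31)
  x <- rnorm(20, sd = 3)
  # same SD: shifting cannot change the variance
  pm0 <- pitman_morgan(x, x + 5)
  expect_equal(pm0$statistic, 0, tolerance = 1e-12)
  expect_equal(pm0$df, 18L)

  y <- 0.5 * x + rnorm(20, sd = 0.5)
  pm <- pitman_morgan(x, y)
  expect_equal(pm$df, 18L)
  expect_gt(pm$statistic, 0)  # x more variable
  # invariance to adding one constant to both samples
  pm_shift <- pitman_morgan(x + 1234, y + 1234)
  expect_equal(pm_shift$statistic, pm$statistic, tolerance = 1e-9)

  expect_error(pitman_morgan(rep(1, 10), rnorm(10)), "variance")
  expect_error(pitman_morgan(1:2, 2:3), "at least 3")
})

test_that("Pitman-Morgan rejection rate matches a sign-flip permutation oracle", {
  set.seed(41)
  n <- 20; reps <- 120; nperm <- 160
  rej_t <- 0; rej_perm <- 0
  for (r in seq_len(reps)) {
    base <- rnorm(n)
    x <- 5.3 * base + rnorm(n, sd = 1.5)
    y <- 2.5 * base + rnorm(n, sd = 1.5)
    pm <- pitman_morgan(x, y)
    rej_t <- rej_t + (pm$p_two_tailed < 0.05)
    obs <- abs(var(x) - var(y))
    stat <- replicate(nperm, {
      swap <- runif(n) < 0.5
      xs <- ifelse(swap, y, x); ys <- ifelse(swap, x, y)
      abs(var(xs) - var(ys))
    })
    p_perm <- (1 + sum(stat >= obs)) / (nperm + 1)
    rej_perm <- rej_perm + (p_perm < 0.05)
  }
  # both should reject nearly always at these variance ratios
  expect_gt(rej_t / reps, 0.9)
  expect_lt(abs(rej_t - rej_perm) / reps, 0.1)
})

test_that("Steiger's test is zero under equality and grades Cohen's q", {
  s0 <- steiger_dependent_correlations(0.5, 0.5, 0.6, 20)
  expect_equal(s0$statistic, 0)
  expect_equal(s0$effect_size, 0)
  q <- cohens_q(0.66, 0.20)
  expect_equal(q, abs(atanh(0.66) - atanh(0.20)))
  expect_equal(round(q, 3), 0.590)
  s <- steiger_dependent_correlations(0.66, 0.20, 0.5, 20)
  expect_equal(s$q_magnitude, "large")
  expect_error(steiger_dependent_correlations(1, 0.5, 0.5, 20), "inside")
})

test_that("Steiger's Z matches an independent formula transcription and is calibrated", {
  # independent implementation, written directly from the published equation
  steiger_oracle <- function(r_j1, r_j2, r_12, n) {
    z1 <- 0.5 * log((1 + r_j1) / (1 - r_j1))
    z2 <- 0.5 * log((1 + r_j2) / (1 - r_j2))
    rb <- (r_j1 + r_j2) / 2
    psi <- r_12 * (1 - rb^2 - rb^2) - 0.5 * rb^2 * (1 - rb^2 - rb^2 - r_12^2)
    sbar <- psi / (1 - rb^2)^2
    (z1 - z2) * sqrt((n - 3) / (2 - 2 * sbar))
  }
  cases <- list(c(0.66, 0.20, 0.50, 20), c(-0.3, 0.4, 0.1, 50),
                c(0.8, 0.6, 0.7, 35))
  for (cs in cases) {
    got <- steiger_dependent_correlations(cs[1], cs[2], cs[3], cs[4])$statistic
    expect_equal(got, steiger_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 0.01)
  }
  # null calibration: trivariate normal with rho(j1) = rho(j2)
  set.seed(51)
  S <- matrix(c(1, 0.5, 0.5,  0.5, 1, 0.3,  0.5, 0.3, 1), 3, 3)
  L <- chol(S)
  n <- 60; reps <- 800
  rej <- 0
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(3 * n), n, 3) %*% L
    st <- steiger_dependent_correlations(cor(X[, 1], X[, 2]), cor(X[, 1], X[, 3]),
                                         cor(X[, 2], X[, 3]), n)
    rej <- rej + (st$p_two_tailed < 0.05)
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("ICC(3,1) behaves as a consistency measure", {
  set.seed(61)
  r1 <- rnorm(30, 100, 15)
  expect_equal(icc_test_retest(r1, r1), 1)
  expect_equal(icc_test_retest(r1, r1 + 7), 1)   # constant shift: consistency 1
  # independent runs: mean ICC near zero
  m <- replicate(150, {
    a <- rnorm(50); b <- rnorm(50)
    icc_test_retest(a, b)
  })
  expect_lt(abs(mean(m)), 0.05)
  expect_error(icc_test_retest(rep(1, 10), rep(1, 10)), "variance")
  # cross-check mean squares against aov on one dataset
  r2 <- r1 + rnorm(30, 0, 5)
  d <- data.frame(y = c(r1, r2), subj = factor(rep(1:30, 2)),
                  run = factor(rep(1:2, each = 30)))
  a <- anova(aov(y ~ subj + run, data = d))
  ms_subj <- a["subj", "Mean Sq"]; ms_err <- a["Residuals", "Mean Sq"]
  expect_equal(icc_test_retest(r1, r2),
               (ms_subj - ms_err) / (ms_subj + ms_err), tolerance = 1e-10)
})

test_that("correlation maintenance flags only real changes", {
  set.seed(71)
  age <- runif(20, 25, 65)
  vol <- 9000 - 40 * age + rnorm(20, 0, 150)
  same <- correlation_maintenance(vol, vol, age)
  expect_equal(same$test$statistic, 0)
  expect_false(same$changed)
  # strongly disrupted volumes: flagged
  broken <- correlation_maintenance(vol, rnorm(20, 7200, 30), age)
  expect_true(abs(broken$r_after) < abs(broken$r_before))
})
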