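# Shapiro-Wilk gate, gated group comparisons and correlations.

test_that("normality gate passes Gaussian groups and flags skewed ones", {
  set.seed(50)
  passNorm <- sapply(1:200, function(i)
    normalityGate(list(rnorm(50), rnorm(50))))
  # each group passes w.p. ~0.95, jointly ~0.90
  expect_gt(mean(passNorm), 0.90 - 3 * sqrt(0.9 * 0.1 / 200))
  set.seed(51)
  passSkew <- sapply(1:200, function(i) normalityGate(list(exp(rnorm(50)))))
  expect_lt(mean(passSkew), 0.10)
  expect_error(normalityGate(list(rnorm(10), c(1, 2))), "n >= 3")
})

test_that("group comparison picks ANOVA/Tukey or Kruskal-Wallis/Dunn by the gate", {
  set.seed(52)
  vals <- c(rnorm(20), rnorm(20), rnorm(20, 2))
  grp <- rep(c("a", "b", "c"), each = 20)
  res <- compareGroups(vals, grp)
  expect_identical(res$test_name, "one-way ANOVA + Tukey")
  expect_match(res$statistic_label, "^F\\(2,57\\)")
  expect_equal(nrow(res$posthoc), 3)
  expect_lt(res$p_value, 0.05)
  # heavily skewed data fall through to Kruskal-Wallis + Dunn
  set.seed(53)
  valsS <- exp(c(rnorm(20), rnorm(20), rnorm(20, 2)))
  resS <- compareGroups(valsS, grp)
  expect_identical(resS$test_name, "Kruskal-Wallis + Dunn")
  expect_match(resS$statistic_label, "^X2\\(2\\)")
  expect_equal(nrow(resS$posthoc), 3)
  expect_true(all(resS$posthoc$p_adjusted >= 0 & resS$posthoc$p_adjusted <= 1))
  expect_error(compareGroups(rnorm(10), rep("a", 10)), "2 groups")
  expect_error(compareGroups(c(rnorm(5), 1), c(rep("a", 5), "b")), "n >= 3")
})

test_that("Dunn post hoc agrees with the direct rank-statistic oracle", {
  set.seed(54)
  vals <- exp(c(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
  grp <- rep(c("a", "b", "c"), each = 10)
  res <- compareGroups(vals, grp)
  expect_identical(res$test_name, "Kruskal-Wallis + Dunn")
  # oracle: Dunn z for each pair from the pooled ranks of all 30 values,
  # Bonferroni over the 3 pairs (no ties here, so no tie correction)
  rk <- rank(vals)
  N <- length(vals)
  for (k in seq_len(nrow(res$posthoc))) {
    a <- res$posthoc$group_a[k]
    b <- res$posthoc$group_b[k]
    z <- (mean(rk[grp == a]) - mean(rk[grp == b])) /
      sqrt((N * (N + 1) / 12) * (1 / 10 + 1 / 10))
    expect_equal(res$posthoc$p_adjusted[k],
                 min(1, 2 * pnorm(-abs(z)) * 3), tolerance = 1e-12)
  }
})

test_that("group comparison is invariant to group ordering", {
  set.seed(56)
  vals <- c(rnorm(15), rnorm(15, 0.5), rnorm(15, 1))
  grp <- rep(c("a", "b", "c"), each = 15)
  o <- sample(45)
  r1 <- compareGroups(vals, grp)
  r2 <- compareGroups(vals[o], grp[o])
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("group comparison rejects the null at high power for a 2-SD shift", {
  set.seed(57)
  hits <- sapply(1:200, function(i) {
    vals <- c(rnorm(20), rnorm(20), rnorm(20, 2))
    compareGroups(vals, rep(c("a", "b", "c"), each = 20))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.95)
})

test_that("correlation returns exact +-1 on perfect pairs and uses the gate", {
  set.seed(58)
  x <- rnorm(30)
  expect_equal(correlateFeatures(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(correlateFeatures(x, -x)$r, -1, tolerance = 1e-12)
  lin <- correlateFeatures(x, 3 + 2 * x)
  expect_identical(lin$method, "pearson")
  expect_equal(lin$r, 1, tolerance = 1e-12)
  # skewed marginals switch to Spearman
  sk <- correlateFeatures(exp(x) + exp(rnorm(30)), exp(rnorm(30)))
  expect_identical(sk$method, "spearman")
  set.seed(59)
  ind <- correlateFeatures(rnorm(1000), rnorm(1000))
  expect_lt(abs(ind$r), 0.1)
  expect_error(correlateFeatures(1:3, 1:3), "4")
  expect_error(correlateFeatures(rep(1, 10), rnorm(10)), "variance")
})
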