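# Path-model ML fitting, fit indices, the correlated-endpoint adjustment,
# the cumulative-sum transform, composite scoring and the
# behaviour-versus-degeneration curves.

test_that("path model parsing and validity work", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "x -> m", "", "m -> y"), f)
  pm <- readPathModel(f)
  expect_equal(nrow(pm@edges), 2)
  expect_setequal(pm@variables, c("x", "m", "y"))
  expect_error(PathModel(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "acyclic")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("x => y", f2)
  expect_error(readPathModel(f2), "unparseable")
})

test_that("a saturated model fits perfectly and a df=1 model shows the clamp", {
  set.seed(70)
  d <- simMediation(300)
  sat <- PathModel(data.frame(from = c("x", "x", "m"), to = c("m", "y", "y")))
  fit <- fitPathModel(sat, d)
  expect_lt(fit@chi2, 1e-6)
  expect_equal(fit@rmsea, 0)
  expect_equal(fit@df, 0)
  # df = 1 model: rmsea is zero whenever chi2 <= df by the max(., 0) clamp
  fit1 <- fitPathModel(mediationModel(), d)
  expect_equal(fit1@df, 1)
  if (fit1@chi2 <= fit1@df) expect_equal(fit1@rmsea, 0)
  expect_equal(fit1@aic, fit1@chi2 + 2 * fit1@nFree)
})

test_that("ML estimates equal the equation-wise OLS oracle for mediation", {
  set.seed(71)
  d <- simMediation(1000)
  fit <- fitPathModel(mediationModel(), d)
  e <- estimates(fit)
  b1 <- unname(coef(lm(m ~ x, d))[2])
  b2 <- unname(coef(lm(y ~ m, d))[2])
  expect_lt(abs(e$est[e$from == "x"] - b1), 1e-6)
  expect_lt(abs(e$est[e$from == "m"] - b2), 1e-6)
  # standardized coefficients recover the generating standardized paths
  expect_lt(abs(e$std[e$from == "x"] - 0.6), 0.1)
  expect_lt(abs(e$std[e$from == "m"] - 0.7), 0.1)
})

test_that("fit rejects unidentifiable or degenerate inputs", {
  set.seed(72)
  d <- simMediation(4)   # 4 complete cases cannot identify 5 parameters
  expect_error(fitPathModel(mediationModel(), d), "complete cases")
  d2 <- data.frame(x = rnorm(50))
  d2$m <- d2$x                 # singular covariance
  d2$y <- rnorm(50)
  expect_error(fitPathModel(mediationModel(), d2), "positive definite")
  expect_error(fitPathModel(mediationModel(), data.frame(x = rnorm(50))),
               "lacks model variable")
})

test_that("the generating model usually wins on AIC against a spurious path", {
  set.seed(73)
  gen <- mediationModel()
  spur <- PathModel(data.frame(from = c("x", "m", "x"), to = c("m", "y", "y")))
  wins <- sapply(1:30, function(i) {
    d <- simMediation(500)
    fitPathModel(gen, d)@aic < fitPathModel(spur, d)@aic
  })
  expect_gte(mean(wins), 0.7)
})

test_that("adjusted Bonferroni follows the correlation-weakened formula", {
  expect_equal(adjustedBonferroni(rep(0.01, 10), 1)$alpha_adjusted, 0.05)
  expect_equal(adjustedBonferroni(rep(0.01, 10), 0)$alpha_adjusted,
               1 - 0.95^(1 / 10))
  expect_equal(adjustedBonferroni(0.02, 0.3)$alpha_adjusted, 0.05)
  a <- adjustedBonferroni(c(0.001, 0.04), 0.5)
  expect_identical(a$significant, c(TRUE, 0.04 < a$alpha_adjusted))
  expect_error(adjustedBonferroni(0.01, 1.2), "\\[0, 1\\]")
  expect_error(adjustedBonferroni(numeric(0), 0.5), "nonempty")
})

test_that("cumulative transform matches its definition and a loop oracle", {
  ft <- expand.grid(subject = c("s1", "s2"), week = c(2, 3, 4, 6, 8),
                    stringsAsFactors = FALSE)
  ft$group <- "g"
  gm <- 4
  ft$f <- gm                        # constant at its group mean
  out <- cumulativeFeatures(ft, features = "f")
  expect_equal(out$f[out$subject == "s1"], 1:5)
  # doubling is invariant under mean normalization
  ft2 <- ft
  ft2$f <- 2 * ft$f
  out2 <- cumulativeFeatures(ft2, features = "f")
  expect_equal(out2$f, out$f)
  # arbitrary table equals an independent loop oracle
  set.seed(74)
  ft3 <- expand.grid(subject = paste0("s", 1:4), week = c(2, 4, 8),
                     stringsAsFactors = FALSE)
  ft3$group <- ifelse(ft3$subject %in% c("s1", "s2"), "a", "b")
  ft3$f <- runif(12, 1, 5)
  out3 <- cumulativeFeatures(ft3, features = "f")
  for (g in c("a", "b")) {
    mu <- mean(ft3$f[ft3$group == g])
    for (s in unique(ft3$subject[ft3$group == g])) {
      raw <- ft3[ft3$subject == s, ]
      raw <- raw[order(raw$week), ]
      expect_equal(out3$f[out3$subject == s], cumsum(raw$f / mu))
    }
  }
  # zero group mean is rejected; incomplete subjects are dropped
  ft4 <- ft3
  ft4$f <- 0
  expect_error(cumulativeFeatures(ft4, features = "f"), "zero")
  ft5 <- ft3[-1, ]
  expect_message(out5 <- cumulativeFeatures(ft5, features = "f"), "dropping")
  expect_false(ft3$subject[1] %in% out5$subject)
})

test_that("composite scoring recovers a constructed linear target", {
  set.seed(75)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 0.7 * X[, 1] + 0.3 * X[, 2] + rnorm(n, 0, 0.02)
  cs <- compositeScore(X, y)
  expect_setequal(cs$selected, c("f1", "f2"))
  expect_lt(abs(cs$weights[["f1"]] - 0.7), 0.05)
  expect_lt(abs(cs$weights[["f2"]] - 0.3), 0.05)
  expect_lt(cs$rmse, 0.05)
  expect_equal(sum(cs$weights), 1, tolerance = 1e-9)
  expect_true(all(cs$weights >= 0))
})

test_that("composite scoring handles exact, null and degenerate cases", {
  set.seed(76)
  y <- rnorm(50)
  cs <- compositeScore(matrix(y, dimnames = list(NULL, "f1")), y)
  expect_equal(unname(cs$weights), 1)
  expect_lt(cs$rmse, 1e-10)
  # pure-noise candidates cannot beat the intercept-only baseline
  X <- matrix(rnorm(50 * 5), 50, 5)
  target <- sort(rnorm(50))
  csn <- compositeScore(X, target)
  expect_gte(csn$rmse, csn$baselineRMSE - 0.15)
  expect_error(compositeScore(matrix(1, 10, 2), rnorm(10)), "constant")
})

test_that("degeneration-behaviour curves localize a step and reject constants", {
  set.seed(77)
  deg <- seq(0, 100, by = 2.5)
  deficit <- ifelse(deg > 50, 3, 0) + rnorm(length(deg), 0, 0.3)
  cv <- degenerationBehaviorCurve(deficit, deg)
  expect_gt(cv$midpoint, 45)
  expect_lt(cv$midpoint, 55)
  expect_lt(cv$slope, 0)
  expect_error(degenerationBehaviorCurve(rep(1, 20), seq(0, 95, by = 5)),
               "single behaviour class")
})

test_that("with unrelated behaviour the curve slope is consistent with zero", {
  set.seed(78)
  deg <- runif(60, 0, 100)
  deficit <- rnorm(60)
  cv <- degenerationBehaviorCurve(deficit, deg)
  # bootstrap CI for the slope covers zero
  boots <- sapply(1:200, function(i) {
    idx <- sample(60, replace = TRUE)
    tryCatch(degenerationBehaviorCurve(deficit[idx], deg[idx])$slope,
             error = function(e) NA)
  })
  ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
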