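test_that("t-tests agree exactly with stats::t.test", {
  set.seed(30)
  for (i in 1:6) {
    x <- rnorm(8, 1); y <- rnorm(10)
    pooled <- ttestIndependent(x, y, "pooled")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref$statistic))
    expect_equal(pooled$p, ref$p.value)
    expect_equal(pooled$df, unname(ref$parameter))
    welch <- ttestIndependent(x, y, "welch")
    refW <- t.test(x, y)
    expect_equal(welch$t, unname(refW$statistic))
    expect_equal(welch$p, refW$p.value)
    expect_equal(welch$df, unname(refW$parameter))
  }
})

test_that("t-test edge cases: identity, separation, zero variance", {
  x <- c(1, 2, 3, 4)
  r <- ttestIndependent(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  big <- ttestIndependent(x + 1000, x + rnorm(4, 0, 1e-3))
  expect_lt(big$p, 1e-6)
  degenerate <- ttestFromSummary(3, 0, 5, 3, 0, 5)
  expect_equal(degenerate$p, 1)
  apart <- ttestFromSummary(3, 0, 5, 4, 0, 5)
  expect_equal(apart$p, 0)
})

test_that("summary-based and raw pooled t-tests coincide", {
  set.seed(31)
  x <- rnorm(8, 0.5, 0.2); y <- rnorm(8, 0.3, 0.25)
  raw <- ttestIndependent(x, y, "pooled")
  summ <- ttestFromSummary(mean(x), sd(x), 8, mean(y), sd(y), 8)
  expect_equal(raw$t, summ$t); expect_equal(raw$p, summ$p)
  # swapping groups flips t, keeps p
  flip <- ttestFromSummary(mean(y), sd(y), 8, mean(x), sd(x), 8)
  expect_equal(flip$t, -summ$t); expect_equal(flip$p, summ$p)
})

test_that("the pooled t-test holds its nominal level under the null", {
  set.seed(32)
  reps <- 4000
  p <- replicate(reps, ttestIndependent(rnorm(8), rnorm(8))$p)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.25)
})

test_that("compareGroups reports per-feature tests with symmetry", {
  set.seed(33)
  vals <- matrix(runif(6 * 8), 6, 8)
  rownames(vals) <- c(sprintf("reading.theta.coh.p%d", 1:3),
                      sprintf("answer1.gamma.psd.ch%d", 1:3))
  g <- rep(c("novice", "experienced"), each = 4)
  ft <- featureTable(vals, g, stage = "normalized")
  cmp <- compareGroups(ft)
  expect_equal(nrow(cmp), 6)
  ftSwap <- featureTable(vals, rev(g), stage = "normalized")
  cmpSwap <- compareGroups(ftSwap)
  m <- match(cmp$feature, cmpSwap$feature)
  expect_equal(cmp$t, -cmpSwap$t[m])
  expect_equal(cmp$p, cmpSwap$p[m])
  # delta excluded by default, included on request
  vals2 <- rbind(vals, "reading.delta.coh.q1" = runif(8))
  ft2 <- featureTable(vals2, g, stage = "normalized")
  expect_equal(nrow(compareGroups(ft2)), 6)
  expect_equal(nrow(compareGroups(ft2, includeDelta = TRUE)), 7)
  tiny <- featureTable(vals[, 1:3], c("novice", "novice", "experienced"),
                       stage = "normalized")
  expect_error(compareGroups(tiny), ">= 2")
})

test_that("BH adjustment is available and more conservative", {
  set.seed(34)
  vals <- matrix(rnorm(40 * 10), 40, 10)
  rownames(vals) <- sprintf("reading.theta.coh.p%d", 1:40)
  ft <- featureTable(vals, rep(c("novice", "experienced"), each = 5),
                     stage = "normalized")
  raw <- compareGroups(ft)
  adj <- compareGroups(ft, adjust = "BH")
  expect_true(sum(adj$significant) <= sum(raw$significant))
  expect_true(all(adj$pAdjusted >= adj$p - 1e-12))
})

test_that("Pearson screening keeps correlates and drops degenerates", {
  set.seed(35)
  y <- rnorm(16)
  vals <- rbind(outcomeCopy = y, noise1 = rnorm(16), constant = rep(2, 16))
  rownames(vals) <- c("reading.theta.coh.a", "reading.theta.coh.b",
                      "reading.theta.coh.c")
  expect_warning(kept <- pearsonScreen(vals, y), "constant")
  expect_true("reading.theta.coh.a" %in% kept)
  expect_false("reading.theta.coh.c" %in% kept)
  expect_warning(none <- pearsonScreen(vals, rep(1, 16)), "constant")
  expect_length(none, 0)
  # null inclusion rate is near the screening level
  hits <- replicate(300, {
    length(pearsonScreen(matrix(rnorm(5 * 16), 5,
                                dimnames = list(paste0("f", 1:5), NULL)),
                         rnorm(16))) / 5
  })
  expect_equal(mean(hits), 0.05, tolerance = 0.4)
})

test_that("lasso penalty limits: empty selection and the OLS endpoint", {
  set.seed(36)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, -2, 0, 0, 0.5) + rnorm(30, 0, 0.1)
  res <- lassoCV(X, y, seed = 2)
  # grid endpoint at lambda_max selects nothing
  fitTop <- glmnet::glmnet(X, y, lambda = max(res$cvLambda))
  expect_equal(sum(coef(fitTop)[-1] != 0), 0)
  # unpenalized endpoint equals least squares
  fit0 <- glmnet::glmnet(X, y, lambda = c(max(res$cvLambda), 0),
                         thresh = 1e-12)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(as.numeric(coef(fit0, s = 0))), unname(ols),
               tolerance = 1e-4)
  # determinism under the fold seed
  res2 <- lassoCV(X, y, seed = 2)
  expect_identical(res$lambda, res2$lambda)
  expect_identical(res$selected, res2$selected)
  expect_error(lassoCV(X[1:3, ], y[1:3], folds = 5), "folds")
})

test_that("the selected-set size is non-increasing along the penalty path", {
  set.seed(37)
  X <- matrix(rnorm(40 * 8), 40, dimnames = list(NULL, paste0("x", 1:8)))
  y <- X[, 1] - 2 * X[, 2] + rnorm(40, 0, 0.5)
  res <- lassoCV(X, y, seed = 3)
  sizes <- res$fit$df                      # glmnet orders lambda decreasing
  expect_true(all(diff(rev(sizes)) <= 0))
})

test_that("post-lasso OLS reports exact fits, null fits and aliasing", {
  set.seed(38)
  X <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("x", 1:4)))
  y <- as.numeric(2 + 3 * X[, 1] - X[, 2])
  fit <- postLassoOLS(X, y, c("x1", "x2"))
  expect_equal(rSquared(fit), 1)
  expect_equal(coef(fit)$estimate[coef(fit)$term == "x1"], 3, tolerance = 1e-9)
  null <- postLassoOLS(X, rnorm(20), character())
  expect_equal(rSquared(null), 0)
  expect_identical(selectedFeatures(null), character())
  Xa <- cbind(X, x5 = X[, 1])
  expect_warning(al <- postLassoOLS(Xa, y, c("x1", "x2", "x5")), "aliased")
  expect_identical(selectedFeatures(al), c("x1", "x2"))
})

test_that("the full modeling stage recovers a planted linear signal", {
  set.seed(39)
  n <- 16
  vals <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(sprintf("reading.gamma.coh.f%d", 1:10), NULL))
  y <- as.numeric(0.5 + 1.5 * vals[1, ] - 1.2 * vals[2, ] + rnorm(n, 0, 0.05))
  ft <- featureTable(vals, rep(c("novice", "experienced"), each = 8),
                     stage = "normalized")
  fit <- fitOutcomeModel(ft, y, outcomeName = "performance", seed = 4)
  expect_true(all(c("reading.gamma.coh.f1", "reading.gamma.coh.f2") %in%
                  selectedFeatures(fit)))
  expect_gt(rSquared(fit), 0.9)
  expect_identical(fit@outcome, "performance")
})
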