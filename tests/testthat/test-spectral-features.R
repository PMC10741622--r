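test_that("PSD is zero for zero signal and satisfies Parseval for white noise", {
  zeros <- epochSetFromList(lapply(1:3, function(e) matrix(0, 14, 256)))
  expect_true(all(psdEpochs(zeros) == 0))

  set.seed(11)
  white <- epochSetFromList(lapply(1:120, function(e)
    matrix(rnorm(14 * 256), 14)))
  P <- psdEpochs(white)
  expect_true(all(P >= 0))
  # one-sided PSD integrates to the variance (df = 1 Hz)
  tot <- colSums(P)
  expect_lt(abs(mean(tot) - 1), 0.02)
  expect_true(all(abs(tot - 1) < 0.05))
})

test_that("a sinusoid's power lands in its band at amplitude^2 / 2", {
  fs <- 256; A <- 3
  t <- (0:(60 * fs - 1)) / fs
  sig <- matrix(rnorm(14 * length(t), 0, 1e-3), 14)
  sig[3, ] <- A * sin(2 * pi * 10 * t)
  rec <- newRecording(sig, montageChannels(), fs)
  P <- psdEpochs(epochSegment(rec, c(0, 60)))
  f <- as.numeric(rownames(P))
  inAlpha <- sum(P[f >= 9 & f <= 11, 3])
  expect_equal(inAlpha, A^2 / 2, tolerance = 0.03)
  # localization: alpha band power dwarfs every other band on that channel
  bp <- vapply(eegBands()$band, function(b) bandPower(P, b)[3], 0)
  expect_gt(bp["alpha"], 100 * max(bp[c("delta", "theta", "beta", "gamma")]))
  expect_error(bandPower(P, c(300, 400)), "no frequency bins")
})

test_that("flat spectra give equal band powers", {
  P <- matrix(2.5, 129, 14, dimnames = list(0:128, montageChannels()))
  for (b in eegBands()$band)
    expect_equal(unname(bandPower(P, b)), rep(2.5, 14))
})

test_that("coherence is 1 for identical channels and ~1/L for independent ones", {
  set.seed(3)
  L <- 60
  eps <- lapply(seq_len(L), function(e) {
    m <- matrix(rnorm(14 * 256), 14)
    m[2, ] <- m[1, ]                          # F7 duplicates AF3
    m
  })
  co <- coherencePairs(epochSetFromList(eps))
  expect_equal(unname(co["AF3-F7", ]), rep(1, 5), tolerance = 1e-9)
  others <- co[rownames(co) != "AF3-F7", ]
  expect_equal(mean(others), 1 / L, tolerance = 0.2)
  expect_true(all(co >= 0 & co <= 1 + 1e-12))
})

test_that("coherence is symmetric and scale invariant", {
  set.seed(4)
  eps <- lapply(1:30, function(e) matrix(rnorm(14 * 256), 14))
  base <- coherencePairs(epochSetFromList(eps))
  scaled <- lapply(eps, function(m) { m[5, ] <- 17 * m[5, ]; m })
  expect_equal(coherencePairs(epochSetFromList(scaled)), base,
               tolerance = 1e-10)
  # symmetry is structural: each unordered pair appears once, value shared
  es <- epochSetFromList(eps)
  X <- coherencePairs(es)
  expect_equal(nrow(X), choose(14, 2))
})

test_that("estimator matches the mixture oracle within 3 simulation SEs", {
  set.seed(6)
  targets <- c(0.25, 0.6)
  for (g in targets) {
    est <- replicate(8, coherencePairs(
      oracleMixtureEpochs(g, L = 60))["FC5-FC6", "theta"])
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - g), 3 * se + 2 * (1 - g)^2 / 60)
  }
})

test_that("coherence requires two retained epochs and PSD one", {
  one <- epochSetFromList(list(matrix(rnorm(14 * 256), 14)))
  expect_error(coherencePairs(one), ">= 2 retained")
  none <- one
  none@artifactMask <- TRUE
  expect_error(psdEpochs(none), "no retained")
})

test_that("baseline correction subtracts per participant and feature", {
  vals <- matrix(c(0.6, 0.3, 0.5, 0.2), 2, 2,
                 dimnames = list(c("reading.theta.coh.FC5-FC6",
                                   "reading.theta.psd.F7"), c("a", "b")))
  base <- matrix(c(0.2, 0.1, 0.5, 0.2), 2, 2,
                 dimnames = list(c("baseline.theta.coh.FC5-FC6",
                                   "baseline.theta.psd.F7"), c("a", "b")))
  ft <- featureTable(vals, c("novice", "experienced"))
  fb <- featureTable(base, c("novice", "experienced"))
  corr <- baselineCorrect(ft, fb)
  expect_equal(featureStage(corr), "baseline_corrected")
  expect_equal(unname(assay(corr)[, "a"]), c(0.4, 0.2))
  expect_equal(unname(assay(corr)[, "b"]), c(0.0, 0.0))  # task == baseline
  expect_error(baselineCorrect(ft, fb[, 1]), "participant")
})

test_that("min-max normalization maps each feature onto [0, 1]", {
  vals <- rbind("reading.theta.coh.FC5-FC6" = c(2, 4, 6),
                "reading.alpha.coh.F7-FC6" = c(5, 5, 5))
  ft <- featureTable(vals, c("novice", "novice", "experienced"),
                     stage = "baseline_corrected")
  expect_warning(nm <- minmaxNormalize(ft), "constant")
  expect_equal(unname(assay(nm)[1, ]), c(0, 0.5, 1))
  expect_equal(unname(assay(nm)[2, ]), c(0, 0, 0))
  expect_equal(featureStage(nm), "normalized")

  set.seed(9)
  vals2 <- matrix(rnorm(40), 8, 5)
  rownames(vals2) <- sprintf("reading.theta.coh.P%d-F8", 1:8)[1:8]
  rownames(vals2) <- paste0("reading.theta.coh.pair", 1:8)  # synthetic names
  rownames(vals2) <- sprintf("reading.theta.psd.ch%d", 1:8)
  ft2 <- featureTable(vals2, rep(c("novice", "experienced"), c(3, 2)),
                      stage = "baseline_corrected")
  nm2 <- assay(minmaxNormalize(ft2))
  expect_equal(unname(apply(nm2, 1, min)), rep(0, 8))
  expect_equal(unname(apply(nm2, 1, max)), rep(1, 8))
})

test_that("raw coherence features outside [0, 1] are rejected by validity", {
  vals <- rbind("reading.theta.coh.FC5-FC6" = c(0.2, 1.4))
  expect_error(featureTable(vals, c("novice", "experienced")), "0, 1")
})
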