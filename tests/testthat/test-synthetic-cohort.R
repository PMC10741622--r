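test_that("cohort config enforces its invariants", {
  expect_error(cohortConfig(nPerGroup = 1), "nPerGroup")
  expect_error(cohortConfig(artifactRate = 1), "artifactRate")
  bad <- defaultEffectTable()
  bad$cohNovice[1] <- 1                       # exactly 1 is unattainable
  expect_error(cohortConfig(effectTable = bad), "unattainable")
  dup <- rbind(defaultEffectTable(), defaultEffectTable()[1, ])
  expect_error(cohortConfig(effectTable = dup), "overlapping")
  selfpair <- defaultEffectTable()
  selfpair$ch2[1] <- selfpair$ch1[1]
  expect_error(cohortConfig(effectTable = selfpair), "distinct")
})

test_that("simulated recordings carry the montage, markers and duration", {
  cfg <- smallConfig(seed = 2)
  sim <- simulateRecording(cfg, 1, "experienced")
  rec <- sim$recording
  expect_identical(channelLabels(rec), montageChannels())
  expect_equal(recordingDuration(rec), sum(cfg@segmentPlan$duration))
  expect_equal(nrow(markers(rec)), 4)
  expect_true(all(is.finite(signalData(rec))))
  expect_equal(nrow(validateMontage(rec)), 0)
  # per-channel couplings recorded for every designed effect channel
  expect_true(all(c("task", "band", "channel", "r", "a") %in%
                  names(sim$groundTruth$couplings)))
  expect_true(all(sim$groundTruth$couplings$a >= 0))
})

test_that("fixed seed and participant index fix every output bit", {
  cfg <- smallConfig(seed = 9)
  a <- simulateRecording(cfg, 3, "novice")
  b <- simulateRecording(cfg, 3, "novice")
  expect_identical(signalData(a$recording), signalData(b$recording))
  expect_identical(a$groundTruth, b$groundTruth)
  c <- simulateRecording(cfg, 4, "novice")
  expect_false(identical(signalData(a$recording), signalData(c$recording)))
})

test_that("isolated-pair mixing reproduces the closed-form coherence", {
  # a_i = a_j = 1 (unit shared source, unit noise) gives gamma^2 = 0.25
  cfg <- cohortConfig(nPerGroup = 2, segmentDurations = c(4, 60, 4, 4),
                      effectTable = data.frame(
                        ch1 = "FC5", ch2 = "FC6", band = "theta",
                        task = "reading",
                        cohExperienced = 0.25, cohNovice = 0.25),
                      artifactRate = 0, seed = 31)
  sim <- simulateRecording(cfg, 1, "novice")
  expect_equal(unique(sim$groundTruth$couplings$a), 1, tolerance = 1e-12)
  set.seed(17)
  est <- replicate(6, {
    i <- sample.int(1000, 1)
    s <- simulateRecording(cfg, i, "novice")
    eps <- epochTasks(s$recording)
    coherencePairs(eps$reading)["FC5-FC6", "theta"]
  })
  expect_equal(mean(est), 0.25, tolerance = 0.15)
})

test_that("zero coupling leaves the estimator at the 1/L floor", {
  cfg <- cohortConfig(nPerGroup = 2, segmentDurations = c(4, 60, 4, 4),
                      effectTable = defaultEffectTable()[0, ],
                      artifactRate = 0, seed = 8)
  sim <- simulateRecording(cfg, 1, "novice")
  co <- coherencePairs(epochTasks(sim$recording)$reading)
  # mean over many pairs and bands concentrates near 1/60
  expect_equal(mean(co[, c("theta", "beta")]), 1 / 60, tolerance = 0.25)
})

test_that("artifact injection is deterministic, counted, and off at rate 0", {
  cfg <- smallConfig(seed = 4)
  rec <- simulateRecording(cfg, 1, "novice")$recording
  none <- injectArtifacts(rec, 0, seed = 1)
  expect_identical(signalData(none$recording), signalData(rec))
  expect_length(none$epochs, 0)
  a <- injectArtifacts(rec, 0.10, seed = 6)
  b <- injectArtifacts(rec, 0.10, seed = 6)
  expect_identical(signalData(a$recording), signalData(b$recording))
  expect_identical(a$epochs, b$epochs)
  expect_equal(length(a$epochs), round(0.10 * recordingDuration(rec)))
  expect_error(injectArtifacts(rec, 1.2, seed = 1), "rate")
})

test_that("group difference direction follows the designed contrasts", {
  et <- defaultEffectTable()[c(1, 6), ]       # one novice>exp, one exp>novice
  cfg <- cohortConfig(nPerGroup = 2, segmentDurations = c(10, 30, 10, 10),
                      effectTable = et, artifactRate = 0, seed = 21)
  co <- lapply(c("novice", "experienced"), function(g) {
    recs <- lapply(1:2, function(i)
      simulateRecording(cfg, i + ifelse(g == "novice", 0, 2), g)$recording)
    rowMeans(vapply(recs, function(r)
      coherencePairs(epochTasks(r)$reading)[c("FC5-FC6", "P8-F8"),
                                            c("theta", "gamma")][cbind(1:2, 1:2)],
      numeric(2)))
  })
  expect_lt(co[[2]][1], co[[1]][1])           # FC5-FC6 theta: exp < novice
  expect_gt(co[[2]][2], co[[1]][2])           # P8-F8 gamma:   exp > novice
})

test_that("behavior simulation honours identity and agreement edge cases", {
  cfg <- smallConfig(seed = 13)
  # feature table with two controlled features
  vals <- rbind(c(0.1, 0.4, 0.7, 0.95), c(0.5, 0.1, 0.9, 0.3))
  rownames(vals) <- c("reading.theta.coh.FC5-FC6", "answer1.beta.coh.F7-F8")
  colnames(vals) <- paste0("P", 1:4)
  ft <- featureTable(vals, rep(c("novice", "experienced"), 2),
                     stage = "normalized")
  bm <- defaultBehaviorModel()
  bm$performance <- list(intercept = 0,
                         coef = c("reading.theta.coh.FC5-FC6" = 1),
                         noiseSD = 0)
  bm$tlx <- list(intercept = 0.5,
                 coef = c("answer1.beta.coh.F7-F8" = 0.2), noiseSD = 0)
  bm$raterNoise <- 0
  cfg@behaviorModel <- bm
  beh <- simulateBehavior(cfg, ft, seed = 1)
  # zero noise, single unit coefficient: performance equals the feature
  expect_equal(beh$behavior$performance, unname(vals[1, ]))
  # zero rater noise: identical raters, ICC = 1
  expect_identical(beh$raterScores[, 1], beh$raterScores[, 2])
  expect_equal(iccAbsoluteAgreement(beh$raterScores)$icc, 1)
  # unknown feature name rejected
  bm$performance$coef <- c("nonexistent.feature" = 1)
  cfg@behaviorModel <- bm
  expect_error(simulateBehavior(cfg, ft, seed = 1), "unknown feature")
})

test_that("cyclic designed-effect graphs are rejected", {
  cyc <- data.frame(ch1 = c("F7", "F8", "AF3"), ch2 = c("F8", "AF3", "F7"),
                    band = "theta", task = "reading",
                    cohExperienced = 0.3, cohNovice = 0.3)
  cfg <- cohortConfig(effectTable = cyc,
                      segmentDurations = c(4, 8, 4, 4), nPerGroup = 2)
  expect_error(simulateRecording(cfg, 1, "novice"), "cycle")
})
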