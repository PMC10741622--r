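test_that("segmentTasks spans run from each marker to the next", {
  rec <- tinyRecording(seconds = 8)          # markers at 0, 2, 4, 6
  segs <- segmentTasks(rec)
  expect_equal(segs$baseline, c(start = 0, end = 2))
  expect_equal(segs$reading, c(start = 2, end = 4))
  expect_equal(segs$answer1, c(start = 4, end = 6))
  expect_equal(segs$answer2, c(start = 6, end = 8))  # truncated at the end
})

test_that("segmentTasks rejects malformed marker sets", {
  rec <- tinyRecording()
  expect_error(segmentTasks(newRecording(signalData(rec), montageChannels(),
                                         256, markers = markers(rec)[-2, ])),
               "reading")
  dup <- rbind(markers(rec), data.frame(label = "Reading", onset = 3.2))
  expect_error(segmentTasks(newRecording(signalData(rec), montageChannels(),
                                         256, markers = dup)),
               "duplicated")
  swapped <- markers(rec)
  swapped$onset <- c(0, 2, 1, 3)
  expect_error(segmentTasks(newRecording(signalData(rec), montageChannels(),
                                         256, markers = swapped)),
               "out of order")
})

test_that("marker labels match case-insensitively after whitespace cleanup", {
  rec <- tinyRecording()
  mk <- markers(rec)
  mk$label <- c("Eyes  Open", "READING", " Answer 1", "answer  2 ")
  segs <- segmentTasks(newRecording(signalData(rec), montageChannels(), 256,
                                    markers = mk))
  expect_named(segs, c("baseline", "reading", "answer1", "answer2"))
})

test_that("epoching floors the interval and partitions the signal", {
  rec <- tinyRecording(seconds = 22)
  es <- epochSegment(rec, c(0, 20))
  expect_equal(dim(epochs(es)), c(20, 14, 256))
  es2 <- epochSegment(rec, c(0, 20.7))       # tail dropped
  expect_equal(dim(epochs(es2))[1], 20)
  # concatenating the epochs reproduces the original samples
  recon <- do.call(cbind, lapply(seq_len(20), function(e)
    matrix(epochs(es)[e, , ], 14)))
  expect_equal(recon, unname(signalData(rec)[, 1:(20 * 256)]))
  expect_warning(short <- epochSegment(rec, c(0, 0.5)), "shorter")
  expect_equal(dim(epochs(short))[1], 0)
})

test_that("artifact rejection flags transients, spares clean epochs", {
  set.seed(1)
  clean <- lapply(1:6, function(e) matrix(rnorm(14 * 256, 0, 10), 14))
  dirty <- clean
  dirty[[3]][5, 100:160] <- dirty[[3]][5, 100:160] + 500
  es <- rejectArtifacts(epochSetFromList(dirty))
  expect_identical(which(artifactMask(es)), 3L)
  esClean <- rejectArtifacts(epochSetFromList(clean))
  expect_false(any(artifactMask(esClean)))
  # flatlined electrode is an artifact too
  flat <- clean
  flat[[2]][7, ] <- 0.01
  expect_true(artifactMask(rejectArtifacts(epochSetFromList(flat)))[2])
})

test_that("a manual override list exempts epochs from rejection", {
  set.seed(8)
  eps <- lapply(1:4, function(e) matrix(rnorm(14 * 256, 0, 10), 14))
  eps[[2]][3, 50:110] <- eps[[2]][3, 50:110] + 400
  es <- epochSetFromList(eps)
  expect_true(artifactMask(rejectArtifacts(es))[2])
  expect_false(artifactMask(rejectArtifacts(es, keepEpochs = 2))[2])
})

test_that("rejection is monotone in thresholds and epoch-local", {
  set.seed(2)
  eps <- lapply(1:12, function(e) matrix(rnorm(14 * 256, 0, 30), 14))
  es <- epochSetFromList(eps)
  loose <- artifactMask(rejectArtifacts(es, absThresh = 150, ptpThresh = 300))
  strict <- artifactMask(rejectArtifacts(es, absThresh = 80, ptpThresh = 160))
  expect_true(all(strict[loose]))            # stricter never unmasks
  # permutation equivariance: decisions depend on the epoch's own samples
  perm <- c(4, 1, 12, 3, 2, 11, 5, 10, 6, 9, 7, 8)
  esP <- epochSetFromList(eps[perm])
  maskP <- artifactMask(rejectArtifacts(esP, absThresh = 80, ptpThresh = 160))
  expect_identical(maskP, strict[perm])
})

test_that("generator artifacts are caught at default thresholds", {
  cfg <- smallConfig(seed = 5, segmentDurations = c(20, 20, 40, 20))
  sim <- simulateRecording(cfg, 1, "novice")
  art <- injectArtifacts(sim$recording, 0.10, seed = 77)
  eps <- epochTasks(art$recording)
  masks <- unlist(lapply(names(eps), function(task) {
    m <- artifactMask(rejectArtifacts(eps[[task]]))
    off <- floor(segmentTasks(art$recording)[[task]][1])
    setNames(m, off + seq_along(m))
  }))
  flagged <- as.integer(names(masks)[masks])
  sens <- mean(art$epochs %in% flagged)
  expect_gte(sens, 0.95)
  expect_equal(rejectionRate(lapply(eps, rejectArtifacts)),
               length(art$epochs) / 100, tolerance = 0.35)
})
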