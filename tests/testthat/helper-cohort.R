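# Shared fixtures, built in code. Unit tests use shortened sessions so the
# suite stays fast; the generator's defaults (full study conditions) are
# exercised where a property depends on them.

smallConfig <- function(seed = 1, nPerGroup = 2,
                        segmentDurations = c(8, 8, 16, 8), ...) {
  cohortConfig(nPerGroup = nPerGroup, segmentDurations = segmentDurations,
               seed = seed, ...)
}

# deterministic low-amplitude recording with canonical markers
tinyRecording <- function(seconds = 4, fs = 256, seed = 42) {
  set.seed(seed)
  n <- seconds * fs
  sig <- matrix(rnorm(14 * n, 0, 5), 14)
  mk <- data.frame(label = c("eyes open", "reading", "answer 1", "answer 2"),
                   onset = seconds * c(0, 0.25, 0.5, 0.75))
  newRecording(sig, montageChannels(), fs, markers = mk)
}

# build an EpochSet directly from a channel x sample matrix per epoch
epochSetFromList <- function(epochList, fs = 256, task = "reading") {
  arr <- array(0, dim = c(length(epochList), nrow(epochList[[1]]), fs))
  for (e in seq_along(epochList)) arr[e, , ] <- epochList[[e]]
  new("EpochSet", task = task, epochs = arr,
      channelLabels = montageChannels(),
      artifactMask = logical(length(epochList)),
      samplingRate = fs, participant = "test")
}

# independent band-limited noise for estimator oracles (test-side generator,
# distinct from the package's spectral-domain construction)
oracleBandNoise <- function(n, fs, lo, hi) {
  f <- (seq_len(n) - 1) * fs / n
  fpos <- pmin(f, fs - f)
  z <- stats::fft(stats::rnorm(n))
  z[!(fpos >= lo & fpos <= hi)] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / stats::sd(x)
}

# EpochSet holding a designed two-channel mixture on FC5/FC6 plus
# independent noise elsewhere; theoretical FC5-FC6 band coherence =
# (a^2/(a^2+1))^2 for the band the source occupies
oracleMixtureEpochs <- function(targetCoh, L = 60, fs = 256,
                                band = c(4, 7)) {
  n <- L * fs
  r <- sqrt(targetCoh)
  a <- sqrt(r / (1 - r))
  S <- oracleBandNoise(n, fs, band[1], band[2])
  sig <- matrix(rnorm(14 * n), 14)
  i <- match(c("FC5", "FC6"), montageChannels())
  sig[i[1], ] <- a * S + oracleBandNoise(n, fs, band[1], band[2])
  sig[i[2], ] <- a * S + oracleBandNoise(n, fs, band[1], band[2])
  rec <- newRecording(sig, montageChannels(), fs)
  epochSegment(rec, c(0, L), task = "reading")
}
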