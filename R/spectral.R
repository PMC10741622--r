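# Kaiser-window FFT spectral features: per-channel PSD, band power, and
# magnitude-squared coherence over all 91 channel pairs, plus the
# feature-space baseline correction and min-max normalization stages.

# windowed FFT of all retained epochs: array [freq bins, epoch, channel];
# one batched mvfft over all (epoch, channel) columns
.epochFFT <- function(epochSet, kaiserBeta) {
  keep <- which(!epochSet@artifactMask)
  d <- dim(epochSet@epochs)
  N <- d[3]; L <- length(keep); C <- d[2]
  w <- signal::kaiser(N, kaiserBeta)
  A <- aperm(epochSet@epochs[keep, , , drop = FALSE], c(3, 1, 2))  # [N, L, C]
  dim(A) <- c(N, L * C)
  X <- mvfft(A * w)
  dim(X) <- c(N, L, C)
  X
}

#' Epoch-averaged power spectral density
#'
#' One-sided PSD per channel in microvolts^2 per Hz, averaged over retained
#' (non-masked) 1-second epochs. Each epoch is tapered with a Kaiser window
#' (the window's power is divided out), so a unit-variance white signal
#' integrates to ~1 uV^2 across 0 to Nyquist. With 1-second epochs at 256 Hz
#' the frequency axis runs 0-128 Hz in 1 Hz steps.
#'
#' @param epochSet an [EpochSet-class] with at least one retained epoch.
#' @param kaiserBeta Kaiser window shape parameter (default 8, strong
#'   sidelobe suppression against spectral leakage).
#' @return Numeric matrix, frequency bins x channels; rownames are
#'   frequencies in Hz.
#' @seealso [bandPower()], [coherencePairs()]
#' @export
psdEpochs <- function(epochSet, kaiserBeta = 8) {
  keep <- sum(!epochSet@artifactMask)
  if (keep < 1)
    stop("no retained epochs for participant '", epochSet@participant,
         "', task '", epochSet@task, "'")
  X <- .epochFFT(epochSet, kaiserBeta)
  .psdFromFFT(X, epochSet@samplingRate, kaiserBeta, epochSet@channelLabels)
}

.psdFromFFT <- function(X, fs, kaiserBeta, labels) {
  N <- dim(X)[1]
  w <- signal::kaiser(N, kaiserBeta)
  P <- colMeans(aperm(abs(X)^2, c(2, 1, 3))) / (fs * sum(w^2))
  nf <- N %/% 2 + 1
  P1 <- 2 * P[seq_len(nf), , drop = FALSE]
  P1[1, ] <- P1[1, ] / 2
  if (N %% 2 == 0) P1[nf, ] <- P1[nf, ] / 2
  dimnames(P1) <- list((seq_len(nf) - 1) * fs / N, labels)
  P1
}

#' Mean in-band power
#'
#' Mean of the PSD bins whose frequency f satisfies `lo <= f <= hi`.
#'
#' @param psd matrix from [psdEpochs()] (rownames = frequency in Hz).
#' @param band one row of [eegBands()], a band name, or `c(lo, hi)`.
#' @return Named numeric vector, one value per channel.
#' @export
bandPower <- function(psd, band) {
  if (is.character(band)) {
    bands <- eegBands()
    band <- bands[bands$band == band, ]
    if (!nrow(band)) stop("unknown band name")
  }
  if (is.data.frame(band)) band <- c(band$lo, band$hi)
  f <- as.numeric(rownames(psd))
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2],
                      "] contains no frequency bins")
  colMeans(psd[sel, , drop = FALSE])
}

#' Band magnitude-squared coherence for all 91 channel pairs
#'
#' For channels x, y the magnitude-squared coherence at frequency f is
#' \deqn{\gamma^2_{xy}(f) = \frac{|\sum_k X_k(f) \bar Y_k(f)|^2}
#'   {\sum_k |X_k(f)|^2 \cdot \sum_k |Y_k(f)|^2}}
#' with the sums over retained Kaiser-windowed 1-second epochs (Welch-style
#' averaging with zero overlap). The band value is the unweighted mean over
#' in-band bins. Values lie in [0, 1] and are symmetric in channel order.
#' With L independent epochs the no-coupling floor is approximately 1/L.
#'
#' @param epochSet an [EpochSet-class] with at least 2 retained epochs
#'   (a single segment is identically coherent).
#' @param kaiserBeta Kaiser window shape parameter.
#' @param bands data.frame of band definitions (default [eegBands()]).
#' @return Matrix, 91 pairs x bands; rownames `"CH1-CH2"` in canonical
#'   montage pair order, colnames the band names.
#' @export
coherencePairs <- function(epochSet, kaiserBeta = 8, bands = eegBands()) {
  keep <- sum(!epochSet@artifactMask)
  if (keep < 2)
    stop("coherence needs >= 2 retained epochs (participant '",
         epochSet@participant, "', task '", epochSet@task, "')")
  X <- .epochFFT(epochSet, kaiserBeta)
  .cohFromFFT(X, epochSet@samplingRate, epochSet@channelLabels, bands)
}

.cohFromFFT <- function(X, fs, labs, bands) {
  .bandFeaturesFromFFT(X, fs, labs, bands)$coh
}

# coherence and band power in one pass over the per-bin cross-spectral
# Gram matrices (band power = Gram diagonal, so the epoch FFT is shared)
.bandFeaturesFromFFT <- function(X, fs, labs, bands, kaiserBeta = 8) {
  N <- dim(X)[1]
  L <- dim(X)[2]
  freqs <- (seq_len(N %/% 2 + 1) - 1) * fs / N
  nch <- dim(X)[3]

  # per-bin cross-spectral Gram matrices, restricted to bins any band needs
  needed <- which(freqs >= min(bands$lo) & freqs <= max(bands$hi))
  Xp <- aperm(X[needed, , , drop = FALSE], c(2, 3, 1))   # [epoch, ch, bin]
  gram <- array(complex(real = 0), dim = c(nch, nch, length(needed)))
  for (i in seq_along(needed)) {
    M <- Xp[, , i]                              # epochs x channels
    gram[, , i] <- crossprod(Conj(M), M)        # sum_k conj(X_k) Y_k
  }

  pairs <- channelPairs()
  pi1 <- match(pairs$ch1, labs); pi2 <- match(pairs$ch2, labs)
  if (anyNA(pi1) || anyNA(pi2))
    stop("epoch set does not carry the full 14-channel montage")
  w <- signal::kaiser(N, kaiserBeta)
  psdScale <- 2 / (L * fs * sum(w^2))
  out <- matrix(NA_real_, nrow(pairs), nrow(bands),
                dimnames = list(paste0(pairs$ch1, "-", pairs$ch2), bands$band))
  bp <- matrix(NA_real_, nrow(bands), nch,
               dimnames = list(bands$band, labs))
  diagIdx <- cbind(seq_len(nch), seq_len(nch))
  for (b in seq_len(nrow(bands))) {
    binsel <- which(freqs[needed] >= bands$lo[b] & freqs[needed] <= bands$hi[b])
    if (!length(binsel)) next
    acc <- matrix(0, nrow(pairs), length(binsel))
    accP <- matrix(0, nch, length(binsel))
    for (j in seq_along(binsel)) {
      G <- gram[, , binsel[j]]
      auto <- Re(G[diagIdx])
      num <- Mod(G[cbind(pi1, pi2)])^2
      acc[, j] <- num / (auto[pi1] * auto[pi2])
      accP[, j] <- auto * psdScale
    }
    out[, b] <- rowMeans(acc)
    bp[b, ] <- rowMeans(accP)
  }
  list(coh = out, bandPow = bp)
}

.featNames <- function(task, band, kind, what)
  sprintf("%s.%s.%s.%s", task, band, kind, what)

#' Spectral feature vector for one participant
#'
#' Computes, per task and band, the 14 channel band powers and the 91 pair
#' coherences from the retained epochs.
#'
#' @param epochsByTask named list of [EpochSet-class] (as from
#'   [epochTasks()]); every element present is featurized under its name.
#' @param kaiserBeta Kaiser window shape parameter.
#' @param bands band definition data.frame.
#' @return Named numeric vector with names `task.band.psd.CH` and
#'   `task.band.coh.CH1-CH2`.
#' @export
participantFeatures <- function(epochsByTask, kaiserBeta = 8,
                                bands = eegBands()) {
  vecs <- lapply(names(epochsByTask), function(task) {
    es <- epochsByTask[[task]]
    if (sum(!es@artifactMask) < 2)
      stop("need >= 2 retained epochs (participant '", es@participant,
           "', task '", task, "')")
    X <- .epochFFT(es, kaiserBeta)              # shared by PSD and coherence
    bf <- .bandFeaturesFromFFT(X, es@samplingRate, es@channelLabels, bands,
                               kaiserBeta)
    v <- numeric(0)
    for (b in seq_len(nrow(bands))) {
      bp <- bf$bandPow[bands$band[b], ]
      names(bp) <- .featNames(task, bands$band[b], "psd", names(bp))
      cv <- bf$coh[, bands$band[b]]
      names(cv) <- .featNames(task, bands$band[b], "coh", rownames(bf$coh))
      v <- c(v, bp, cv)
    }
    v
  })
  unlist(vecs)
}

#' Baseline-correct task features against the eyes-open segment
#'
#' Subtracts, for each participant and each (band, kind, channels) feature,
#' the participant's eyes-open baseline value from the task value. Outputs
#' may be negative; the stage becomes `"baseline_corrected"`.
#'
#' @param taskTable [FeatureTable-class] of task features (stage `"raw"`).
#' @param baselineTable [FeatureTable-class] of the same participants'
#'   baseline features (tasks labeled `"baseline"`).
#' @return A corrected [FeatureTable-class].
#' @export
baselineCorrect <- function(taskTable, baselineTable) {
  if (!identical(colnames(taskTable), colnames(baselineTable)))
    stop("participant missing a baseline: tables must cover the same ",
         "participants in the same order")
  rdT <- rowData(taskTable); rdB <- rowData(baselineTable)
  keyT <- paste(rdT$band, rdT$kind, rdT$ch1, rdT$ch2)
  keyB <- paste(rdB$band, rdB$kind, rdB$ch1, rdB$ch2)
  idx <- match(keyT, keyB)
  if (anyNA(idx))
    stop("baseline table lacks features: ",
         paste(head(rownames(taskTable)[is.na(idx)], 3), collapse = ", "))
  vals <- assay(taskTable) - assay(baselineTable)[idx, , drop = FALSE]
  out <- featureTable(vals, colData(taskTable)$group,
                      stage = "baseline_corrected")
  out
}

#' Min-max normalize each feature across participants
#'
#' Per feature (row), maps the minimum across participants to 0 and the
#' maximum to 1. Constant features become all-zero with a warning.
#'
#' @param table a [FeatureTable-class] with >= 2 participants.
#' @return A [FeatureTable-class] with stage `"normalized"`.
#' @export
minmaxNormalize <- function(table) {
  v <- assay(table)
  if (ncol(v) < 2) stop("min-max normalization needs >= 2 participants")
  lo <- apply(v, 1, min); hi <- apply(v, 1, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to all zeros")
    rng[const] <- 1
  }
  out <- (v - lo) / rng
  out[const, ] <- 0
  featureTable(out, colData(table)$group, stage = "normalized")
}

#' Extract the full feature set for a cohort
#'
#' Runs segmentation, epoching, artifact rejection and spectral feature
#' extraction for every participant, then baseline-corrects the three task
#' stages against the eyes-open segment and min-max normalizes across
#' participants.
#'
#' @param recordings named list of [Recording-class] objects.
#' @param groups character vector of group labels, one per recording.
#' @param kaiserBeta,bands spectral parameters.
#' @param absThresh,ptpThresh,flatThresh artifact thresholds, see
#'   [rejectArtifacts()].
#' @return list with [FeatureTable-class] elements `raw`, `baseline`,
#'   `corrected`, `normalized`, plus `rejectionRates` (per participant).
#' @export
cohortFeatures <- function(recordings, groups, kaiserBeta = 8,
                           bands = eegBands(), absThresh = 100,
                           ptpThresh = 200, flatThresh = 0.1) {
  stopifnot(length(recordings) == length(groups))
  ids <- names(recordings)
  if (is.null(ids)) ids <- paste0("P", seq_along(recordings))
  taskVecs <- vector("list", length(recordings))
  baseVecs <- vector("list", length(recordings))
  rates <- numeric(length(recordings))
  for (i in seq_along(recordings)) {
    eps <- epochTasks(recordings[[i]], participant = ids[i])
    eps <- lapply(eps, rejectArtifacts, absThresh = absThresh,
                  ptpThresh = ptpThresh, flatThresh = flatThresh)
    rates[i] <- rejectionRate(eps)
    worst <- vapply(eps, rejectionRate, 0)
    if (any(worst > 0.5))
      warning("participant '", ids[i], "' loses >50% of epochs in task(s) ",
              paste(names(worst)[worst > 0.5], collapse = ", "),
              "; kept, but review the recording")
    baseVecs[[i]] <- participantFeatures(eps["baseline"], kaiserBeta, bands)
    taskVecs[[i]] <- participantFeatures(
      eps[c("reading", "answer1", "answer2")], kaiserBeta, bands)
  }
  rawMat <- do.call(cbind, taskVecs)
  baseMat <- do.call(cbind, baseVecs)
  colnames(rawMat) <- colnames(baseMat) <- ids
  raw <- featureTable(rawMat, groups, stage = "raw")
  baseline <- featureTable(baseMat, groups, stage = "raw")
  corrected <- baselineCorrect(raw, baseline)
  normalized <- minmaxNormalize(corrected)
  names(rates) <- ids
  list(raw = raw, baseline = baseline, corrected = corrected,
       normalized = normalized, rejectionRates = rates)
}
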