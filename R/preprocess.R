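# Task segmentation, 1-second epoching, and threshold-based artifact
# rejection.

#' Locate the four task segments of a session
#'
#' Matches the event markers "eyes open", "reading", "answer 1", "answer 2"
#' (case-insensitively, after whitespace normalization) and returns each
#' segment's time span: from its marker to the next marker of any kind, or
#' to the end of the recording for the last segment.
#'
#' @param recording a [Recording-class] whose markers include all four
#'   segment labels.
#' @return Named list (`baseline`, `reading`, `answer1`, `answer2`) of
#'   `c(start, end)` in seconds.
#' @examples
#' cfg <- cohortConfig(segmentDurations = c(4, 4, 8, 4), seed = 1)
#' rec <- simulateRecording(cfg, 1, "novice")$recording
#' segmentTasks(rec)
#' @export
segmentTasks <- function(recording) {
  mk <- recording@markers
  if (!nrow(mk)) stop("recording has no markers")
  mk <- mk[order(mk$onset), , drop = FALSE]
  norm <- .normalizeLabel(mk$label)
  dur <- recordingDuration(recording)
  out <- list()
  for (task in names(.taskMarkers)) {
    hit <- which(norm == .taskMarkers[[task]])
    if (length(hit) == 0)
      stop("missing segment marker: '", .taskMarkers[[task]], "'")
    if (length(hit) > 1)
      stop("duplicated segment marker: '", .taskMarkers[[task]], "'")
    start <- mk$onset[hit]
    end <- if (hit < nrow(mk)) mk$onset[hit + 1] else dur
    out[[task]] <- c(start = start, end = min(end, dur))
  }
  onsets <- vapply(out, `[`, 0, 1)
  if (is.unsorted(onsets))
    stop("segment markers out of order: ",
         paste(names(.taskMarkers), collapse = " < "), " expected")
  out
}

#' Cut one task interval into 1-second epochs
#'
#' Produces `floor(duration / length)` non-overlapping epochs; any leftover
#' tail is discarded. All artifact masks start FALSE.
#'
#' @param recording a [Recording-class].
#' @param interval `c(start, end)` seconds within the recording.
#' @param task task label to attach.
#' @param length epoch length in seconds (default 1).
#' @param participant participant id to attach.
#' @return An [EpochSet-class]. An interval shorter than one epoch yields an
#'   empty set with a warning.
#' @export
epochSegment <- function(recording, interval, task = "segment", length = 1,
                         participant = "") {
  fs <- recording@samplingRate
  start <- interval[[1]]; end <- min(interval[[2]], recordingDuration(recording))
  if (end < start) stop("interval end precedes start")
  nep <- floor((end - start) / length)
  epLen <- as.integer(round(fs * length))
  if (nep == 0)
    warning("interval shorter than one epoch; returning empty EpochSet")
  s0 <- as.integer(round(start * fs))
  nch <- nrow(recording@signal)
  slab <- recording@signal[, s0 + seq_len(nep * epLen), drop = FALSE]
  dim(slab) <- c(nch, epLen, nep)              # [channel, sample, epoch]
  arr <- aperm(slab, c(3, 1, 2))               # [epoch, channel, sample]
  new("EpochSet", task = task, epochs = arr,
      channelLabels = recording@channelLabels,
      artifactMask = logical(nep), samplingRate = epLen / length,
      participant = as.character(participant))
}

#' Epoch all four task segments of a recording
#'
#' Convenience wrapper: [segmentTasks()] then [epochSegment()] per segment.
#'
#' @inheritParams epochSegment
#' @return Named list of [EpochSet-class] objects
#'   (`baseline`, `reading`, `answer1`, `answer2`).
#' @export
epochTasks <- function(recording, length = 1, participant = "") {
  segs <- segmentTasks(recording)
  out <- lapply(names(segs), function(task)
    epochSegment(recording, segs[[task]], task = task, length = length,
                 participant = participant))
  names(out) <- names(segs)
  out
}

#' Mask artifact-contaminated epochs
#'
#' An epoch is masked when any channel violates any threshold within that
#' epoch alone (no cross-epoch information is used): absolute deviation from
#' the epoch mean above `absThresh`, peak-to-peak range above `ptpThresh`,
#' or peak-to-peak below `flatThresh` (flatlined electrode). Stricter
#' thresholds can only mask more epochs, never fewer. Defaults are standard
#' quantitative-EEG practice for wet-electrode consumer headsets.
#'
#' Real artifact screening typically has a manual component; `keepEpochs`
#' emulates a reviewer's override list: those epoch indices are left
#' unmasked whatever the thresholds say.
#'
#' @param epochSet an [EpochSet-class].
#' @param absThresh max |sample - epoch channel mean| in microvolts.
#' @param ptpThresh max peak-to-peak range in microvolts.
#' @param flatThresh min peak-to-peak range in microvolts.
#' @param keepEpochs epoch indices exempted from rejection (manual override).
#' @return The [EpochSet-class] with an updated artifact mask.
#' @export
rejectArtifacts <- function(epochSet, absThresh = 100, ptpThresh = 200,
                            flatThresh = 0.1, keepEpochs = integer()) {
  stopifnot(absThresh > 0, ptpThresh > 0, flatThresh > 0)
  d <- dim(epochSet@epochs)
  if (d[1] == 0) return(epochSet)
  flat <- epochSet@epochs
  dim(flat) <- c(d[1] * d[2], d[3])            # rows = (epoch, channel)
  mu <- rowMeans(flat)
  cols <- lapply(seq_len(d[3]), function(s) flat[, s])
  hi <- do.call(pmax, cols); lo <- do.call(pmin, cols)
  maxdev <- pmax(hi - mu, mu - lo)
  ptp <- hi - lo
  viol <- matrix(maxdev > absThresh | ptp > ptpThresh | ptp < flatThresh,
                 d[1], d[2])
  bad <- rowSums(viol) > 0
  bad[intersect(keepEpochs, seq_len(d[1]))] <- FALSE
  epochSet@artifactMask <- epochSet@artifactMask | bad
  epochSet
}

#' Fraction of epochs masked as artifacts
#'
#' @param epochSets an [EpochSet-class] or list of them.
#' @return Fraction of masked epochs (pooled over the list).
#' @export
rejectionRate <- function(epochSets) {
  if (is(epochSets, "EpochSet")) epochSets <- list(epochSets)
  masks <- unlist(lapply(epochSets, artifactMask))
  if (!length(masks)) return(0)
  mean(masks)
}
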