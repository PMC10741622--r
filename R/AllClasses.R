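#' Canonical 14-channel montage
#'
#' Channel labels of the wireless headset's 10-20 subset, in canonical order.
#' All downstream channel-pair indexing (the 91 coherence features per task
#' and band) refers to this ordering, which makes feature vectors
#' deterministic across recordings regardless of on-disk channel order.
#'
#' @return Character vector of 14 channel labels.
#' @examples
#' montageChannels()
#' @export
montageChannels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' All unordered channel pairs of the canonical montage
#'
#' @return A data.frame with columns `ch1`, `ch2` (91 rows, canonical order).
#' @examples
#' nrow(channelPairs())  # choose(14, 2) = 91
#' @export
channelPairs <- function() {
  idx <- combn(montageChannels(), 2)
  data.frame(ch1 = idx[1, ], ch2 = idx[2, ], stringsAsFactors = FALSE)
}

#' Default EEG frequency bands
#'
#' Band edges in Hz, inclusive at the 1 Hz bin resolution implied by 1-second
#' epochs: delta 1-3, theta 4-7, alpha 8-12, beta 13-30, gamma 31-45. The
#' gamma band is capped at 45 Hz (the headset passband is 0.2-45 Hz) and
#' starts above the beta edge so that bands partition the bins.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @examples
#' eegBands()
#' @export
eegBands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo   = c(1, 4, 8, 13, 31),
             hi   = c(3, 7, 12, 30, 45),
             stringsAsFactors = FALSE)
}

# task label vocabulary: canonical task id -> marker label on disk
.taskMarkers <- c(baseline = "eyes open", reading = "reading",
                  answer1 = "answer 1", answer2 = "answer 2")

.normalizeLabel <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Recording: a multichannel EEG recording with event markers
#'
#' Holds a channels-by-samples signal matrix in microvolts, channel labels,
#' the sampling rate, timed event markers, and free-form provenance metadata.
#'
#' @slot channelLabels character, one label per row of `signal`.
#' @slot samplingRate sampling rate in Hz.
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot markers data.frame with columns `label` and `onset` (seconds).
#' @slot meta list of provenance fields.
#'
#' @seealso [readRecording()], [writeRecording()], [validateMontage()]
#' @export
setClass("Recording",
  representation(channelLabels = "character", samplingRate = "numeric",
                 signal = "matrix", markers = "data.frame", meta = "list"))

setValidity("Recording", function(object) {
  msgs <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  if (nrow(object@signal) != length(object@channelLabels))
    msgs <- c(msgs, "signal must have one row per channel label")
  if (anyDuplicated(object@channelLabels))
    msgs <- c(msgs, "channel labels must be unique")
  if (!all(c("label", "onset") %in% names(object@markers)))
    msgs <- c(msgs, "markers must have columns 'label' and 'onset'")
  else {
    dur <- ncol(object@signal) / object@samplingRate
    if (nrow(object@markers) && (any(object@markers$onset < 0) ||
                                 any(object@markers$onset > dur)))
      msgs <- c(msgs, "marker onsets must lie within [0, duration]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Recording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param channelLabels character vector, one per row.
#' @param samplingRate Hz.
#' @param markers data.frame with `label`, `onset` columns (may be empty).
#' @param meta list of provenance fields.
#' @return A [Recording-class] object.
#' @examples
#' rec <- newRecording(matrix(rnorm(14 * 256), 14), montageChannels(), 256)
#' recordingDuration(rec)
#' @export
newRecording <- function(signal, channelLabels, samplingRate,
                         markers = data.frame(label = character(),
                                              onset = numeric()),
                         meta = list()) {
  rownames(signal) <- channelLabels
  new("Recording", channelLabels = channelLabels,
      samplingRate = samplingRate, signal = signal,
      markers = as.data.frame(markers), meta = meta)
}

#' EpochSet: fixed-length epochs of one task segment
#'
#' @slot task one of baseline/reading/answer1/answer2 (or a free label).
#' @slot epochs numeric array epoch x channel x sample.
#' @slot channelLabels character.
#' @slot artifactMask logical, TRUE marks an epoch as artifact-contaminated.
#' @slot samplingRate Hz; epochs have exactly `samplingRate` samples (1 s).
#' @slot participant participant identifier.
#' @export
setClass("EpochSet",
  representation(task = "character", epochs = "array",
                 channelLabels = "character", artifactMask = "logical",
                 samplingRate = "numeric", participant = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msgs <- character()
  if (length(d) != 3)
    msgs <- c(msgs, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (d[3] != object@samplingRate)
      msgs <- c(msgs, "each epoch must have exactly samplingRate samples (1 s)")
    if (d[2] != length(object@channelLabels))
      msgs <- c(msgs, "channel dimension must match channelLabels")
    if (d[1] != length(object@artifactMask))
      msgs <- c(msgs, "artifactMask must have one entry per epoch")
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureTable: participant-by-feature matrix as a SummarizedExperiment
#'
#' Rows are features, columns participants. `rowData` carries the feature
#' decomposition (`task`, `band`, `kind`, `ch1`, `ch2`); `colData` carries the
#' expertise group; `metadata(x)$stage` is one of `"raw"`,
#' `"baseline_corrected"`, `"normalized"`. Raw coherence features lie in
#' [0, 1]; baseline-corrected values may be negative; normalized columns are
#' min-max scaled to [0, 1] per feature across participants.
#'
#' @seealso [featureTable()], [cohortFeatures()], [baselineCorrect()],
#'   [minmaxNormalize()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  st <- metadata(object)$stage
  if (is.null(st) ||
      !st %in% c("raw", "baseline_corrected", "normalized"))
    return("metadata(x)$stage must be raw/baseline_corrected/normalized")
  if (st == "raw") {
    coh <- rowData(object)$kind == "coh"
    v <- assay(object)[coh, , drop = FALSE]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      return("raw coherence features must lie in [0, 1]")
  }
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values features x participants numeric matrix; rownames are feature
#'   names of the form `task.band.kind.channels` (e.g.
#'   `"reading.theta.coh.FC5-FC6"`, `"answer1.beta.psd.F7"`).
#' @param group character/factor of expertise labels, one per participant.
#' @param stage processing stage tag.
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(values, group, stage = "raw") {
  stopifnot(!is.null(rownames(values)))
  parts <- strsplit(rownames(values), ".", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad))
    stop("feature names must be task.band.kind.channels; offending: ",
         paste(head(rownames(values)[bad], 3), collapse = ", "))
  info <- do.call(rbind, parts)
  chs <- strsplit(info[, 4], "-", fixed = TRUE)
  rd <- DataFrame(task = info[, 1], band = info[, 2], kind = info[, 3],
                  ch1 = vapply(chs, `[`, "", 1),
                  ch2 = vapply(chs, function(z) if (length(z) > 1) z[2] else NA_character_, ""))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("P", seq_len(ncol(values)))
  se <- SummarizedExperiment(assays = list(values = values), rowData = rd,
                             colData = DataFrame(group = as.character(group),
                                                 row.names = colnames(values)))
  metadata(se)$stage <- stage
  new("FeatureTable", se)
}

#' ModelFit: a Lasso-selected, OLS-refit linear model
#'
#' @slot outcome outcome name.
#' @slot selected names of Lasso-selected features.
#' @slot coefficients data.frame: term, estimate, std.error, p.value.
#' @slot r2 coefficient of determination of the OLS refit.
#' @slot lambda penalty chosen by cross-validation (minimum mean CV MSE).
#' @slot cvLambda lambda grid of the CV curve.
#' @slot cvMSE mean cross-validated MSE per grid point.
#' @slot seed fold seed.
#' @slot nobs number of observations.
#' @export
setClass("ModelFit",
  representation(outcome = "character", selected = "character",
                 coefficients = "data.frame", r2 = "numeric",
                 lambda = "numeric", cvLambda = "numeric", cvMSE = "numeric",
                 seed = "numeric", nobs = "numeric"))

setValidity("ModelFit", function(object) {
  if (length(object@r2) && !is.na(object@r2) &&
      (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
    return("r2 must lie in [0, 1]")
  if (length(object@lambda) && !is.na(object@lambda) && object@lambda < 0)
    return("lambda must be nonnegative")
  TRUE
})

#' CohortConfig: design of a synthetic study cohort
#'
#' Bundles everything the generator needs: group sizes, the session plan
#' (marker label and duration of each segment), the designed coherence
#' effects, the background-spectrum model, the artifact contamination rate,
#' the behavioral linear model, and the master seed. Defaults reproduce the
#' study conditions: n = 8 per group, 256 Hz, segments eyes open / reading /
#' answer 1 / answer 2 of 180/180/720/180 s, designed band-coherence
#' contrasts at the reported channel pairs, and ~10% contaminated epochs.
#'
#' @slot nPerGroup participants per group (novice, experienced).
#' @slot samplingRate Hz.
#' @slot segmentPlan data.frame `label`, `duration` (seconds).
#' @slot effectTable data.frame `ch1`,`ch2`,`band`,`task`,`cohExperienced`,
#'   `cohNovice` — target band coherence per group.
#' @slot background list: `alpha` (1/f exponent), `sd` (background SD, uV),
#'   `alphaAmp` (posterior 10 Hz oscillation SD, uV), `alphaChannels`.
#' @slot artifactRate fraction of epochs to contaminate.
#' @slot behaviorModel list with `performance`, `tlx` (each: intercept,
#'   named coef, noiseSD), `raterNoise`, `nItems`, `itemWeights`.
#' @slot seed master seed.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig",
  representation(nPerGroup = "numeric", samplingRate = "numeric",
                 segmentPlan = "data.frame", effectTable = "data.frame",
                 background = "list", artifactRate = "numeric",
                 behaviorModel = "list", seed = "numeric"))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nPerGroup < 2) msgs <- c(msgs, "nPerGroup must be >= 2")
  if (object@artifactRate < 0 || object@artifactRate >= 1)
    msgs <- c(msgs, "artifactRate must lie in [0, 1)")
  if (any(object@segmentPlan$duration <= 0))
    msgs <- c(msgs, "segment durations must be positive")
  et <- object@effectTable
  if (nrow(et)) {
    tg <- c(et$cohExperienced, et$cohNovice)
    if (any(tg < 0) || any(tg > 1))
      msgs <- c(msgs, "target coherences must lie in [0, 1]")
    if (any(tg == 1))
      msgs <- c(msgs, "coherence target of exactly 1 is unattainable with nonzero noise")
    if (any(et$ch1 == et$ch2))
      msgs <- c(msgs, "effect pairs must join distinct channels")
    if (!all(c(et$ch1, et$ch2) %in% montageChannels()))
      msgs <- c(msgs, "effect channels must belong to the montage")
    key <- paste(pmin(et$ch1, et$ch2), pmax(et$ch1, et$ch2), et$band, et$task)
    if (anyDuplicated(key))
      msgs <- c(msgs, "overlapping effect entries on the same (pair, band, task)")
  }
  if (length(msgs)) msgs else TRUE
})
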