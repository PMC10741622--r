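# Recording input/output.
#
# Three on-disk forms are supported:
#   * "csv"  - diffable fixture dialect: one row per sample, first column the
#              time in seconds, one column per channel; markers and metadata
#              in a JSON sidecar ("<stem>.json").
#   * "edf"  - EDF/EDF+ with markers as EDF+ annotations (read and write).
#   * "xdf"  - chunked lab-streaming container (read; see writeXDF for the
#              minimal writer used to build test fixtures).
# Channels are reordered into canonical montage order on read whenever all
# labels belong to the montage.

.canonicalize <- function(rec) {
  mont <- montageChannels()
  if (all(rec@channelLabels %in% mont)) {
    ord <- order(match(rec@channelLabels, mont))
    rec@channelLabels <- rec@channelLabels[ord]
    rec@signal <- rec@signal[ord, , drop = FALSE]
    rownames(rec@signal) <- rec@channelLabels
  }
  rec
}

.sniffFormat <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", edf = "edf", xdf = "xdf",
         stop("cannot infer format from extension of ", path))
}

#' Read an EEG recording
#'
#' Reads a recording from EDF/EDF+, XDF, or the CSV fixture dialect, converts
#' samples to microvolts, extracts markers from the format's annotation
#' stream (EDF+ annotations, XDF marker stream, or the CSV JSON sidecar), and
#' reorders channels into canonical montage order when all labels are
#' montage channels. Markers with labels outside the expected task vocabulary
#' are kept and flagged in `meta$unknown_markers`.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"edf"`, `"xdf"`; inferred from the file
#'   extension by default.
#' @return A [Recording-class].
#' @seealso [writeRecording()], [validateMontage()]
#' @export
readRecording <- function(path, format = c("auto", "csv", "edf", "xdf")) {
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path)
  if (!file.exists(path)) stop("file does not exist: ", path)
  rec <- switch(format,
                csv = .readCSVRecording(path),
                edf = readEDF(path),
                xdf = readXDF(path))
  known <- .normalizeLabel(rec@markers$label) %in% .taskMarkers
  if (any(!known))
    rec@meta$unknown_markers <- rec@markers$label[!known]
  .canonicalize(rec)
}

#' Write an EEG recording
#'
#' @param recording a [Recording-class].
#' @param path output path.
#' @param format `"csv"` (fixture dialect + JSON sidecar) or `"edf"` (EDF+
#'   with annotations); inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path, format = c("auto", "csv", "edf")) {
  validObject(recording)
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path)
  switch(format,
         csv = .writeCSVRecording(recording, path),
         edf = writeEDF(recording, path))
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.[^.]+$", ".json", path)

.readCSVRecording <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  labs <- names(dt)[-1]
  side <- .sidecarPath(path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  mk <- if (!is.null(sc$markers) && length(sc$markers))
    data.frame(label = as.character(sc$markers$label),
               onset = as.numeric(sc$markers$onset))
  else data.frame(label = character(), onset = numeric())
  newRecording(t(as.matrix(dt[, -1])), labs, as.numeric(sc$sampling_rate),
               markers = mk,
               meta = if (is.null(sc$meta)) list() else as.list(sc$meta))
}

.writeCSVRecording <- function(recording, path) {
  n <- ncol(recording@signal)
  dt <- data.table::as.data.table(t(recording@signal))
  data.table::setnames(dt, recording@channelLabels)
  dt <- cbind(data.table::data.table(time = (seq_len(n) - 1) / recording@samplingRate), dt)
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(sampling_rate = recording@samplingRate,
         channels = recording@channelLabels,
         markers = recording@markers,
         meta = recording@meta),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a recording against the study montage
#'
#' Report-only check: lists montage channels that are missing, extra
#' non-montage channels, missing task segment markers (eyes open, reading,
#' answer 1, answer 2), and non-finite samples (with channel and sample
#' index of the first occurrence per channel).
#'
#' @param recording a [Recording-class].
#' @return data.frame with columns `issue` and `detail`; zero rows when the
#'   recording is canonical.
#' @export
validateMontage <- function(recording) {
  issues <- list()
  mont <- montageChannels()
  miss <- setdiff(mont, recording@channelLabels)
  if (length(miss))
    issues <- c(issues, list(c("missing_channel", paste(miss, collapse = " "))))
  extra <- setdiff(recording@channelLabels, mont)
  if (length(extra))
    issues <- c(issues, list(c("extra_channel", paste(extra, collapse = " "))))
  have <- .normalizeLabel(recording@markers$label)
  for (seg in names(.taskMarkers))
    if (!.taskMarkers[[seg]] %in% have)
      issues <- c(issues, list(c("missing_segment", unname(.taskMarkers[[seg]]))))
  bad <- which(!is.finite(recording@signal), arr.ind = TRUE)
  if (nrow(bad)) {
    first <- bad[!duplicated(bad[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(first)))
      issues <- c(issues, list(c("nonfinite_sample",
        sprintf("%s@%d", recording@channelLabels[first[i, 1]], first[i, 2]))))
  }
  out <- data.frame(issue = vapply(issues, `[`, "", 1),
                    detail = vapply(issues, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out
}
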