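# Minimal XDF (extensible data format) codec for lab-streaming recordings.
#
# The reader understands the chunked container: magic "XDF:", then chunks of
# [NumLengthBytes (1|4|8)][Length][Tag uint16 LE][content], with tags
# 1 FileHeader, 2 StreamHeader, 3 Samples, 4 ClockOffset, 5 Boundary,
# 6 StreamFooter. Numeric streams (float32/double64) become the signal
# matrix; a string-format stream of type "Markers" becomes the marker list,
# with onsets expressed relative to the first EEG timestamp. writeXDF is a
# deliberately small writer used to build round-trip fixtures.

.readUint <- function(con, nbytes) {
  if (nbytes < 4) {
    as.numeric(readBin(con, integer(), 1, size = nbytes, signed = FALSE,
                       endian = "little"))
  } else if (nbytes == 4) {
    v <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (v < 0) v <- v + 2^32                   # R ints are signed
    as.numeric(v)
  } else {
    lo <- .readUint(con, 4)
    hi <- .readUint(con, 4)
    lo + hi * 2^32
  }
}

.readVarlen <- function(con) {
  n <- readBin(con, integer(), 1, size = 1, signed = FALSE)
  if (!n %in% c(1, 4, 8)) stop("corrupt XDF stream: bad length tag ", n,
                               " at byte ", seek(con, NA))
  .readUint(con, n)
}

#' Read an XDF recording
#'
#' @param path an XDF file containing one numeric EEG stream (float32 or
#'   double64 samples) and optionally one string-format marker stream.
#' @return A [Recording-class]; marker onsets are seconds relative to the
#'   first EEG sample.
#' @export
readXDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "XDF:"))
    stop("corrupt XDF stream: bad magic at byte 0 of ", path)
  streams <- list()
  repeat {
    nlb <- readBin(con, integer(), 1, size = 1, signed = FALSE)
    if (length(nlb) == 0) break
    if (!nlb %in% c(1, 4, 8))
      stop("corrupt XDF stream: bad chunk length tag at byte ", seek(con, NA))
    len <- .readUint(con, nlb)
    tag <- readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little")
    body <- len - 2
    if (tag == 2) {                            # StreamHeader
      sid <- as.character(.readUint(con, 4))
      xmlTxt <- readChar(con, body - 4, useBytes = TRUE)
      info <- xml2::read_xml(xmlTxt)
      get1 <- function(q) xml2::xml_text(xml2::xml_find_first(info, q))
      labels <- xml2::xml_text(
        xml2::xml_find_all(info, ".//channels/channel/label"))
      streams[[sid]] <- list(
        name = get1("./name"), type = get1("./type"),
        nch = as.integer(get1("./channel_count")),
        srate = as.numeric(get1("./nominal_srate")),
        fmt = get1("./channel_format"), labels = labels,
        samples = list(), stamps = list())
    } else if (tag == 3) {                     # Samples
      sid <- as.character(.readUint(con, 4))
      st <- streams[[sid]]
      if (is.null(st)) stop("XDF samples for undeclared stream ", sid)
      ns <- .readVarlen(con)
      vals <- if (st$fmt == "string") character(ns) else
        matrix(NA_real_, st$nch, ns)
      stamps <- rep(NA_real_, ns)
      for (i in seq_len(ns)) {
        tb <- readBin(con, integer(), 1, size = 1, signed = FALSE)
        if (tb == 8) stamps[i] <- readBin(con, double(), 1, endian = "little")
        if (st$fmt == "string") {
          sl <- .readVarlen(con)
          vals[i] <- readChar(con, sl, useBytes = TRUE)
        } else if (st$fmt == "float32") {
          vals[, i] <- readBin(con, double(), st$nch, size = 4, endian = "little")
        } else if (st$fmt == "double64") {
          vals[, i] <- readBin(con, double(), st$nch, size = 8, endian = "little")
        } else stop("unsupported XDF channel format: ", st$fmt)
      }
      streams[[sid]]$samples <- c(st$samples, list(vals))
      streams[[sid]]$stamps <- c(st$stamps, list(stamps))
    } else {                                   # FileHeader/ClockOffset/etc.
      if (body > 0) readBin(con, "raw", body)
    }
  }

  isEEG <- vapply(streams, function(s) s$fmt != "string", TRUE)
  if (!any(isEEG)) stop("no numeric EEG stream found in ", path)
  eeg <- streams[[which(isEEG)[1]]]
  sig <- do.call(cbind, eeg$samples)
  stamps <- unlist(eeg$stamps)
  # fill deducible timestamps forward at the nominal rate
  t0 <- stamps[which(!is.na(stamps))[1]]
  if (is.na(t0)) t0 <- 0
  labs <- if (length(eeg$labels) == eeg$nch) eeg$labels else
    paste0("CH", seq_len(eeg$nch))

  mk <- data.frame(label = character(), onset = numeric())
  for (s in streams[!isEEG]) {
    lab <- unlist(s$samples)
    on <- unlist(s$stamps) - t0
    mk <- rbind(mk, data.frame(label = lab, onset = on))
  }
  mk <- mk[order(mk$onset), , drop = FALSE]
  newRecording(sig, labs, eeg$srate, markers = mk,
               meta = list(source = path, format = "xdf",
                           stream_name = eeg$name))
}

.writeVarlen <- function(con, x) {
  writeBin(as.integer(4), con, size = 1)
  writeBin(as.integer(x), con, size = 4, endian = "little")
}

.writeChunk <- function(con, tag, payload) {
  .writeVarlen(con, length(payload) + 2)
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(payload, con)
}

#' Write a minimal XDF container (fixture support)
#'
#' Writes one double64 EEG stream (all samples time-stamped at the nominal
#' rate from time 0) and one string marker stream. Intended for building
#' round-trip test fixtures, not for interoperability with every XDF
#' consumer.
#'
#' @param recording a [Recording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXDF <- function(recording, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("XDF:", con, 4, eos = NULL)
  .writeChunk(con, 1, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>"))

  chXml <- paste0(vapply(recording@channelLabels, function(l)
    sprintf("<channel><label>%s</label><unit>microvolts</unit></channel>", l), ""),
    collapse = "")
  hdr <- sprintf(paste0(
    "<?xml version=\"1.0\"?><info><name>EEG</name><type>EEG</type>",
    "<channel_count>%d</channel_count><nominal_srate>%g</nominal_srate>",
    "<channel_format>double64</channel_format><desc><channels>%s</channels></desc></info>"),
    nrow(recording@signal), recording@samplingRate, chXml)
  .writeChunk(con, 2, c(writeBin(1L, raw(), size = 4, endian = "little"),
                        charToRaw(hdr)))

  n <- ncol(recording@signal)
  stamps <- (seq_len(n) - 1) / recording@samplingRate
  body <- raw(0)
  buf <- rawConnection(raw(0), "wb")
  writeBin(1L, buf, size = 4, endian = "little")        # stream id
  writeBin(as.integer(4), buf, size = 1)
  writeBin(as.integer(n), buf, size = 4, endian = "little")
  for (i in seq_len(n)) {
    writeBin(as.integer(8), buf, size = 1)
    writeBin(stamps[i], buf, endian = "little")
    writeBin(recording@signal[, i], buf, size = 8, endian = "little")
  }
  body <- rawConnectionValue(buf); close(buf)
  .writeChunk(con, 3, body)

  mhdr <- paste0("<?xml version=\"1.0\"?><info><name>Markers</name>",
                 "<type>Markers</type><channel_count>1</channel_count>",
                 "<nominal_srate>0</nominal_srate>",
                 "<channel_format>string</channel_format></info>")
  .writeChunk(con, 2, c(writeBin(2L, raw(), size = 4, endian = "little"),
                        charToRaw(mhdr)))
  if (nrow(recording@markers)) {
    buf <- rawConnection(raw(0), "wb")
    writeBin(2L, buf, size = 4, endian = "little")
    writeBin(as.integer(4), buf, size = 1)
    writeBin(as.integer(nrow(recording@markers)), buf, size = 4, endian = "little")
    for (i in seq_len(nrow(recording@markers))) {
      writeBin(as.integer(8), buf, size = 1)
      writeBin(recording@markers$onset[i], buf, endian = "little")
      lab <- charToRaw(recording@markers$label[i])
      writeBin(as.integer(4), buf, size = 1)
      writeBin(length(lab), buf, size = 4, endian = "little")
      writeBin(lab, buf)
    }
    body <- rawConnectionValue(buf); close(buf)
    .writeChunk(con, 3, body)
  }
  invisible(path)
}
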