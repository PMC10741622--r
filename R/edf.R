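# Minimal EDF/EDF+ codec.
#
# Covers what the pipeline needs: continuous (EDF+C) recordings, 2-byte
# samples with per-signal physical/digital scaling, and event markers stored
# as EDF+ time-stamped annotation lists (TALs) in an "EDF Annotations"
# signal. One data record = 1 s. Samples are quantized to the 16-bit digital
# range, so write-then-read agrees with the original up to one least
# significant bit of the recorded gain.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

# numeric -> ascii field of at most 8 chars
.edfNum8 <- function(x) {
  for (d in 7:0) {
    s <- formatC(x, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", x, " in 8 characters")
}

.annotBytesNeeded <- function(markers, nrec) {
  base <- 20                                     # timekeeping TAL + slack
  if (!nrow(markers)) return(base)
  per <- max(nchar(sprintf("+%.4f", markers$onset)) + nchar(markers$label) + 3)
  base + per * max(1, nrow(markers))
}

#' Write a recording as EDF+
#'
#' @param recording a [Recording-class]; duration is padded with zeros to a
#'   whole number of 1-second records if needed.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readEDF()], [writeRecording()]
#' @export
writeEDF <- function(recording, path) {
  fs <- recording@samplingRate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  sig <- recording@signal
  nch <- nrow(sig)
  nrec <- ceiling(ncol(sig) / fs)
  if (ncol(sig) < nrec * fs)
    sig <- cbind(sig, matrix(0, nch, nrec * fs - ncol(sig)))

  pmin <- apply(sig, 1, min); pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  pmin <- vapply(pmin, function(v) as.numeric(.edfNum8(v * (1 + 1e-6) - 1e-6)), 0)
  pmax <- vapply(pmax, function(v) as.numeric(.edfNum8(v * (1 + 1e-6) + 1e-6)), 0)
  gain <- (pmax - pmin) / 65535
  if (any(gain > 0.51))
    warning("amplitude range exceeds the headset's 0.51 uV/bit resolution; ",
            "rescaled with gain(s) up to ", signif(max(gain), 3), " uV/bit")

  annSamp <- ceiling(.annotBytesNeeded(recording@markers, nrec) / 2)
  ns <- nch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edfPad(x, width), con, width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate 01-JAN-2020 X X X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("EDF+C", 44); wr(nrec, 8); wr("1", 8); wr(ns, 4)
  labs <- c(recording@channelLabels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr(if (i <= nch) "AgAgCl electrode" else "", 80)
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) .edfNum8(pmin[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) .edfNum8(pmax[i]) else "1", 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) "HP:0.2Hz LP:45Hz" else "", 80)
  for (i in seq_len(ns)) wr(if (i <= nch) fs else annSamp, 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- round((sig - pmin) / gain) - 32768
  dig[dig < -32768] <- -32768; dig[dig > 32767] <- 32767
  mk <- recording@markers
  mkNorm <- if (nrow(mk)) floor(mk$onset) else numeric()
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    tal <- sprintf("+%d\x14\x14", r - 1)
    if (nrow(mk)) {
      inrec <- which(mkNorm == r - 1)
      for (i in inrec)
        tal <- paste0(tal, sprintf("+%.4f\x14%s\x14", mk$onset[i], mk$label[i]))
    }
    raw <- c(charToRaw(tal), as.raw(0))
    raw <- c(raw, raw(annSamp * 2 - length(raw)))
    writeBin(raw, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Parses the header and all data records, rescales each signal from digital
#' to physical units, and extracts event markers from any "EDF Annotations"
#' signal (timekeeping-only TALs are dropped).
#'
#' @param path an EDF/EDF+ file.
#' @return A [Recording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (bad version field) at byte 0: ", path)
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recDur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)               # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)               # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  isAnn <- labs == "EDF Annotations"
  gain <- (pmax - pmin) / (dmax - dmin)

  dat <- vector("list", sum(!isAnn))
  for (j in seq_along(dat)) dat[[j]] <- matrix(0, nsamp[!isAnn][j], nrec)
  annRaw <- raw()
  seek(con, hdrBytes)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      if (isAnn[s]) {
        annRaw <- c(annRaw, readBin(con, "raw", nsamp[s] * 2))
      } else {
        v <- readBin(con, integer(), nsamp[s], size = 2, signed = TRUE,
                     endian = "little")
        if (length(v) < nsamp[s])
          stop("corrupt EDF stream: truncated record ", r, " at byte ",
               seek(con, NA))
        j <- sum(!isAnn[1:s])
        dat[[j]][, r] <- v
      }
    }
  }
  chan <- which(!isAnn)
  sigmat <- matrix(0, length(chan), nrec * nsamp[chan[1]])
  for (j in seq_along(chan)) {
    scale <- gain[chan[j]]
    sigmat[j, ] <- as.vector(dat[[j]]) * scale + pmin[chan[j]] - dmin[chan[j]] * scale
  }
  uu <- tolower(units[chan])
  mv <- uu %in% c("mv")
  if (any(mv)) sigmat[mv, ] <- sigmat[mv, ] * 1000
  vv <- uu %in% c("v")
  if (any(vv)) sigmat[vv, ] <- sigmat[vv, ] * 1e6

  mk <- data.frame(label = character(), onset = numeric())
  if (length(annRaw)) {
    txt <- rawToChar(annRaw[annRaw != as.raw(0)], multiple = FALSE)
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
    for (t in tals) {
      fields <- strsplit(t, "\x14", fixed = TRUE)[[1]]
      i <- 1
      while (i + 1 <= length(fields)) {        # (onset, label) pairs; a lone
        on <- suppressWarnings(as.numeric(fields[i]))  # trailing timestamp is
        lab <- fields[i + 1]                   # the next record's timekeeper
        if (!is.na(on) && nzchar(lab))
          mk <- rbind(mk, data.frame(label = lab, onset = on))
        i <- i + 2
      }
    }
  }
  newRecording(sigmat, labs[chan], nsamp[chan[1]] / recDur, markers = mk,
               meta = list(source = path, format = "edf"))
}
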