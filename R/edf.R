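# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a 256-byte ASCII header, ns * 256 bytes of per-signal header
# fields (grouped field-wise), then data records of 16-bit little-endian
# samples, signal by signal. Physical values are linearly coded between the
# per-signal digital and physical ranges. Only plain EDF is handled (no
# EDF+ annotation signals); data-record duration is fixed at 1 s on write.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edfField <- function(raw, from, width) {
  trimws(rawToChar(raw[from:(from + width - 1L)]))
}

#' Write an EEGRecord to an EDF file
#'
#' Samples are quantized to 16 bits with the physical range set from each
#' channel's min/max, so a read-back reproduces the signal to within one
#' quantization step of that range. The record duration must be a whole
#' number of seconds and the sampling rate an integer.
#'
#' @param record an [EEGRecord-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(record, path) {
  stopifnot(is(record, "EEGRecord"))
  fs <- samplingRate(record)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writing requires an integer sampling rate")
  fs <- as.integer(round(fs))
  dur <- durationS(record)
  if (abs(dur - round(dur)) > 1e-9)
    stop("EDF writing requires a whole number of seconds")
  nRec <- as.integer(round(dur))
  sig <- signalMatrix(record)
  ns <- ncol(sig)

  physMin <- apply(sig, 2, min)
  physMax <- apply(sig, 2, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768L
  digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad(subjectId(record), 80),
    edfPad("spectroseize synthetic recording", 80),
    edfPad("01.01.20", 8),
    edfPad("00.00.00", 8),
    edfPad(256L * (ns + 1L), 8),
    edfPad("", 44),
    edfPad(nRec, 8),
    edfPad(1L, 8),
    edfPad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(values, width)
    writeChar(paste0(vapply(values, edfPad, "", width = width),
                     collapse = ""), con, eos = NULL)
  fld(channelLabels(record), 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(physMin, digits = 6, format = "g"), 8)
  fld(formatC(physMax, digits = 6, format = "g"), 8)
  fld(rep(digMin, ns), 8)
  fld(rep(digMax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- matrix(0L, nrow(sig), ns)
  for (j in seq_len(ns)) {
    d <- round((sig[, j] - physMin[j]) * scale[j]) + digMin
    dig[, j] <- as.integer(pmin(pmax(d, digMin), digMax))
  }
  for (r in seq_len(nRec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns))
      writeBin(dig[rows, j], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read selected channels of an EDF file
#'
#' Channels are returned in the requested order. A requested bipolar label
#' such as \code{"FP2-F8"} is taken from the file directly when stored;
#' otherwise, if both referential channels \code{"FP2"} and \code{"F8"}
#' exist, the derivation is computed as their difference. The stored
#' bipolar channel wins when both routes are possible.
#'
#' @param path EDF file path.
#' @param channelLabels character vector of channel labels to extract.
#' @return an [EEGRecord-class] (with an empty seizure table; annotations
#'   live in separate summary files, see [readChbmitAnnotations()]).
#' @examples
#' cfg <- synthConfig(durationS = 4, seed = 1)
#' f <- tempfile(fileext = ".edf")
#' writeEDF(generateRecord(cfg), f)
#' rec <- readEDF(f, c("FP2-F8", "F8-T8", "T8-P8"))
#' @export
readEDF <- function(path, channelLabels) {
  if (!file.exists(path))
    stop(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256L)
  ns <- as.integer(edfField(fixed, 253L, 4L))
  nRec <- as.integer(edfField(fixed, 237L, 8L))
  recDur <- as.numeric(edfField(fixed, 245L, 8L))
  patient <- edfField(fixed, 9L, 80L)
  if (is.na(ns) || ns < 1L)
    stop("malformed EDF header: bad signal count")

  sigHdr <- readBin(con, "raw", 256L * ns)
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(j)
      edfField(sigHdr, offset + (j - 1L) * width + 1L, width), "")
  }
  off <- 0L
  labels <- grab(off, 16L); off <- off + 16L * ns
  off <- off + 80L * ns                      # transducer
  off <- off + 8L * ns                       # physical dimension
  physMin <- as.numeric(grab(off, 8L)); off <- off + 8L * ns
  physMax <- as.numeric(grab(off, 8L)); off <- off + 8L * ns
  digMin <- as.numeric(grab(off, 8L)); off <- off + 8L * ns
  digMax <- as.numeric(grab(off, 8L)); off <- off + 8L * ns
  off <- off + 80L * ns                      # prefiltering
  sampPerRec <- as.integer(grab(off, 8L))

  raw <- readBin(con, "integer", n = sum(sampPerRec) * nRec, size = 2L,
                 signed = TRUE, endian = "little")
  perRec <- sum(sampPerRec)
  starts <- cumsum(c(0L, sampPerRec[-ns]))
  readChan <- function(j) {
    idx <- as.vector(outer(seq_len(sampPerRec[j]) + starts[j],
                           (seq_len(nRec) - 1L) * perRec, "+"))
    d <- raw[idx]
    (d - digMin[j]) * (physMax[j] - physMin[j]) / (digMax[j] - digMin[j]) +
      physMin[j]
  }

  resolve <- function(lab) {
    j <- match(lab, labels)
    if (!is.na(j))
      return(list(x = readChan(j), fs = sampPerRec[j] / recDur))
    parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      ja <- match(parts[1], labels); jb <- match(parts[2], labels)
      if (!is.na(ja) && !is.na(jb)) {
        if (sampPerRec[ja] != sampPerRec[jb])
          stop(sprintf(
            "inconsistent per-channel sampling rates for derivation '%s'",
            lab))
        return(list(x = readChan(ja) - readChan(jb),
                    fs = sampPerRec[ja] / recDur))
      }
    }
    stop(sprintf("channel not found in EDF file: '%s'", lab))
  }

  chans <- lapply(channelLabels, resolve)
  fsAll <- vapply(chans, `[[`, 0, "fs")
  if (length(unique(fsAll)) != 1L)
    stop("inconsistent per-channel sampling rates among requested channels")
  sig <- do.call(cbind, lapply(chans, `[[`, "x"))
  EEGRecord(sig, channelLabels, fs = fsAll[1],
            subjectId = if (nzchar(patient)) patient
                        else sub("\\.edf$", "", basename(path)))
}
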