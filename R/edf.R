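# Minimal European Data Format (EDF, 16-bit) writer and reader.
# Continuous recordings only, 1-s data records, identical sampling rate across
# signals — exactly the shape this package produces. Field widths follow the
# EDF header layout (256 bytes global + 256 per signal, ASCII, space-padded).

.edfPad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' Signals are quantized to 16-bit integers over each channel's physical
#' range; the quantization step is \code{(physMax - physMin) / 65535}.
#' Subject metadata (subject id, group, week) is stored in the EDF recording
#' identification field and restored by [readRecording()].
#'
#' @param rec a [Recording-class]; its duration must be a whole number of
#'   seconds.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- fsHz(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nSamp <- ncol(rec@samples)
  if (nSamp %% fs != 0)
    stop("EDF export requires a whole number of seconds of data")
  nRec <- nSamp %/% fs
  ns <- nrow(rec@samples)

  physMin <- apply(rec@samples, 1, min)
  physMax <- apply(rec@samples, 1, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768L
  digMax <- 32767L

  recId <- sprintf("subject=%s group=%s week=%s",
                   rec@subjectId, rec@groupLabel, rec@week)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("X", 80), .edfPad(recId, 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 + 256 * ns, 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1, 8), .edfPad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(.edfPad(rec@channelLabels, 16), collapse = ""),
    paste(.edfPad(rep("", ns), 80), collapse = ""),
    paste(.edfPad(rep("uV", ns), 8), collapse = ""),
    paste(.edfPad(formatC(physMin, digits = 7, format = "g"), 8), collapse = ""),
    paste(.edfPad(formatC(physMax, digits = 7, format = "g"), 8), collapse = ""),
    paste(.edfPad(rep(digMin, ns), 8), collapse = ""),
    paste(.edfPad(rep(digMax, ns), 8), collapse = ""),
    paste(.edfPad(rep("", ns), 80), collapse = ""),
    paste(.edfPad(rep(fs, ns), 8), collapse = ""),
    paste(.edfPad(rep("", ns), 32), collapse = ""))
  writeChar(sig, con, eos = NULL)

  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec@samples[ch, idx] - physMin[ch]) / scale[ch]) + digMin
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.edfReadField <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)),
         character(1))
}

#' Read an EDF recording
#'
#' @param path EDF file written by [writeEDF()] (or any continuous 16-bit EDF
#'   with a uniform sampling rate).
#' @return A [Recording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                      # version
  readChar(con, 80, useBytes = TRUE)                     # patient id
  recId <- trimws(readChar(con, 80, useBytes = TRUE))
  readChar(con, 16, useBytes = TRUE)                     # date + time
  readChar(con, 8, useBytes = TRUE)                      # header bytes
  readChar(con, 44, useBytes = TRUE)                     # reserved
  nRec <- as.integer(.edfReadField(con, 8))
  durRec <- as.numeric(.edfReadField(con, 8))
  ns <- as.integer(.edfReadField(con, 4))

  labels <- .edfReadField(con, 16, ns)
  .edfReadField(con, 80, ns)                             # transducer
  .edfReadField(con, 8, ns)                              # physical dim
  physMin <- as.numeric(.edfReadField(con, 8, ns))
  physMax <- as.numeric(.edfReadField(con, 8, ns))
  digMin <- as.numeric(.edfReadField(con, 8, ns))
  digMax <- as.numeric(.edfReadField(con, 8, ns))
  .edfReadField(con, 80, ns)                             # prefiltering
  spr <- as.integer(.edfReadField(con, 8, ns))
  .edfReadField(con, 32, ns)                             # reserved

  if (length(unique(spr)) != 1)
    stop("EDF files with per-signal sampling rates are not supported")
  fs <- spr[1] / durRec
  scale <- (physMax - physMin) / (digMax - digMin)

  out <- matrix(0, nrow = ns, ncol = nRec * spr[1])
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      out[ch, idx] <- physMin[ch] + (dig - digMin[ch]) * scale[ch]
    }
  }

  meta <- c(subject = NA_character_, group = NA_character_, week = NA_character_)
  m <- regmatches(recId,
    regexec("subject=(\\S+) group=(\\S+) week=(\\S+)", recId))[[1]]
  if (length(m) == 4) meta <- c(subject = m[2], group = m[3], week = m[4])

  Recording(out, fsHz = fs, channelLabels = labels,
            subjectId = meta[["subject"]], groupLabel = meta[["group"]],
            week = suppressWarnings(as.integer(meta[["week"]])))
}
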