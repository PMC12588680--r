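# Recording I/O (CSV, EDF) and epoch selection.

#' Write a recording to CSV
#'
#' Plain columnar text: metadata comment lines, then a header
#' \code{time_s,<channel>,...} and one row per sample (comma separator,
#' decimal point). Exact round trip with [readRecording()].
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs_hz: %.10g", fsHz(rec)),
    sprintf("# subject_id: %s", rec@subjectId),
    sprintf("# group_label: %s", rec@groupLabel),
    sprintf("# week: %s", rec@week)), con)
  df <- data.frame(time_s = (seq_len(ncol(rec@samples)) - 1) / fsHz(rec))
  for (ch in rec@channelLabels) df[[ch]] <- rec@samples[ch, ]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readRecordingCSV <- function(path) {
  lines <- readLines(path, n = 50)
  meta <- list(fs_hz = NA, subject_id = NA, group_label = NA, week = NA)
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("CSV recording must have a time_s column")
  chans <- setdiff(names(df), "time_s")
  fs <- as.numeric(meta$fs_hz)
  if (!is.finite(fs)) {
    dt <- diff(df$time_s[1:2])
    fs <- 1 / dt
  }
  mat <- t(as.matrix(df[chans]))
  if (anyNA(mat) || !is.numeric(mat))
    stop("CSV recording has missing or non-numeric samples ",
         "(inconsistent channel lengths?)")
  Recording(mat, fsHz = fs, channelLabels = chans,
            subjectId = as.character(meta$subject_id),
            groupLabel = as.character(meta$group_label),
            week = suppressWarnings(as.integer(meta$week)))
}

#' Read a recording
#'
#' @param path path to an EDF or CSV recording.
#' @param format \code{"edf"}, \code{"csv"}, or \code{"auto"} (by extension).
#' @return A [Recording-class].
#' @export
readRecording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else
      if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
        stop("cannot infer format from extension of ", path,
             " (supported: EDF, CSV)")
  switch(format, edf = readEDF(path), csv = .readRecordingCSV(path))
}

#' Write a recording
#'
#' @inheritParams readRecording
#' @param rec a [Recording-class].
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, edf = writeEDF(rec, path), csv = writeRecordingCSV(rec, path))
}

#' Select artifact-free analysis epochs
#'
#' Greedy earliest-window rule: candidate windows start on a 1-s grid; a
#' window qualifies if, on every channel, no sample deviates from the channel
#' median by more than \code{artifactK} robust standard deviations (MAD). The
#' earliest qualifying non-overlapping windows are returned. This automates
#' the visual artifact screening used in practice; the threshold is exposed.
#'
#' @param rec a [Recording-class].
#' @param n number of epochs (default 3).
#' @param epochS epoch length in seconds (default 30).
#' @param artifactK robust-SD multiple above which a sample is an artifact
#'   (default 6).
#' @return An [EpochSet-class].
#' @export
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 256 * 95), nrow = 2,
#'                         dimnames = list(c("MCx", "STN"), NULL)), 256)
#' selectEpochs(rec, n = 3)
selectEpochs <- function(rec, n = 3, epochS = 30, artifactK = 6) {
  fs <- fsHz(rec)
  total <- durationS(rec)
  if (total < n * epochS)
    stop(sprintf("recording is %.1f s but %d epochs of %g s need %.0f s",
                 total, n, epochS, n * epochS))
  x <- rec@samples
  bad <- rep(FALSE, ncol(x))
  for (ch in seq_len(nrow(x))) {
    med <- stats::median(x[ch, ])
    rsd <- stats::mad(x[ch, ])
    if (rsd == 0) rsd <- stats::sd(x[ch, ])
    bad <- bad | abs(x[ch, ] - med) > artifactK * rsd
  }
  cumBad <- c(0, cumsum(bad))
  epLen <- as.integer(round(epochS * fs))
  starts <- numeric(0)
  t0 <- 0
  maxStart <- total - epochS
  while (length(starts) < n && t0 <= maxStart + 1e-9) {
    i0 <- floor(t0 * fs) + 1
    if (cumBad[i0 + epLen] - cumBad[i0] == 0) {
      starts <- c(starts, t0)
      t0 <- t0 + epochS
    } else {
      t0 <- t0 + 1
    }
  }
  if (length(starts) < n)
    stop(sprintf("only %d clean %g-s window(s) found; %d required",
                 length(starts), epochS, n))
  EpochSet(cbind(starts, starts + epochS), fsHz = fs, sourceDurationS = total)
}

# Sample indices (1-based) of a half-open epoch [start, end):
# first sample floor(start*fs)+1, count round((end-start)*fs).
.epochIdx <- function(ep, fs) {
  i0 <- floor(ep[1] * fs) + 1
  n <- as.integer(round((ep[2] - ep[1]) * fs))
  i0:(i0 + n - 1)
}

#' Extract epoch samples from one channel
#'
#' @param rec a [Recording-class].
#' @param channel channel label.
#' @param es an [EpochSet-class].
#' @return list of numeric vectors, one per epoch; sample values are
#'   untouched.
#' @export
epochSamples <- function(rec, channel, es) {
  x <- samples(rec, channel)
  fs <- fsHz(rec)
  lapply(seq_len(nEpochs(es)), function(i) x[.epochIdx(es@epochs[i, ], fs)])
}
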