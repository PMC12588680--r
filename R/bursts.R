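# Beta-burst detection: z-scored signals, 10-cycle Morlet band power
# envelopes, a pooled percentile threshold per region, supra-threshold run
# detection with a 100 ms minimum, and amplitude / rate / long-burst
# probability statistics.

#' Burst-detection configuration
#'
#' @param waveletCycles Morlet cycles per frequency (default 10).
#' @param freqGridHz full analysis grid, 1..128 Hz at 1 Hz steps.
#' @param band beta sub-band analysed, from [betaBand()] (default high beta,
#'   21-30 Hz).
#' @param thresholdQuantile envelope power quantile defining a burst
#'   (default 0.75).
#' @param minDurationS minimum burst duration in seconds (default 0.100,
#'   read inclusively).
#' @param longDurationS duration above which a burst counts as long
#'   (default 0.350, read strictly).
#' @return list of validated settings.
#' @export
burstConfig <- function(waveletCycles = 10, freqGridHz = 1:128,
                        band = betaBand("high"), thresholdQuantile = 0.75,
                        minDurationS = 0.100, longDurationS = 0.350) {
  stopifnot(thresholdQuantile > 0, thresholdQuantile < 1,
            minDurationS > 0, longDurationS > minDurationS,
            waveletCycles > 0)
  list(waveletCycles = waveletCycles, freqGridHz = freqGridHz, band = band,
       thresholdQuantile = thresholdQuantile, minDurationS = minDurationS,
       longDurationS = longDurationS)
}

#' z-score a signal
#'
#' \code{(x - mean) / sd} with the population standard deviation, removing
#' between-subject amplitude variability before burst analysis.
#'
#' @param x numeric vector, length >= 2, nonconstant.
#' @return z-scored vector (mean 0, population SD 1).
#' @export
#' @examples
#' zScoreSignal(c(1, 2, 3))
zScoreSignal <- function(x) {
  if (length(x) < 2) stop("signal must have length >= 2")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop("constant signal has zero variance; z-score undefined")
  (x - mu) / sdev
}

# Complex Morlet kernel at frequency f: Gaussian envelope with
# sigma_t = cycles / (2 pi f), truncated at +/- 4 sigma, unit L2 norm so
# white-noise envelope power is comparable across frequencies.
.morletKernel <- function(f, fs, cycles) {
  sigma <- cycles / (2 * pi * f)
  hw <- ceiling(4 * sigma * fs)
  tt <- (-hw:hw) / fs
  k <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Band power envelope from a 10-cycle Morlet transform
#'
#' For each integer frequency of the band the signal is convolved with a
#' complex Morlet wavelet; the squared magnitudes (power) are averaged across
#' the band's frequencies, giving one nonnegative envelope sample per input
#' sample. The input is expected to be z-scored, so the envelope is in
#' z-power units and insensitive to the original amplitude scale.
#'
#' @param x numeric vector (one epoch of one channel, z-scored).
#' @param fs sampling rate in Hz.
#' @param cfg a [burstConfig()].
#' @return numeric envelope, same length as \code{x}.
#' @export
bandEnvelope <- function(x, fs, cfg = burstConfig()) {
  b <- cfg$band
  freqs <- cfg$freqGridHz[cfg$freqGridHz >= b$lo & cfg$freqGridHz <= b$hi]
  if (!length(freqs))
    stop("band has no frequencies on the analysis grid")
  if (max(freqs) > fs / 2)
    stop(sprintf("band reaches %g Hz, beyond the Nyquist rate %g Hz",
                 max(freqs), fs / 2))
  if (max(cfg$freqGridHz) > fs / 2 && max(freqs) <= fs / 2)
    NULL  # grid tops out at Nyquist (128 Hz at fs = 256); band itself is fine
  pow <- matrix(0, nrow = length(x), ncol = length(freqs))
  for (j in seq_along(freqs))
    pow[, j] <- Mod(.convSame(x, .morletKernel(freqs[j], fs, cfg$waveletCycles)))^2
  rowMeans(pow)
}

#' Common percentile threshold over pooled envelopes
#'
#' All envelope samples of one region (across subjects, groups and weeks) are
#' pooled and the linear-interpolation percentile (R type-7 quantile) at
#' \code{cfg$thresholdQuantile} is returned, giving one common amplitude
#' threshold per region.
#'
#' @param envelopes list of numeric envelopes (or a single numeric vector).
#' @param cfg a [burstConfig()].
#' @return scalar threshold.
#' @export
#' @examples
#' pooledThreshold(list(1:100))  # 75.25
pooledThreshold <- function(envelopes, cfg = burstConfig()) {
  pool <- unlist(envelopes, use.names = FALSE)
  if (!length(pool)) stop("envelope pool is empty")
  unname(stats::quantile(pool, cfg$thresholdQuantile, type = 7))
}

#' Detect beta bursts in one envelope
#'
#' Maximal runs of samples strictly above the threshold lasting at least
#' \code{cfg$minDurationS} become bursts; runs touching either epoch boundary
#' are discarded (clipped bursts would bias durations downward). Times are
#' half-open: a run over samples i..j (1-based) spans
#' \code{[(i-1)/fs, j/fs)}.
#'
#' @param envelope numeric envelope of one epoch.
#' @param threshold common region threshold from [pooledThreshold()].
#' @param fs sampling rate in Hz.
#' @param cfg a [burstConfig()].
#' @param channel label recorded in the result.
#' @return A [BurstSet-class].
#' @export
detectBursts <- function(envelope, threshold, fs, cfg = burstConfig(),
                         channel = NA_character_) {
  above <- envelope > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values &
    starts > 1 & ends < length(envelope) &         # discard boundary-touching
    r$lengths / fs >= cfg$minDurationS - 1e-9
  b <- data.frame(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0), peak = numeric(0),
                  mean = numeric(0))
  if (any(keep)) {
    si <- starts[keep]
    ei <- ends[keep]
    b <- data.frame(
      start_s = (si - 1) / fs,
      end_s = ei / fs,
      duration_s = (ei - si + 1) / fs,
      peak = mapply(function(i, j) max(envelope[i:j]), si, ei),
      mean = mapply(function(i, j) mean(envelope[i:j]), si, ei))
  }
  BurstSet(b, thresholdUsed = threshold, channel = channel,
           minDurationS = cfg$minDurationS)
}

#' Combine burst sets from several epochs
#'
#' Epoch-local burst times are offset to recording time so a subject-week's
#' epochs yield a single set.
#'
#' @param bsList list of [BurstSet-class], one per epoch.
#' @param epochStartsS epoch start times in seconds.
#' @return A combined [BurstSet-class].
#' @export
combineBurstSets <- function(bsList, epochStartsS) {
  stopifnot(length(bsList) == length(epochStartsS))
  dfs <- mapply(function(bs, off) {
    b <- bs@bursts
    if (nrow(b)) { b$start_s <- b$start_s + off; b$end_s <- b$end_s + off }
    b
  }, bsList, epochStartsS, SIMPLIFY = FALSE)
  b <- do.call(rbind, dfs)
  b <- b[order(b$start_s), , drop = FALSE]
  rownames(b) <- NULL
  BurstSet(b, thresholdUsed = bsList[[1]]@thresholdUsed,
           channel = bsList[[1]]@channel,
           minDurationS = bsList[[1]]@minDurationS)
}

#' Burst summary statistics
#'
#' Amplitude is the mean of the per-burst peak envelope (z-power units); rate
#' is bursts per minute; long-burst probability is the percentage of bursts
#' strictly longer than \code{longDurationS}. With zero bursts the rate is 0
#' and amplitude / long-burst probability are missing.
#'
#' @param bs a [BurstSet-class].
#' @param totalTimeS analysed time in seconds (> 0).
#' @param longDurationS long-burst cutoff (default 0.350 s, strict).
#' @return named list: \code{amplitude}, \code{rate}, \code{longBurstProb}
#'   (percent), \code{nBursts}.
#' @export
burstStats <- function(bs, totalTimeS, longDurationS = 0.350) {
  if (totalTimeS <= 0) stop("totalTimeS must be positive")
  b <- bs@bursts
  n <- nrow(b)
  list(
    amplitude = if (n) mean(b$peak) else NA_real_,
    rate = 60 * n / totalTimeS,
    longBurstProb = if (n) 100 * mean(b$duration_s > longDurationS) else NA_real_,
    nBursts = n)
}

#' Write a burst set to CSV
#' @param bs a [BurstSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBurstCSV <- function(bs, path) {
  utils::write.csv(bs@bursts[c("start_s", "end_s", "duration_s", "peak", "mean")],
                   path, row.names = FALSE)
  invisible(path)
}
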