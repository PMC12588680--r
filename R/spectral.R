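# Hanning-windowed periodogram power spectra at 1 Hz resolution,
# normalization to the 5-45 + 55-95 Hz power sum, and band means.

# Split epoch sample vectors into non-overlapping windows of exactly fs
# samples (1 s => 1 Hz bins). Partial trailing windows are dropped.
.oneSecWindows <- function(epochList, fs) {
  fs <- as.integer(round(fs))
  out <- list()
  for (x in epochList) {
    nw <- length(x) %/% fs
    if (nw < 1) stop("epoch shorter than 1 s cannot form a spectral window")
    for (w in seq_len(nw))
      out[[length(out) + 1]] <- x[((w - 1) * fs + 1):(w * fs)]
  }
  out
}

# One-sided Hann periodogram of a single window; scale such that the sum over
# bins of a stationary signal tracks its variance (window power compensated):
# P[k] = |FFT(w.(x - mean))|^2 / (N * sum(w^2)), doubled off DC/Nyquist.
.hannPeriodogram <- function(x) {
  n <- length(x)
  w <- .hann(n)
  X <- stats::fft(w * (x - mean(x)))
  half <- n %/% 2
  P <- Mod(X[1:(half + 1)])^2 / (n * sum(w^2))
  if (half >= 2) P[2:half] <- 2 * P[2:half]
  P
}

#' Averaged Hanning periodogram at 1 Hz resolution
#'
#' Each epoch is cut into non-overlapping 1-s windows (exactly \code{fs}
#' samples, so bins fall on integer frequencies); each window is mean-removed,
#' Hann-tapered and Fourier transformed; the one-sided periodograms are
#' averaged across all windows of all epochs. No further detrending is
#' applied (acquisition is assumed high-pass filtered).
#'
#' @param rec a [Recording-class], or a numeric vector of samples.
#' @param channel channel label (ignored when \code{rec} is a vector).
#' @param es an [EpochSet-class], or a list of numeric epoch vectors; when
#'   \code{rec} is a vector and \code{es} is NULL the whole vector is one
#'   epoch.
#' @param fs sampling rate, required when \code{rec} is a plain vector.
#' @return A [PowerSpectrum-class] with bins 0..Nyquist at 1 Hz spacing, in
#'   absolute (variance) units.
#' @export
periodogramHann <- function(rec, channel = NULL, es = NULL, fs = NULL) {
  if (is(rec, "Recording")) {
    fs <- fsHz(rec)
    epochList <- if (is.null(es)) list(samples(rec, channel))
      else epochSamples(rec, channel, es)
  } else {
    if (is.null(fs)) stop("fs must be given for plain-vector input")
    epochList <- if (is.null(es)) list(as.numeric(rec))
      else if (is.list(es)) es else stop("es must be a list for vector input")
  }
  if (abs(fs - round(fs)) > 1e-9)
    stop("1-Hz bins require an integer sampling rate")
  wins <- .oneSecWindows(epochList, fs)
  P <- rowMeans(vapply(wins, .hannPeriodogram, numeric(round(fs) %/% 2 + 1)))
  PowerSpectrum(freqsHz = 0:(round(fs) %/% 2), power = P)
}

#' Normalize a power spectrum to the 5-45 + 55-95 Hz power sum
#'
#' Each bin is divided by the summed power over the integer bins 5..45 and
#' 55..95 Hz inclusive. The 46-54 Hz gap excludes the 50 Hz mains region.
#'
#' @param ps an absolute [PowerSpectrum-class] covering at least 5-95 Hz.
#' @return A normalized [PowerSpectrum-class]; normalizing twice is a no-op.
#' @export
normalizeSpectrum <- function(ps) {
  if (isNormalized(ps)) return(ps)
  bands <- rbind(c(5, 45), c(55, 95))
  idx <- c(.bandIdx(ps@freqsHz, 5, 45), .bandIdx(ps@freqsHz, 55, 95))
  total <- sum(ps@power[idx])
  if (total <= 0)
    stop("normalization sum over 5-45 and 55-95 Hz is zero")
  PowerSpectrum(ps@freqsHz, ps@power / total, normalized = TRUE,
                normBands = bands)
}

#' Mean power over a frequency band
#'
#' Arithmetic mean of the per-bin values over the inclusive integer bins
#' \code{lo..hi}.
#'
#' @param ps a [PowerSpectrum-class] or [CoherenceSpectrum-class].
#' @param band a band from [betaBand()], or a list with \code{lo}, \code{hi}.
#' @param requireNormalized for power spectra, insist on a normalized input
#'   (default TRUE, matching how band powers are reported).
#' @return scalar band mean.
#' @export
bandMean <- function(ps, band, requireNormalized = TRUE) {
  vals <- if (is(ps, "CoherenceSpectrum")) ps@icoh else {
    if (requireNormalized && !isNormalized(ps))
      stop("spectrum must be normalized before band means are taken")
    ps@power
  }
  idx <- .bandIdx(ps@freqsHz, band$lo, band$hi)
  mean(vals[idx])
}
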