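# Imaginary coherence between MCx and STN: the absolute imaginary part of the
# complex coherency, insensitive to zero-lag (volume-conducted) coupling.

#' Imaginary coherence spectrum between two channels
#'
#' Auto- and cross-spectra are averaged over non-overlapping 1-s Hanning
#' windows pooled across all epochs; the coherency is
#' \code{C(f) = Sxy / sqrt(Sxx Syy)} and \code{|Im C(f)|} is returned. A
#' zero-lag scaled copy gives exactly zero at every bin.
#'
#' @param rec a [Recording-class], or a numeric vector (channel x).
#' @param xChannel,yChannel channel labels when \code{rec} is a Recording.
#' @param y numeric vector (channel y) when \code{rec} is a vector.
#' @param es an [EpochSet-class], a list of epoch index... or NULL for the
#'   whole recording as one epoch.
#' @param fs sampling rate for plain-vector input.
#' @return A [CoherenceSpectrum-class].
#' @export
imaginaryCoherence <- function(rec, xChannel = "MCx", yChannel = "STN",
                               y = NULL, es = NULL, fs = NULL) {
  if (is(rec, "Recording")) {
    fs <- fsHz(rec)
    xe <- if (is.null(es)) list(samples(rec, xChannel))
      else epochSamples(rec, xChannel, es)
    ye <- if (is.null(es)) list(samples(rec, yChannel))
      else epochSamples(rec, yChannel, es)
  } else {
    if (is.null(fs)) stop("fs must be given for plain-vector input")
    if (is.null(y)) stop("y channel vector must be given")
    if (length(rec) != length(y)) stop("channels must have equal length")
    xe <- list(as.numeric(rec))
    ye <- list(as.numeric(y))
  }
  if (abs(fs - round(fs)) > 1e-9)
    stop("1-Hz bins require an integer sampling rate")
  xw <- .oneSecWindows(xe, fs)
  yw <- .oneSecWindows(ye, fs)
  if (length(xw) != length(yw)) stop("channels must yield equal window counts")
  if (length(xw) < 2)
    stop("coherence needs at least 2 windows (single-window coherence is degenerate)")
  n <- as.integer(round(fs))
  half <- n %/% 2
  w <- .hann(n)
  Sxx <- Syy <- numeric(half + 1)
  Sxy <- complex(half + 1)
  for (i in seq_along(xw)) {
    X <- stats::fft(w * (xw[[i]] - mean(xw[[i]])))[1:(half + 1)]
    Y <- stats::fft(w * (yw[[i]] - mean(yw[[i]])))[1:(half + 1)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  denom <- sqrt(Sxx * Syy)
  ic <- numeric(half + 1)
  ok <- denom > 0
  if (any(!ok))
    warning("zero-power bins encountered; their coherence is reported as 0")
  ic[ok] <- abs(Im(Sxy[ok] / denom[ok]))
  # floor floating-point residue so exact zero-lag copies report exactly 0
  ic[ic < 1e-12] <- 0
  CoherenceSpectrum(freqsHz = 0:half, icoh = pmin(ic, 1))
}

#' Band-mean imaginary coherence
#'
#' @param cs a [CoherenceSpectrum-class].
#' @param band a band from [betaBand()].
#' @return scalar mean of \code{|Im C|} over the band's inclusive integer
#'   bins.
#' @export
bandMeanCoherence <- function(cs, band) bandMean(cs, band)
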