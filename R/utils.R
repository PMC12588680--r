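# Internal numeric helpers shared across modules.

# Symmetric Hann window of length n.
.hann <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Same-length linear convolution of a real signal with a (complex) kernel of
# odd length, via zero-padded FFT. Output sample i is aligned with input
# sample i (kernel centre).
.convSame <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  stopifnot(m %% 2 == 1)
  L <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(c(kern, rep(0, L - m)))
  full <- stats::fft(X * K, inverse = TRUE) / L
  half <- (m - 1) / 2
  full[(half + 1):(half + n)]
}

# Deterministic child seed stream: distinct 31-bit seeds from a root seed.
.childSeed <- function(root, k) {
  as.integer((as.numeric(root) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

# Frequency (Hz) of each FFT bin for an N-point transform at rate fs,
# signed (negative for the upper half).
.fftFreqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[k > n / 2] <- f[k > n / 2] - fs
  f
}

# Integer-bin indices of a [lo, hi] band (inclusive) within a 0..Nyquist
# 1-Hz-spaced frequency axis.
.bandIdx <- function(freqs, lo, hi) {
  idx <- which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9)
  if (!length(idx)) stop(sprintf("band [%g, %g] Hz is outside the spectrum", lo, hi))
  if (lo < min(freqs) - 1e-9 || hi > max(freqs) + 1e-9)
    stop(sprintf("band [%g, %g] Hz extends outside the spectrum", lo, hi))
  idx
}

#' Standard beta-band definitions
#'
#' Inclusive integer-bin band edges: total beta 13-30 Hz, low beta 13-20 Hz,
#' high beta 21-30 Hz. Low and high beta partition total beta without overlap.
#'
#' @param name one of \code{"total"}, \code{"low"}, \code{"high"}, or a custom
#'   band via \code{lo}/\code{hi}.
#' @param lo,hi custom band edges in Hz (inclusive), used when \code{name} is
#'   \code{"custom"}.
#' @return list with elements \code{name}, \code{lo}, \code{hi}.
#' @export
#' @examples
#' betaBand("high")
betaBand <- function(name = c("total", "low", "high", "custom"),
                     lo = NULL, hi = NULL) {
  name <- match.arg(name)
  b <- switch(name,
    total = list(name = "total", lo = 13, hi = 30),
    low = list(name = "low", lo = 13, hi = 20),
    high = list(name = "high", lo = 21, hi = 30),
    custom = list(name = "custom", lo = lo, hi = hi))
  if (is.null(b$lo) || is.null(b$hi) || b$lo > b$hi)
    stop("band must have lo <= hi")
  b
}
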