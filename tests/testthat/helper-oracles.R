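# Independent oracles and shared fixtures, built in code at test time.

# Brute-force one-sided Hann periodogram by direct DFT summation (O(N^2)),
# same scale convention as the package: P[k] = |sum w x e^{-2pi i kn/N}|^2 /
# (N sum w^2), doubled off DC/Nyquist. Kept free of stats::fft on purpose.
bruteHannPeriodogram <- function(x) {
  N <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  xc <- w * (x - mean(x))
  half <- N %/% 2
  nIdx <- 0:(N - 1)
  P <- numeric(half + 1)
  for (k in 0:half) {
    e <- exp(-2i * pi * k * nIdx / N)
    P[k + 1] <- Mod(sum(xc * e))^2 / (N * sum(w^2))
  }
  if (half >= 2) P[2:half] <- 2 * P[2:half]
  P
}

# Averaged brute-force periodogram over non-overlapping 1-s windows.
bruteAvgPeriodogram <- function(x, fs) {
  nw <- length(x) %/% fs
  Ps <- sapply(seq_len(nw), function(w)
    bruteHannPeriodogram(x[((w - 1) * fs + 1):(w * fs)]))
  rowMeans(Ps)
}

# One run of the burst-recovery study: well-separated rectangular-envelope
# high-beta bursts (amplitude 10 x background SD, durations 150-600 ms) at
# ~25% occupancy, detected through the full z-score -> Morlet envelope ->
# pooled 75th-percentile threshold -> run-detection pipeline.
burstRecoveryRun <- function(seed, nBursts = 30, durS = 47, amplitude = 10) {
  set.seed(seed)
  fs <- 256
  d <- stats::runif(nBursts, 0.15, 0.6)
  on <- seq(1, durS - 2, length.out = nBursts) + stats::runif(nBursts, 0, 0.3)
  ev <- data.frame(onset_s = on, duration_s = d,
                   center_freq_hz = stats::runif(nBursts, 21, 30),
                   amplitude = amplitude)
  cfg <- synthRecordingConfig(
    durationS = durS, burstRatePerMin = c(low = 0, high = 0),
    couplingGain = 0, lineGain = 0.5, burstEnvelope = "rect",
    forcedEvents = list(MCx = ev, STN = NULL), seed = seed)
  sim <- simulateRecording(cfg)
  x <- zScoreSignal(samples(sim$recording, "MCx"))
  bc <- burstConfig()
  env <- bandEnvelope(x, fs, bc)
  thr <- pooledThreshold(list(env), bc)
  bs <- detectBursts(env, thr, fs, bc)
  b <- bursts(bs)
  edgeErr <- numeric(0)
  matched <- 0L
  for (k in seq_len(nBursts)) {
    ov <- which(b$end_s > ev$onset_s[k] &
                  b$start_s < ev$onset_s[k] + ev$duration_s[k])
    if (length(ov) == 1) {
      matched <- matched + 1L
      edgeErr <- c(edgeErr,
                   abs(b$start_s[ov] - ev$onset_s[k]),
                   abs(b$end_s[ov] - (ev$onset_s[k] + ev$duration_s[k])))
    }
  }
  st <- burstStats(bs, durS)
  list(nInjected = nBursts, nDetected = nrow(b), matched = matched,
       edgeErr = edgeErr, detLBP = st$longBurstProb,
       trueLBP = 100 * mean(d > 0.35), env = env, threshold = thr,
       meanAmplitude = st$amplitude)
}

# Simulate one mediation dataset x -> m -> y with standardized true paths.
simMediation <- function(n, b1 = 0.6, b2 = 0.7) {
  x <- stats::rnorm(n)
  m <- b1 * x + stats::rnorm(n, 0, sqrt(1 - b1^2))
  y <- b2 * m + stats::rnorm(n, 0, sqrt(1 - b2^2))
  data.frame(x = x, m = m, y = y)
}

mediationModel <- function() {
  PathModel(data.frame(from = c("x", "m"), to = c("m", "y")))
}
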