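# z-score, Morlet band envelope, pooled threshold, run detection and
# burst statistics.

test_that("z-score has the closed form, is idempotent and rejects constants", {
  expect_equal(zScoreSignal(c(1, 2, 3)),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  set.seed(30)
  x <- rnorm(1000, 5, 3)
  z <- zScoreSignal(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  expect_equal(zScoreSignal(z), z, tolerance = 1e-10)
  expect_error(zScoreSignal(c(5, 5, 5)), "zero variance")
  expect_error(zScoreSignal(1), "length")
})

test_that("band envelope is frequency selective and scale invariant", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  x <- zScoreSignal(sin(2 * pi * 25 * t) + 0.01 * sin(2 * pi * 3 * t))
  mid <- (2 * fs):(8 * fs)
  envH <- bandEnvelope(x, fs, burstConfig(band = betaBand("high")))
  envL <- bandEnvelope(x, fs, burstConfig(band = betaBand("low")))
  expect_gt(mean(envH[mid]) / mean(envL[mid]), 10)
  expect_true(all(bandEnvelope(rep(0, fs), fs) == 0))
  # doubling before z-scoring changes nothing
  x2 <- zScoreSignal(2 * (sin(2 * pi * 25 * t) + 0.01 * sin(2 * pi * 3 * t)))
  expect_equal(bandEnvelope(x2, fs, burstConfig()), envH, tolerance = 1e-9)
  expect_error(bandEnvelope(x, 50, burstConfig(band = betaBand("high"))),
               "Nyquist")
})

test_that("pooled threshold is the linear-interpolation 75th percentile", {
  expect_equal(pooledThreshold(list(1:100)), 75.25)
  expect_equal(pooledThreshold(list(rep(4, 10))), 4)
  set.seed(31)
  a <- runif(500)
  b <- runif(300)
  expect_equal(pooledThreshold(list(a, b)),
               unname(quantile(c(a, b), 0.75, type = 7)))
  expect_error(pooledThreshold(list()), "empty")
  # threshold contract: 25% +- 1/pool of samples exceed it
  thr <- pooledThreshold(list(a, b))
  frac <- mean(c(a, b) > thr)
  expect_lt(abs(frac - 0.25), 1 / 800 + 1e-12)
})

test_that("run detection honours minimum duration and boundary discard", {
  fs <- 100
  cfg <- burstConfig()
  base <- rep(0.1, 10 * fs)
  expect_equal(nBursts(detectBursts(base, 1, fs, cfg)), 0)
  # one rectangular 400 ms run mid-epoch
  env <- base
  env[301:340] <- 2
  bs <- detectBursts(env, 1, fs, cfg)
  expect_equal(nBursts(bs), 1)
  expect_equal(bursts(bs)$duration_s, 0.4)
  expect_equal(bursts(bs)$start_s, 3.0)
  expect_equal(bursts(bs)$end_s, 3.4)
  expect_equal(burstStats(bs, 10)$longBurstProb, 100)
  # an 80 ms run is below the 100 ms minimum
  env2 <- base
  env2[301:308] <- 2
  expect_equal(nBursts(detectBursts(env2, 1, fs, cfg)), 0)
  # a run touching the epoch boundary is discarded, not truncated
  env3 <- base
  env3[1:60] <- 2
  expect_equal(nBursts(detectBursts(env3, 1, fs, cfg)), 0)
})

test_that("burst statistics follow their definitions", {
  b <- data.frame(start_s = c(1, 10, 20), end_s = c(1.2, 10.3, 20.4),
                  duration_s = c(0.2, 0.3, 0.4), peak = c(2, 3, 4),
                  mean = c(1.5, 2, 3))
  bs <- BurstSet(b, thresholdUsed = 1)
  st <- burstStats(bs, 90)
  expect_equal(st$rate, 2)
  expect_equal(st$longBurstProb, 100 / 3, tolerance = 1e-9)
  expect_equal(st$amplitude, 3)
  # all long
  bL <- transform(b, duration_s = 0.4)
  expect_equal(burstStats(BurstSet(bL, 1), 90)$longBurstProb, 100)
  # empty set
  b0 <- b[0, ]
  st0 <- burstStats(BurstSet(b0, 1), 90)
  expect_equal(st0$rate, 0)
  expect_true(is.na(st0$amplitude) && is.na(st0$longBurstProb))
  expect_error(burstStats(bs, -1), "positive")
})

test_that("injected high-SNR bursts are recovered end to end", {
  r <- burstRecoveryRun(seed = 101)
  expect_equal(r$nDetected, r$nInjected)
  expect_equal(r$matched, r$nInjected)
  # boundaries localized well inside the wavelet smoothing scale
  expect_lt(max(r$edgeErr), 0.05)
  # threshold contract on this run's pooled envelope
  frac <- mean(r$env > r$threshold)
  expect_lt(abs(frac - 0.25), 1 / length(r$env) + 1e-9)
})

test_that("raising injected amplitude never decreases count or amplitude", {
  lo <- burstRecoveryRun(seed = 102, amplitude = 5)
  hi <- burstRecoveryRun(seed = 102, amplitude = 10)
  expect_gte(hi$nDetected, lo$nDetected)
  expect_gte(hi$meanAmplitude, lo$meanAmplitude)
})

test_that("combining epoch burst sets offsets times into recording time", {
  fs <- 100
  cfg <- burstConfig()
  env <- rep(0.1, 5 * fs)
  env[101:140] <- 2
  bs1 <- detectBursts(env, 1, fs, cfg)
  bs2 <- detectBursts(env, 1, fs, cfg)
  comb <- combineBurstSets(list(bs1, bs2), c(0, 30))
  expect_equal(bursts(comb)$start_s, c(1, 31))
  expect_equal(nBursts(comb), 2)
})
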