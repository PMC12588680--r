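# Synthetic recording and cohort generators: reproducibility, spectral and
# coupling contracts, ground-truth bookkeeping and the endpoint path model.

test_that("config validation catches impossible settings", {
  expect_error(synthRecordingConfig(durationS = 0.5), "at least 1 s")
  expect_error(synthRecordingConfig(couplingGain = 1.5), "couplingGain")
  expect_error(synthRecordingConfig(burstRatePerMin = c(low = -1, high = 0)),
               "nonnegative")
  expect_error(cohortConfig(groups = list(list(label = "g", n = 0,
                                               traj = rep(1, 5)))),
               "at least one subject")
  expect_error(cohortConfig(weeks = c(2, 2, 3)), "strictly increasing")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- synthRecordingConfig(durationS = 10, seed = 7)
  a <- simulateRecording(cfg)
  b <- simulateRecording(cfg)
  expect_identical(samples(a$recording), samples(b$recording))
  expect_identical(a$events, b$events)
})

test_that("zero burst rate and zero coupling give background-only channels", {
  cfg <- synthRecordingConfig(durationS = 10,
                              burstRatePerMin = c(low = 0, high = 0),
                              couplingGain = 0, seed = 8)
  sim <- simulateRecording(cfg)
  expect_equal(nrow(sim$events$MCx), 0)
  expect_equal(nrow(sim$events$STN), 0)
  expect_equal(dim(samples(sim$recording)), c(2L, 2560L))
})

test_that("a forced high-amplitude event is found by the burst detector", {
  fs <- 256
  cfg <- synthRecordingConfig(
    durationS = 90, burstRatePerMin = c(low = 0, high = 0),
    couplingGain = 0, lineGain = 0,
    forcedEvents = list(MCx = data.frame(onset_s = 10, duration_s = 0.4,
                                         center_freq_hz = 25, amplitude = 10),
                        STN = NULL), seed = 9)
  sim <- simulateRecording(cfg)
  expect_equal(nrow(sim$events$MCx), 1)
  x <- zScoreSignal(samples(sim$recording, "MCx"))
  bc <- burstConfig()
  env <- bandEnvelope(x, fs, bc)
  bs <- detectBursts(env, pooledThreshold(list(env), bc), fs, bc)
  b <- bursts(bs)
  overlapping <- sum(b$end_s > 10 & b$start_s < 10.4)
  expect_equal(overlapping, 1)
})

test_that("event counts agree across seeds in expectation", {
  cfg <- synthRecordingConfig(durationS = 30,
                              burstRatePerMin = c(low = 5, high = 5),
                              couplingGain = 0, seed = 0)
  countFor <- function(seeds) sapply(seeds, function(s) {
    cfg$seed <- s
    sim <- simulateRecording(cfg)
    nrow(sim$events$MCx)
  })
  c1 <- countFor(1:100)
  c2 <- countFor(1001:1100)
  sediff <- sqrt(var(c1) / 100 + var(c2) / 100)
  expect_lt(abs(mean(c1) - mean(c2)), 2 * sediff + 1e-9)
  # Poisson target: 5/min x 2 bands x 0.5 min = 5 expected events
  expect_lt(abs(mean(c(c1, c2)) - 5), 3 * sd(c(c1, c2)) / sqrt(200))
})

test_that("background periodogram slope matches the configured exponent", {
  slopes <- sapply(1:20, function(s) {
    cfg <- synthRecordingConfig(durationS = 30,
                                burstRatePerMin = c(low = 0, high = 0),
                                couplingGain = 0, lineGain = 0,
                                oneOverFExponent = 1, seed = s)
    ps <- periodogramHann(simulateRecording(cfg)$recording, "MCx")
    f <- 5:45
    -unname(coef(lm(log(specPower(ps)[f + 1]) ~ log(f)))[2])
  })
  expect_lt(abs(mean(slopes) - 1), 0.3)
})

test_that("lagged coupling produces imaginary coherence above the null", {
  bandIC <- function(seed, gain) {
    cfg <- synthRecordingConfig(durationS = 90,
                                burstRatePerMin = c(low = 0, high = 0),
                                couplingGain = gain, couplingLagMs = 20,
                                seed = seed)
    cs <- imaginaryCoherence(simulateRecording(cfg)$recording)
    bandMeanCoherence(cs, betaBand("total"))
  }
  nullv <- sapply(1:19, bandIC, gain = 0)
  expect_gt(bandIC(100, 0.3), quantile(nullv, 0.95))
})

test_that("null endpoint coefficients give no feature-behaviour correlation", {
  cc <- cohortConfig(
    groups = list(list(label = "G", n = 150, traj = 1)), weeks = 1,
    pathCoefficients = list(behavior = c(stn_power = 0),
                            th = c(stn_power = 0), od = c(stn_power = 0)),
    noiseSd = c(behavior = 1, th = 1, od = 1), latentSd = 1, subjectSd = 0,
    simulateSignals = FALSE, seed = 60)
  ch <- simulateCohort(cc)
  d <- merge(ch$endpoints, ch$trueParameters$latents)
  for (f in c("stn_power", "mcx_power", "stn_burst_rate"))
    expect_lt(abs(cor(d[[f]], d$cylinder_index)), 3 / sqrt(nrow(d)))
})

test_that("a 0.7 behaviour path coefficient is recovered by regression", {
  cc <- cohortConfig(
    groups = list(list(label = "G", n = 200, traj = 1)), weeks = 1,
    pathCoefficients = list(behavior = c(stn_power = 0.7),
                            th = c(stn_power = 0), od = c(stn_power = 0)),
    noiseSd = c(behavior = 0.3, th = 1, od = 1), latentSd = 1, subjectSd = 0,
    simulateSignals = FALSE, seed = 61)
  ch <- simulateCohort(cc)
  d <- merge(ch$endpoints, ch$trueParameters$latents)
  bhat <- unname(coef(lm(cylinder_index ~ stn_power, d))[2])
  expect_lt(abs(bhat - 0.7), 0.1)
})

test_that("rising trajectories raise detected week-8 long-burst probability", {
  cc <- cohortConfig(
    groups = list(list(label = "A53T-high", n = 5, traj = c(1.5, 3.0))),
    weeks = c(2, 8), seed = 62)
  ch <- simulateCohort(cc)
  ft <- extractFeatures(ch$recordings, ch$endpoints)
  m2 <- mean(ft$stn_high_long_burst_prob[ft$week == 2], na.rm = TRUE)
  m8 <- mean(ft$stn_high_long_burst_prob[ft$week == 8], na.rm = TRUE)
  expect_gt(m8, m2)
})

test_that("cohort artifacts round-trip through the on-disk layout", {
  cc <- cohortConfig(groups = list(list(label = "EV", n = 1, traj = 1)),
                     weeks = 2, seed = 63)
  ch <- simulateCohort(cc)
  dir <- withr::local_tempdir()
  writeCohort(ch, dir, cfg = cc)
  files <- list.files(dir)
  expect_true(any(grepl("\\.edf$", files)))
  expect_true("endpoints.csv" %in% files)
  expect_true("config.txt" %in% files)
  rec <- readRecording(file.path(dir, grep("\\.edf$", files, value = TRUE)[1]))
  expect_equal(channelLabels(rec), c("MCx", "STN"))
  expect_equal(groupLabel(rec), "EV")
})
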