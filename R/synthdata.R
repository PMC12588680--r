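# Synthetic two-channel (MCx, STN) field-potential generator and cohort
# simulator. Every generated quantity (injected bursts, coupling, endpoint
# coefficients) is returned as ground truth so the downstream pipeline can be
# validated end to end.

# 1/f^expo background: white Gaussian noise shaped in the frequency domain
# (amplitude ~ f^(-expo/2)), rescaled to unit SD. Exactly controllable slope.
.pinkNoise <- function(n, fs, expo) {
  z <- stats::fft(stats::rnorm(n))
  f <- abs(.fftFreqs(n, fs))
  amp <- ifelse(f > 0, f^(-expo / 2), 0)
  x <- Re(stats::fft(z * amp, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Band-limited Gaussian noise via frequency-domain masking, unit SD.
.bandNoise <- function(n, fs, lo, hi) {
  z <- stats::fft(stats::rnorm(n))
  f <- abs(.fftFreqs(n, fs))
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(z * mask, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Synthetic recording configuration
#'
#' Defaults emulate the acquisition analysed by the pipeline: 256 Hz
#' sampling, 90 s (three 30-s epochs), 1/f background with a 50 Hz mains
#' component, Poisson beta bursts with gamma durations in the low
#' (13-20 Hz) and high (21-30 Hz) sub-bands, and a lagged shared beta source
#' mixed into both channels so the imaginary coherence is nonzero.
#'
#' @param fsHz sampling rate (default 256).
#' @param durationS recording length in seconds (>= 1).
#' @param oneOverFExponent background spectral slope (power ~ 1/f^exponent).
#' @param lineFreqHz,lineGain mains frequency (default 50 Hz) and amplitude
#'   relative to the unit-SD background.
#' @param burstRatePerMin expected bursts/min per sub-band, named vector
#'   \code{c(low = ..., high = ...)}.
#' @param burstDurationShape,burstDurationScale gamma parameters of burst
#'   duration (seconds); default mean 0.3 s.
#' @param burstAmplitudeMean,burstAmplitudeSd envelope gain of a burst
#'   relative to the background SD (truncated at 0.5).
#' @param couplingGain fraction of a shared 13-30 Hz source mixed into both
#'   channels, in [0, 1].
#' @param couplingLagMs delay of the shared source at STN relative to MCx.
#' @param burstEnvelope \code{"hann"} (gradual on/offsets, the default) or
#'   \code{"rect"} (abrupt, sharply timed events for timing-recovery
#'   studies); a per-event \code{envelope} column in \code{forcedEvents}
#'   overrides it.
#' @param minGapS enforced gap between bursts within a channel; colliding
#'   draws are resampled (up to 200 tries) and dropped if unplaceable.
#' @param forcedEvents optional list per channel
#'   (\code{list(MCx = data.frame(onset_s, duration_s, center_freq_hz,
#'   amplitude), STN = ...)}) of events injected verbatim before any random
#'   events.
#' @param perChannel optional per-channel scaling,
#'   \code{list(MCx = list(burstRateScale=, burstAmpScale=, burstDurScale=,
#'   betaNoiseGain=), STN = ...)}.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return validated config list.
#' @export
synthRecordingConfig <- function(fsHz = 256, durationS = 90,
                                 oneOverFExponent = 1,
                                 lineFreqHz = 50, lineGain = 0.5,
                                 burstRatePerMin = c(low = 6, high = 6),
                                 burstDurationShape = 3,
                                 burstDurationScale = 0.1,
                                 burstAmplitudeMean = 2,
                                 burstAmplitudeSd = 0.5,
                                 couplingGain = 0.3, couplingLagMs = 20,
                                 burstEnvelope = c("hann", "rect"),
                                 minGapS = 0.2, forcedEvents = NULL,
                                 perChannel = NULL, seed = 1) {
  burstEnvelope <- match.arg(burstEnvelope)
  if (durationS < 1)
    stop("durationS must be at least 1 s to hold an analysis window")
  if (couplingGain < 0 || couplingGain > 1)
    stop("couplingGain must lie in [0, 1]")
  if (any(burstRatePerMin < 0) || burstDurationScale < 0 || minGapS < 0)
    stop("rates, scales and gaps must be nonnegative")
  if (is.null(names(burstRatePerMin)))
    names(burstRatePerMin) <- c("low", "high")[seq_along(burstRatePerMin)]
  list(fsHz = fsHz, durationS = durationS,
       oneOverFExponent = oneOverFExponent, lineFreqHz = lineFreqHz,
       lineGain = lineGain, burstRatePerMin = burstRatePerMin,
       burstDurationShape = burstDurationShape,
       burstDurationScale = burstDurationScale,
       burstAmplitudeMean = burstAmplitudeMean,
       burstAmplitudeSd = burstAmplitudeSd,
       couplingGain = couplingGain, couplingLagMs = couplingLagMs,
       burstEnvelope = burstEnvelope,
       minGapS = minGapS, forcedEvents = forcedEvents,
       perChannel = perChannel, seed = as.integer(seed))
}

.subBandRange <- function(name) {
  switch(name, low = c(13, 20), high = c(21, 30),
         stop("unknown sub-band: ", name))
}

# Draw non-overlapping burst events for one channel.
.drawEvents <- function(cfg, rateScale = 1, ampScale = 1, durScale = 1) {
  ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                   center_freq_hz = numeric(0), amplitude = numeric(0))
  placed <- function(on, d) {
    if (!nrow(ev)) return(TRUE)
    all(on + d + cfg$minGapS <= ev$onset_s |
          on >= ev$onset_s + ev$duration_s + cfg$minGapS)
  }
  for (bandName in names(cfg$burstRatePerMin)) {
    rate <- cfg$burstRatePerMin[[bandName]] * rateScale
    if (rate <= 0) next
    rng <- .subBandRange(bandName)
    nEv <- stats::rpois(1, rate * cfg$durationS / 60)
    for (k in seq_len(nEv)) {
      for (try in 1:200) {
        d <- stats::rgamma(1, shape = cfg$burstDurationShape,
                           scale = cfg$burstDurationScale * durScale)
        d <- min(max(d, 0.1), 2)
        if (d >= cfg$durationS) next
        on <- stats::runif(1, 0, cfg$durationS - d)
        if (placed(on, d)) {
          f <- stats::runif(1, rng[1], rng[2])
          a <- max(stats::rnorm(1, cfg$burstAmplitudeMean * ampScale,
                                cfg$burstAmplitudeSd), 0.5)
          ev <- rbind(ev, data.frame(onset_s = on, duration_s = d,
                                     center_freq_hz = f, amplitude = a))
          break
        }
      }
    }
  }
  ev[order(ev$onset_s), , drop = FALSE]
}

# Add burst waveforms (tapered carrier sinusoids) to a channel signal.
# Envelope "hann" gives gradual on/offsets; "rect" gives abrupt, sharply
# timed events (per-event override via an `envelope` column).
.injectEvents <- function(x, ev, fs, envelope = "hann") {
  for (k in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset_s[k] * fs) + 1
    n <- max(as.integer(round(ev$duration_s[k] * fs)), 2)
    if (i0 + n - 1 > length(x)) n <- length(x) - i0 + 1
    tt <- (0:(n - 1)) / fs
    shape <- if (!is.null(ev$envelope)) ev$envelope[k] else envelope
    taper <- if (identical(shape, "rect")) rep(1, n) else .hann(n)
    x[i0:(i0 + n - 1)] <- x[i0:(i0 + n - 1)] +
      ev$amplitude[k] * taper *
        sin(2 * pi * ev$center_freq_hz[k] * tt + stats::runif(1, 0, 2 * pi))
  }
  x
}

#' Simulate a two-channel recording with known burst ground truth
#'
#' Each channel is unit-SD 1/f background plus a mains component, injected
#' beta bursts, and \code{couplingGain} of a shared 13-30 Hz source (delayed
#' by \code{couplingLagMs} at STN so the cross-spectrum acquires an imaginary
#' part). Identical config and seed give bit-identical output.
#'
#' @param cfg a [synthRecordingConfig()].
#' @param subjectId,groupLabel,week metadata stored in the recording.
#' @return list with elements \code{recording} (a [Recording-class]) and
#'   \code{events} (list of per-channel ground-truth event data.frames).
#' @export
simulateRecording <- function(cfg = synthRecordingConfig(),
                              subjectId = "S1", groupLabel = "sim",
                              week = 1L) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(cfg$seed)

  fs <- cfg$fsHz
  n <- as.integer(round(cfg$durationS * fs))
  tt <- (0:(n - 1)) / fs
  chans <- c("MCx", "STN")
  sig <- matrix(0, 2, n, dimnames = list(chans, NULL))
  events <- list()

  for (ch in chans) {
    pc <- cfg$perChannel[[ch]]
    rateScale <- if (is.null(pc$burstRateScale)) 1 else pc$burstRateScale
    ampScale <- if (is.null(pc$burstAmpScale)) 1 else pc$burstAmpScale
    durScale <- if (is.null(pc$burstDurScale)) 1 else pc$burstDurScale
    betaGain <- if (is.null(pc$betaNoiseGain)) 0 else pc$betaNoiseGain

    x <- .pinkNoise(n, fs, cfg$oneOverFExponent)
    if (cfg$lineGain > 0)
      x <- x + cfg$lineGain * sin(2 * pi * cfg$lineFreqHz * tt +
                                  stats::runif(1, 0, 2 * pi))
    ev <- .drawEvents(cfg, rateScale, ampScale, durScale)
    if (!is.null(cfg$forcedEvents[[ch]])) {
      forced <- cfg$forcedEvents[[ch]]
      ev <- rbind(forced[names(ev)], ev)
      ev <- ev[order(ev$onset_s), , drop = FALSE]
    }
    rownames(ev) <- NULL
    x <- .injectEvents(x, ev, fs,
                       envelope = if (is.null(cfg$burstEnvelope)) "hann"
                         else cfg$burstEnvelope)
    if (betaGain > 0) x <- x + betaGain * .bandNoise(n, fs, 21, 30)
    sig[ch, ] <- x
    events[[ch]] <- ev
  }

  if (cfg$couplingGain > 0) {
    s <- .bandNoise(n, fs, 13, 30)
    lag <- as.integer(round(cfg$couplingLagMs / 1000 * fs))
    sLag <- c(rep(0, lag), s)[1:n]
    sig["MCx", ] <- sig["MCx", ] + cfg$couplingGain * s
    sig["STN", ] <- sig["STN", ] + cfg$couplingGain * sLag
  }

  rec <- Recording(sig, fsHz = fs, channelLabels = chans,
                   subjectId = subjectId, groupLabel = groupLabel,
                   week = as.integer(week))
  list(recording = rec, events = events)
}

#' Cohort configuration
#'
#' Defaults emulate a three-group longitudinal design: an empty-vector
#' control group (n = 12) with flat trajectories and two lesion groups
#' (n = 7 and n = 6) whose pathology drive rises across weeks 2, 3, 4, 6, 8.
#' Per subject-week, latent beta features (power, burst amplitude, burst
#' rate per region) are drawn around the group trajectory; they scale the
#' injected signal content and generate the behavioural/histological
#' endpoints through a linear-Gaussian path model whose true coefficients
#' are returned for recovery testing.
#'
#' @param groups list of \code{list(label =, n =, traj =)} where \code{traj}
#'   is the per-week pathology multiplier (same length as \code{weeks}).
#' @param weeks measurement weeks, strictly increasing.
#' @param pathCoefficients named list of named coefficient vectors over the
#'   latent features \code{mcx_power, mcx_burst_amplitude, mcx_burst_rate,
#'   stn_power, stn_burst_amplitude, stn_burst_rate}; endpoints
#'   \code{behavior} (per week) and \code{th}, \code{od} (terminal week).
#' @param intercepts endpoint values at a pathology drive of 1 (control).
#' @param noiseSd endpoint noise SDs.
#' @param latentSd SD of the latent features around the trajectory.
#' @param subjectSd SD of the per-subject random offset shared across weeks.
#' @param baseRecording a [synthRecordingConfig()] used as the per-session
#'   template.
#' @param simulateSignals when FALSE only latent features and endpoints are
#'   generated (fast path for large-n endpoint-model studies).
#' @param seed root seed; per-subject streams are derived deterministically.
#' @return validated config list.
#' @export
cohortConfig <- function(
    groups = list(
      list(label = "EV", n = 12, traj = c(1, 1, 1, 1, 1)),
      list(label = "A53T-low", n = 7, traj = c(1.1, 1.2, 1.3, 1.6, 1.9)),
      list(label = "A53T-high", n = 6, traj = c(1.5, 1.8, 2.1, 2.6, 3.0))),
    weeks = c(2, 3, 4, 6, 8),
    pathCoefficients = list(
      behavior = c(stn_power = 6, stn_burst_amplitude = 3),
      th = c(stn_power = -38),
      od = c(stn_power = -42)),
    intercepts = c(behavior = 50, th = 100, od = 100),
    noiseSd = c(behavior = 3, th = 5, od = 5),
    latentSd = 0.15, subjectSd = 0.1,
    baseRecording = synthRecordingConfig(),
    simulateSignals = TRUE, seed = 1) {
  if (any(vapply(groups, function(g) g$n, numeric(1)) < 1))
    stop("every group needs at least one subject")
  if (is.unsorted(weeks, strictly = TRUE))
    stop("weeks must be strictly increasing")
  for (g in groups) {
    if (length(g$traj) != length(weeks))
      stop("trajectory multipliers must match the number of weeks")
    if (any(g$traj < 0)) stop("trajectory multipliers must be nonnegative")
  }
  list(groups = groups, weeks = weeks, pathCoefficients = pathCoefficients,
       intercepts = intercepts, noiseSd = noiseSd, latentSd = latentSd,
       subjectSd = subjectSd, baseRecording = baseRecording,
       simulateSignals = simulateSignals, seed = as.integer(seed))
}

.latentNames <- c("mcx_power", "mcx_burst_amplitude", "mcx_burst_rate",
                  "stn_power", "stn_burst_amplitude", "stn_burst_rate")

#' Simulate a longitudinal cohort with known endpoint model
#'
#' Per subject and week one recording (unless \code{simulateSignals} is
#' FALSE), plus an endpoint table (cylinder index per week; TH+ count and
#' striatal optical density generated at the terminal week and carried on
#' every row, as terminal histology is) and the full generative truth.
#'
#' @param cfg a [cohortConfig()].
#' @return list: \code{recordings} (named list of [Recording-class]),
#'   \code{events} (ground-truth injected bursts per recording),
#'   \code{endpoints} (data.frame subject, group, week, cylinder_index,
#'   th_count, striatal_od), \code{trueParameters} (latent features,
#'   coefficients, trajectories, noise).
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))

  recs <- list()
  evs <- list()
  rows <- list()
  lats <- list()
  sIdx <- 0
  for (g in cfg$groups) {
    for (s in seq_len(g$n)) {
      sIdx <- sIdx + 1
      subj <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g$label), s)
      set.seed(.childSeed(cfg$seed, sIdx))
      subjEff <- stats::rnorm(1, 0, cfg$subjectSd)
      latW8 <- NULL
      for (wi in seq_along(cfg$weeks)) {
        w <- cfg$weeks[wi]
        m <- g$traj[wi]
        lat <- stats::setNames(
          m + subjEff + stats::rnorm(length(.latentNames), 0, cfg$latentSd),
          .latentNames)
        if (wi == length(cfg$weeks)) latW8 <- lat
        lats[[length(lats) + 1]] <- data.frame(
          subject = subj, group = g$label, week = w, t(lat))
        beh <- cfg$intercepts[["behavior"]] +
          sum(cfg$pathCoefficients$behavior *
                (lat[names(cfg$pathCoefficients$behavior)] - 1)) +
          stats::rnorm(1, 0, cfg$noiseSd[["behavior"]])
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, group = g$label, week = w,
          cylinder_index = min(max(beh, 0), 100))
        if (cfg$simulateSignals) {
          rcfg <- cfg$baseRecording
          rcfg$seed <- .childSeed(cfg$seed, 100000 + sIdx * 100 + wi)
          rcfg$perChannel <- list(
            MCx = list(burstRateScale = max(lat[["mcx_burst_rate"]], 0.1),
                       burstAmpScale = max(lat[["mcx_burst_amplitude"]], 0.1),
                       burstDurScale = max(m, 0.5),
                       betaNoiseGain = 0.3 * max(lat[["mcx_power"]] - 1, 0)),
            STN = list(burstRateScale = max(lat[["stn_burst_rate"]], 0.1),
                       burstAmpScale = max(lat[["stn_burst_amplitude"]], 0.1),
                       burstDurScale = max(m, 0.5),
                       betaNoiseGain = 0.3 * max(lat[["stn_power"]] - 1, 0)))
          sim <- simulateRecording(rcfg, subjectId = subj,
                                   groupLabel = g$label, week = w)
          key <- sprintf("%s_w%d", subj, w)
          recs[[key]] <- sim$recording
          evs[[key]] <- sim$events
        }
      }
      th <- cfg$intercepts[["th"]] +
        sum(cfg$pathCoefficients$th *
              (latW8[names(cfg$pathCoefficients$th)] - 1)) +
        stats::rnorm(1, 0, cfg$noiseSd[["th"]])
      od <- cfg$intercepts[["od"]] +
        sum(cfg$pathCoefficients$od *
              (latW8[names(cfg$pathCoefficients$od)] - 1)) +
        stats::rnorm(1, 0, cfg$noiseSd[["od"]])
      for (k in (length(rows) - length(cfg$weeks) + 1):length(rows)) {
        rows[[k]]$th_count <- max(th, 0)
        rows[[k]]$striatal_od <- max(od, 0)
      }
    }
  }
  endpoints <- do.call(rbind, rows)
  latents <- do.call(rbind, lats)
  list(recordings = recs, events = evs, endpoints = endpoints,
       trueParameters = list(latents = latents,
                             coefficients = cfg$pathCoefficients,
                             intercepts = cfg$intercepts,
                             noiseSd = cfg$noiseSd,
                             trajectories = lapply(cfg$groups, `[[`, "traj"),
                             weeks = cfg$weeks))
}

#' Write a simulated cohort to disk
#'
#' One EDF per subject-week (channels MCx, STN), a CSV event sidecar per
#' recording, the endpoint table as CSV and the configuration as key: value
#' text.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param cfg the [cohortConfig()] used (written as config.txt when given).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings)) {
    writeEDF(cohort$recordings[[key]], file.path(dir, paste0(key, ".edf")))
    evAll <- do.call(rbind, lapply(names(cohort$events[[key]]), function(ch) {
      ev <- cohort$events[[key]][[ch]]
      if (nrow(ev)) cbind(channel = ch, ev) else NULL
    }))
    if (is.null(evAll))
      evAll <- data.frame(channel = character(0), onset_s = numeric(0),
                          duration_s = numeric(0), center_freq_hz = numeric(0),
                          amplitude = numeric(0))
    utils::write.csv(evAll, file.path(dir, paste0(key, "_events.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$endpoints, file.path(dir, "endpoints.csv"),
                   row.names = FALSE)
  if (!is.null(cfg)) writeConfigText(cfg, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write a configuration as key: value text
#' @param cfg a configuration list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfigText <- function(cfg, path) {
  flat <- unlist(cfg[!vapply(cfg, function(x)
    is.function(x) || is.list(x) && !is.null(names(x)) &&
      any(vapply(x, is.list, logical(1))), logical(1))])
  writeLines(sprintf("%s: %s", names(flat), as.character(flat)), path)
  invisible(path)
}
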