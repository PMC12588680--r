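# Orchestration: per-cohort feature extraction (power, coherence, bursts),
# the full simulate -> epoch -> features -> statistics -> path-model run,
# and report writing.

.featureRegistry <- function() {
  c("mcx_total_beta_power", "mcx_high_beta_power", "mcx_low_beta_power",
    "stn_total_beta_power", "stn_high_beta_power", "stn_low_beta_power",
    "coh_total_beta", "coh_high_beta", "coh_low_beta",
    "mcx_high_burst_amplitude", "mcx_high_burst_rate", "mcx_high_long_burst_prob",
    "mcx_low_burst_amplitude", "mcx_low_burst_rate", "mcx_low_long_burst_prob",
    "stn_high_burst_amplitude", "stn_high_burst_rate", "stn_high_long_burst_prob",
    "stn_low_burst_amplitude", "stn_low_burst_rate", "stn_low_long_burst_prob")
}

#' Extract the longitudinal feature table from a set of recordings
#'
#' For every recording: artifact-screened 30-s epochs; normalized power band
#' means (total/high/low beta) per region; band-mean imaginary coherence
#' between MCx and STN; and beta-burst statistics per region and sub-band.
#' Burst thresholds are the common 75th-percentile thresholds pooled
#' region-wise (per sub-band) over the entire input set before any
#' per-subject detection, so group and week comparisons share one threshold.
#' Deterministic given its inputs.
#'
#' @param recordings list of [Recording-class] (each with MCx and STN).
#' @param endpoints optional data.frame keyed by subject/group/week with
#'   endpoint columns (e.g. cylinder_index, th_count, striatal_od) joined
#'   onto the table.
#' @param nEpochs,epochS,artifactK epoch-selection rule (see
#'   [selectEpochs()]).
#' @param thresholdQuantile burst threshold quantile (default 0.75).
#' @return data.frame, one row per subject-week, with the full feature
#'   registry; features that could not be computed are NA with the reason in
#'   attribute \code{"flags"}.
#' @export
extractFeatures <- function(recordings, endpoints = NULL, nEpochs = 3,
                            epochS = 30, artifactK = 6,
                            thresholdQuantile = 0.75) {
  if (!length(recordings)) stop("no recordings supplied")
  regions <- c(mcx = "MCx", stn = "STN")
  bandsPB <- list(high = betaBand("high"), low = betaBand("low"))
  flags <- character(0)

  # pass 1: epochs, z-scored epoch samples, envelopes (for threshold pooling)
  prep <- lapply(recordings, function(rec) {
    miss <- setdiff(regions, channelLabels(rec))
    if (length(miss))
      return(list(ok = FALSE,
                  why = paste("missing region(s):", paste(miss, collapse = ","))))
    es <- tryCatch(selectEpochs(rec, n = nEpochs, epochS = epochS,
                                artifactK = artifactK),
                   error = function(e) e)
    if (inherits(es, "error")) return(list(ok = FALSE, why = conditionMessage(es)))
    z <- list()
    env <- list()
    for (rg in names(regions)) {
      eps <- epochSamples(rec, regions[[rg]], es)
      zAll <- zScoreSignal(unlist(eps, use.names = FALSE))
      lens <- c(0, cumsum(lengths(eps)))
      zEps <- lapply(seq_along(eps), function(i) zAll[(lens[i] + 1):lens[i + 1]])
      z[[rg]] <- zEps
      for (bn in names(bandsPB)) {
        cfg <- burstConfig(band = bandsPB[[bn]],
                           thresholdQuantile = thresholdQuantile)
        env[[paste(rg, bn, sep = "_")]] <-
          lapply(zEps, bandEnvelope, fs = fsHz(rec), cfg = cfg)
      }
    }
    list(ok = TRUE, es = es, z = z, env = env, fs = fsHz(rec))
  })

  # common thresholds: pool all envelope samples region-wise per sub-band
  thresholds <- list()
  for (rg in names(regions)) for (bn in names(bandsPB)) {
    key <- paste(rg, bn, sep = "_")
    pool <- unlist(lapply(prep, function(p) if (isTRUE(p$ok)) p$env[[key]]),
                   use.names = FALSE)
    cfg <- burstConfig(band = bandsPB[[bn]],
                       thresholdQuantile = thresholdQuantile)
    thresholds[[key]] <- if (length(pool)) pooledThreshold(pool, cfg) else NA_real_
  }

  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    row <- data.frame(subject = subjectId(rec), group = groupLabel(rec),
                      week = week(rec))
    for (f in .featureRegistry()) row[[f]] <- NA_real_
    p <- prep[[i]]
    if (!isTRUE(p$ok)) {
      flags <<- c(flags, sprintf("%s w%s: %s", subjectId(rec), week(rec), p$why))
      return(row)
    }
    es <- p$es
    for (rg in names(regions)) {
      ps <- normalizeSpectrum(periodogramHann(rec, regions[[rg]], es))
      row[[paste0(rg, "_total_beta_power")]] <- bandMean(ps, betaBand("total"))
      row[[paste0(rg, "_high_beta_power")]] <- bandMean(ps, betaBand("high"))
      row[[paste0(rg, "_low_beta_power")]] <- bandMean(ps, betaBand("low"))
    }
    cs <- imaginaryCoherence(rec, "MCx", "STN", es = es)
    row$coh_total_beta <- bandMeanCoherence(cs, betaBand("total"))
    row$coh_high_beta <- bandMeanCoherence(cs, betaBand("high"))
    row$coh_low_beta <- bandMeanCoherence(cs, betaBand("low"))
    totalTime <- nEpochs * epochS
    for (rg in names(regions)) for (bn in names(bandsPB)) {
      key <- paste(rg, bn, sep = "_")
      cfg <- burstConfig(band = bandsPB[[bn]],
                         thresholdQuantile = thresholdQuantile)
      bsList <- lapply(p$env[[key]], detectBursts,
                       threshold = thresholds[[key]], fs = p$fs, cfg = cfg,
                       channel = regions[[rg]])
      bs <- combineBurstSets(bsList, epochs(es)[, 1])
      st <- burstStats(bs, totalTime)
      row[[paste0(rg, "_", bn, "_burst_amplitude")]] <- st$amplitude
      row[[paste0(rg, "_", bn, "_burst_rate")]] <- st$rate
      row[[paste0(rg, "_", bn, "_long_burst_prob")]] <- st$longBurstProb
    }
    row
  })
  ft <- do.call(rbind, rows)
  if (!is.null(endpoints)) {
    ft <- merge(ft, endpoints, by = c("subject", "group", "week"),
                all.x = TRUE, sort = FALSE)
  }
  ft <- ft[order(ft$group, ft$subject, ft$week), , drop = FALSE]
  rownames(ft) <- NULL
  attr(ft, "flags") <- flags
  attr(ft, "thresholds") <- thresholds
  ft
}

#' Run configuration for the full pipeline
#'
#' @param mode \code{"rat"} (simulate recordings, run every stage) or
#'   \code{"human-features"} (consume a precomputed feature table; signal
#'   stages are skipped, the path-model stages run unchanged).
#' @param outDir output directory.
#' @param seed mandatory root seed.
#' @param cohort a [cohortConfig()] (rat mode).
#' @param featureCsv path to a precomputed feature CSV (human-features mode).
#' @param modelFiles named character vector of path-model files; defaults to
#'   the bundled high-beta and low-beta mediation models.
#' @param nEpochs,epochS,artifactK epoch rule passed to [extractFeatures()].
#' @return validated config list.
#' @export
runConfig <- function(mode = c("rat", "human-features"), outDir = tempfile("betadyn_"),
                      seed = NULL, cohort = cohortConfig(seed = seed),
                      featureCsv = NULL,
                      modelFiles = c(
                        high_beta = system.file("extdata", "model_high_beta.txt",
                                                package = "betadyn"),
                        low_beta = system.file("extdata", "model_low_beta.txt",
                                               package = "betadyn")),
                      nEpochs = 3, epochS = 30, artifactK = 6) {
  mode <- match.arg(mode)
  if (is.null(seed)) stop("a seed is mandatory for a pipeline run")
  if (mode == "human-features" && is.null(featureCsv))
    stop("human-features mode requires featureCsv")
  if (!all(file.exists(modelFiles)))
    stop("model file(s) not found: ",
         paste(modelFiles[!file.exists(modelFiles)], collapse = ", "))
  cohort$seed <- as.integer(seed)
  list(mode = mode, outDir = outDir, seed = as.integer(seed),
       cohort = cohort, featureCsv = featureCsv, modelFiles = modelFiles,
       nEpochs = nEpochs, epochS = epochS, artifactK = artifactK)
}

.weekStats <- function(ft, feature) {
  out <- list()
  for (w in sort(unique(ft$week))) {
    d <- ft[ft$week == w & !is.na(ft[[feature]]), ]
    if (nrow(d) < 6 || length(unique(d$group)) < 2) next
    if (min(table(d$group)) < 3) next
    res <- tryCatch(compareGroups(d[[feature]], d$group),
                    error = function(e) NULL)
    if (!is.null(res))
      out[[as.character(w)]] <- list(week = w, test = res$test_name,
                                     statistic = res$statistic_label,
                                     p_value = res$p_value,
                                     posthoc = res$posthoc)
  }
  out
}

#' Run the full pipeline
#'
#' Stages: simulate (rat mode) -> epochs/features -> group statistics and
#' final-week correlations -> path models -> cumulative composite score and
#' behaviour-versus-degeneration curves -> report. Outputs land in
#' \code{cfg$outDir}: \code{features.csv}, \code{group_stats.json},
#' \code{correlations.json}, \code{sem_<model>.json},
#' \code{composite.json}, \code{curves.json} and \code{run_log.txt}. A stage
#' failure writes a \code{failed/<stage>} marker, keeps partial outputs and
#' aborts with the stage name.
#'
#' @param cfg a [runConfig()].
#' @return invisible list of the main in-memory results.
#' @export
runAll <- function(cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(cfg$outDir, "run_log.txt")
  cat(sprintf("betadyn %s | mode=%s | seed=%d | %s\n",
              as.character(utils::packageVersion("betadyn")), cfg$mode,
              cfg$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = log)
  stage <- function(name, expr) {
    cat(sprintf("stage %s\n", name), file = log, append = TRUE)
    tryCatch(expr, error = function(e) {
      dir.create(file.path(cfg$outDir, "failed"), showWarnings = FALSE)
      writeLines(conditionMessage(e), file.path(cfg$outDir, "failed", name))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  results <- list()
  if (cfg$mode == "rat") {
    cohort <- stage("simulate", simulateCohort(cfg$cohort))
    ft <- stage("features",
                extractFeatures(cohort$recordings, cohort$endpoints,
                                nEpochs = cfg$nEpochs, epochS = cfg$epochS,
                                artifactK = cfg$artifactK))
    results$cohort <- cohort
  } else {
    ft <- stage("features", utils::read.csv(cfg$featureCsv))
  }
  utils::write.csv(ft, file.path(cfg$outDir, "features.csv"), row.names = FALSE)
  results$features <- ft

  keyCols <- c("subject", "group", "week")
  numFeatures <- setdiff(names(ft)[vapply(ft, is.numeric, logical(1))], "week")

  stats <- stage("stats", {
    gs <- lapply(stats::setNames(nm = numFeatures), function(f) .weekStats(ft, f))
    lastWeek <- max(ft$week)
    dl <- ft[ft$week == lastWeek, ]
    corTargets <- intersect(c("cylinder_index", "th_count", "striatal_od"),
                            names(ft))
    cors <- list()
    for (tgt in corTargets) {
      for (f in setdiff(numFeatures, corTargets)) {
        ok <- stats::complete.cases(dl[[f]], dl[[tgt]])
        if (sum(ok) >= 4 && stats::sd(dl[[f]][ok]) > 0 &&
            stats::sd(dl[[tgt]][ok]) > 0) {
          ct <- correlateFeatures(dl[[f]], dl[[tgt]])
          cors[[paste(tgt, f, sep = "~")]] <-
            list(target = tgt, feature = f, method = ct$method, r = ct$r,
                 p_value = ct$p_value, n = ct$n)
        }
      }
    }
    jsonlite::write_json(gs, file.path(cfg$outDir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(cors, file.path(cfg$outDir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(groupStats = gs, correlations = cors)
  })
  results$stats <- stats

  sems <- stage("sem", {
    out <- list()
    for (nm in names(cfg$modelFiles)) {
      model <- readPathModel(cfg$modelFiles[[nm]])
      if (!all(model@variables %in% names(ft))) next
      fit <- fitPathModel(model, ft)
      pv <- estimates(fit)$p
      cm <- abs(stats::cor(ft[model@variables],
                           use = "pairwise.complete.obs"))
      rbar <- mean(cm[upper.tri(cm)])
      adj <- adjustedBonferroni(pv, rbar)
      writeSEMFitJSON(fit, file.path(cfg$outDir, sprintf("sem_%s.json", nm)))
      out[[nm]] <- list(fit = fit, adjusted = adj)
    }
    out
  })
  results$sem <- sems

  composite <- stage("composite", {
    menu <- c(.featureRegistry(), "cylinder_index", "striatal_od")
    menu <- intersect(menu, names(ft))
    need <- c(menu, "th_count")
    ftc <- ft[stats::complete.cases(ft[need]), , drop = FALSE]
    cum <- cumulativeFeatures(ftc, features = setdiff(need, keyCols))
    last <- cum[cum$week == max(cum$week), , drop = FALSE]
    # neurodegeneration target: mean of min-max normalized TH+ and OD losses
    ctrl <- ftc$group[which.max(ftc$th_count)]  # least-degenerated group
    lastRaw <- ftc[ftc$week == max(ftc$week), , drop = FALSE]
    mm <- function(x) if (diff(range(x)) > 0)
      (x - min(x)) / diff(range(x)) else rep(0, length(x))
    lossTh <- 1 - lastRaw$th_count / mean(lastRaw$th_count[lastRaw$group == ctrl])
    lossOd <- 1 - lastRaw$striatal_od /
      mean(lastRaw$striatal_od[lastRaw$group == ctrl])
    target <- 100 * (mm(lossTh) + mm(lossOd)) / 2
    perGroup <- list()
    for (g in unique(last$group)) {
      gi <- last$group == g
      ti <- lastRaw$group == g
      perGroup[[g]] <- compositeScore(last[gi, menu, drop = FALSE],
                                      target[ti])
    }
    jsonlite::write_json(
      lapply(perGroup, function(x) x[c("selected", "weights", "rmse",
                                       "baselineRMSE")]),
      file.path(cfg$outDir, "composite.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    curves <- tryCatch({
      deficit <- abs(lastRaw$cylinder_index - 50)
      degen <- 100 * (lossTh + lossOd) / 2
      degenerationBehaviorCurve(deficit, degen,
                                ifelse(lastRaw$group == ctrl, "EV", "A53T"))
    }, error = function(e) NULL)
    if (!is.null(curves))
      jsonlite::write_json(curves, file.path(cfg$outDir, "curves.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(perGroup = perGroup, target = target, curves = curves)
  })
  results$composite <- composite

  cat("done\n", file = log, append = TRUE)
  invisible(results)
}
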