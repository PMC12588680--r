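# Accessors and show methods for the core containers.

#' @rdname Recording-class
#' @param object,x a package object
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))
#' @rdname Recording-class
#' @export
setMethod("fsHz", "Recording", function(x) x@fsHz)
#' @rdname EpochSet-class
#' @export
setMethod("fsHz", "EpochSet", function(x) x@fsHz)

#' @rdname Recording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname Recording-class
#' @export
setMethod("channelLabels", "Recording", function(x) x@channelLabels)

#' @rdname Recording-class
#' @param channel channel label (default: all channels as a matrix)
#' @export
setGeneric("samples", function(x, channel = NULL) standardGeneric("samples"))
#' @rdname Recording-class
#' @export
setMethod("samples", "Recording", function(x, channel = NULL) {
  if (is.null(channel)) return(x@samples)
  if (!channel %in% x@channelLabels)
    stop("unknown channel label: ", channel)
  x@samples[channel, ]
})

#' @rdname Recording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname Recording-class
#' @export
setMethod("subjectId", "Recording", function(x) x@subjectId)

#' @rdname Recording-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname Recording-class
#' @export
setMethod("groupLabel", "Recording", function(x) x@groupLabel)

#' @rdname Recording-class
#' @export
setGeneric("week", function(x) standardGeneric("week"))
#' @rdname Recording-class
#' @export
setMethod("week", "Recording", function(x) x@week)

#' @rdname Recording-class
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @rdname Recording-class
#' @export
setMethod("durationS", "Recording", function(x) ncol(x@samples) / x@fsHz)

#' @rdname EpochSet-class
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname EpochSet-class
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)

#' @rdname EpochSet-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname EpochSet-class
#' @export
setMethod("nEpochs", "EpochSet", function(x) nrow(x@epochs))

#' @rdname PowerSpectrum-class
#' @export
setGeneric("freqsHz", function(x) standardGeneric("freqsHz"))
#' @rdname PowerSpectrum-class
#' @export
setMethod("freqsHz", "PowerSpectrum", function(x) x@freqsHz)
#' @rdname CoherenceSpectrum-class
#' @export
setMethod("freqsHz", "CoherenceSpectrum", function(x) x@freqsHz)

#' @rdname PowerSpectrum-class
#' @export
setGeneric("specPower", function(x) standardGeneric("specPower"))
#' @rdname PowerSpectrum-class
#' @export
setMethod("specPower", "PowerSpectrum", function(x) x@power)

#' @rdname PowerSpectrum-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname PowerSpectrum-class
#' @export
setMethod("isNormalized", "PowerSpectrum", function(x) x@normalized)

#' @rdname CoherenceSpectrum-class
#' @export
setGeneric("icoh", function(x) standardGeneric("icoh"))
#' @rdname CoherenceSpectrum-class
#' @export
setMethod("icoh", "CoherenceSpectrum", function(x) x@icoh)

#' @rdname BurstSet-class
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))
#' @rdname BurstSet-class
#' @export
setMethod("bursts", "BurstSet", function(x) x@bursts)

#' @rdname BurstSet-class
#' @export
setGeneric("nBursts", function(x) standardGeneric("nBursts"))
#' @rdname BurstSet-class
#' @export
setMethod("nBursts", "BurstSet", function(x) nrow(x@bursts))

#' @rdname BurstSet-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname BurstSet-class
#' @export
setMethod("thresholdUsed", "BurstSet", function(x) x@thresholdUsed)

#' @rdname SEMFit-class
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname SEMFit-class
#' @export
setMethod("estimates", "SEMFit", function(x) x@estimates)

#' @rdname SEMFit-class
#' @export
setGeneric("fitIndices", function(x) standardGeneric("fitIndices"))
#' @rdname SEMFit-class
#' @export
setMethod("fitIndices", "SEMFit", function(x) {
  c(chi2 = x@chi2, df = x@df, rmsea = x@rmsea, aic = x@aic,
    srmr = x@srmr, cfi = x@cfi, n = x@n, nFree = x@nFree)
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fsHz,
              ncol(object@samples) / object@fsHz))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
  cat(sprintf("  subject %s | group %s | week %s\n", object@subjectId,
              object@groupLabel, object@week))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epoch(s) of %s s (source %.1f s @ %g Hz)\n",
              nrow(object@epochs),
              paste(unique(round(object@epochs[, 2] - object@epochs[, 1], 3)),
                    collapse = "/"),
              object@sourceDurationS, object@fsHz))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, %g-%g Hz, %s\n",
              length(object@freqsHz), min(object@freqsHz), max(object@freqsHz),
              if (object@normalized) "normalized" else "absolute"))
})

setMethod("show", "CoherenceSpectrum", function(object) {
  cat(sprintf("CoherenceSpectrum: %d bins, %g-%g Hz, max |Im C| = %.3f\n",
              length(object@freqsHz), min(object@freqsHz), max(object@freqsHz),
              max(object@icoh)))
})

setMethod("show", "BurstSet", function(object) {
  cat(sprintf("BurstSet (%s): %d burst(s), threshold %.4g\n",
              object@channel, nrow(object@bursts), object@thresholdUsed))
})

setMethod("show", "PathModel", function(object) {
  cat(sprintf("PathModel: %d variable(s), %d path(s)\n",
              length(object@variables), nrow(object@edges)))
  if (nrow(object@edges))
    cat(paste0("  ", object@edges$from, " -> ", object@edges$to,
               collapse = "\n"), "\n")
})

setMethod("show", "SEMFit", function(object) {
  cat(sprintf(
    "SEMFit: n = %d, chi2(%d) = %.4g, RMSEA = %.4g, AIC = %.4g%s\n",
    object@n, object@df, object@chi2, object@rmsea, object@aic,
    if (object@converged) "" else " [NOT CONVERGED]"))
  print(object@estimates, digits = 3)
})
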