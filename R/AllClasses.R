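#' @import methods
NULL

#' Multichannel field-potential recording
#'
#' Container for a resting-state recording: a channel-by-time sample matrix
#' (arbitrary amplifier units), its sampling rate and the subject metadata the
#' longitudinal pipeline keys on.
#'
#' @slot samples numeric matrix, channels in rows (rownames are the channel
#'   labels), samples in columns.
#' @slot fsHz sampling rate in Hz.
#' @slot channelLabels region labels, e.g. \code{"MCx"}, \code{"STN"}.
#' @slot subjectId subject identifier.
#' @slot groupLabel experimental group, e.g. \code{"EV"}, \code{"A53T-high"}.
#' @slot week integer week of the recording session.
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    samples = "matrix",
    fsHz = "numeric",
    channelLabels = "character",
    subjectId = "character",
    groupLabel = "character",
    week = "integer"
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@fsHz) != 1 || !is.finite(object@fsHz) || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "samples must have one row per channel label")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be numeric")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples channel-by-time numeric matrix.
#' @param fsHz sampling rate (Hz).
#' @param channelLabels channel labels; defaults to the matrix rownames.
#' @param subjectId,groupLabel,week subject metadata.
#' @return A [Recording-class] object.
#' @export
Recording <- function(samples, fsHz, channelLabels = rownames(samples),
                      subjectId = NA_character_, groupLabel = NA_character_,
                      week = NA_integer_) {
  if (is.null(channelLabels))
    stop("channelLabels must be supplied (or set as rownames of samples)")
  samples <- as.matrix(samples)
  if (length(channelLabels) != nrow(samples))
    stop("samples must have one row per channel label (",
         nrow(samples), " rows, ", length(channelLabels), " labels)")
  rownames(samples) <- channelLabels
  new("Recording",
    samples = samples, fsHz = as.numeric(fsHz),
    channelLabels = as.character(channelLabels),
    subjectId = as.character(subjectId),
    groupLabel = as.character(groupLabel), week = as.integer(week))
}

#' Set of analysis epochs
#'
#' Half-open time intervals \code{[start, end)} in seconds selected from a
#' recording for spectral/burst analysis. Sample index of time t is
#' \code{floor(t * fs)} (0-based), so adjacent epochs never share a sample.
#'
#' @slot epochs two-column matrix (start_s, end_s).
#' @slot fsHz sampling rate of the source recording.
#' @slot sourceDurationS duration of the source recording in seconds.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(epochs = "matrix", fsHz = "numeric",
                 sourceDurationS = "numeric"))

setValidity("EpochSet", function(object) {
  ep <- object@epochs
  msg <- character(0)
  if (ncol(ep) != 2) msg <- c(msg, "epochs must have two columns (start_s, end_s)")
  else {
    if (any(ep[, 2] <= ep[, 1])) msg <- c(msg, "epochs must have positive length")
    if (any(ep[, 1] < 0) || any(ep[, 2] > object@sourceDurationS + 1e-9))
      msg <- c(msg, "epochs must lie within the recording bounds")
    if (nrow(ep) > 1) {
      o <- order(ep[, 1])
      if (any(ep[o, 1][-1] < ep[o, 2][-nrow(ep)] - 1e-9))
        msg <- c(msg, "epochs must be non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

EpochSet <- function(epochs, fsHz, sourceDurationS) {
  epochs <- matrix(as.numeric(epochs), ncol = 2,
                   dimnames = list(NULL, c("start_s", "end_s")))
  new("EpochSet", epochs = epochs, fsHz = as.numeric(fsHz),
      sourceDurationS = as.numeric(sourceDurationS))
}

#' Frequency-indexed power spectrum
#'
#' @slot freqsHz frequency bins (Hz), 0..Nyquist at 1 Hz spacing.
#' @slot power per-bin power; absolute units before normalization, a unitless
#'   fraction afterwards.
#' @slot normalized whether [normalizeSpectrum()] has been applied.
#' @slot normBands two-column matrix of the bands the normalization summed over.
#'
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  representation(freqsHz = "numeric", power = "numeric",
                 normalized = "logical", normBands = "matrix"))

setValidity("PowerSpectrum", function(object) {
  msg <- character(0)
  if (length(object@freqsHz) != length(object@power))
    msg <- c(msg, "freqsHz and power must have equal length")
  if (any(object@power < -1e-12))
    msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

PowerSpectrum <- function(freqsHz, power, normalized = FALSE,
                          normBands = matrix(numeric(0), ncol = 2)) {
  new("PowerSpectrum", freqsHz = as.numeric(freqsHz),
      power = as.numeric(power), normalized = normalized,
      normBands = normBands)
}

#' Imaginary-coherence spectrum
#'
#' Absolute imaginary part of the coherency between two channels, per 1-Hz bin.
#'
#' @slot freqsHz frequency bins (Hz).
#' @slot icoh per-bin |Im coherency| in [0, 1].
#'
#' @exportClass CoherenceSpectrum
setClass("CoherenceSpectrum",
  representation(freqsHz = "numeric", icoh = "numeric"))

setValidity("CoherenceSpectrum", function(object) {
  msg <- character(0)
  if (length(object@freqsHz) != length(object@icoh))
    msg <- c(msg, "freqsHz and icoh must have equal length")
  if (any(object@icoh < -1e-12) || any(object@icoh > 1 + 1e-9))
    msg <- c(msg, "icoh must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

CoherenceSpectrum <- function(freqsHz, icoh) {
  new("CoherenceSpectrum", freqsHz = as.numeric(freqsHz),
      icoh = as.numeric(icoh))
}

#' Detected beta bursts
#'
#' Supra-threshold oscillation periods from one envelope, sorted and
#' non-overlapping, each at least the configured minimum duration.
#'
#' @slot bursts data.frame with columns start_s, end_s, duration_s, peak, mean.
#' @slot thresholdUsed the envelope power threshold applied.
#' @slot channel source channel label.
#' @slot minDurationS minimum duration enforced at detection (s).
#'
#' @exportClass BurstSet
setClass("BurstSet",
  representation(bursts = "data.frame", thresholdUsed = "numeric",
                 channel = "character", minDurationS = "numeric"))

setValidity("BurstSet", function(object) {
  b <- object@bursts
  msg <- character(0)
  need <- c("start_s", "end_s", "duration_s", "peak", "mean")
  if (!all(need %in% names(b)))
    msg <- c(msg, "bursts must have columns start_s, end_s, duration_s, peak, mean")
  else if (nrow(b)) {
    if (any(b$duration_s <= 0)) msg <- c(msg, "burst durations must be positive")
    if (any(b$duration_s < object@minDurationS - 1e-9))
      msg <- c(msg, "all bursts must meet the minimum duration")
    if (is.unsorted(b$start_s)) msg <- c(msg, "bursts must be sorted by start")
    if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)] - 1e-9))
      msg <- c(msg, "bursts must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

BurstSet <- function(bursts, thresholdUsed, channel = NA_character_,
                     minDurationS = 0.1) {
  new("BurstSet", bursts = bursts, thresholdUsed = as.numeric(thresholdUsed),
      channel = as.character(channel), minDurationS = as.numeric(minDurationS))
}

#' Directed path model over observed variables
#'
#' A recursive (acyclic) system of linear structural relations. Exogenous
#' variables (those never appearing as an edge target) get free variances and
#' covariances; each endogenous variable gets a free residual variance.
#'
#' @slot variables observed variable names.
#' @slot edges data.frame with columns \code{from}, \code{to}; one free path
#'   coefficient per row.
#'
#' @exportClass PathModel
setClass("PathModel",
  representation(variables = "character", edges = "data.frame"))

setValidity("PathModel", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!all(c("from", "to") %in% names(e)))
    msg <- c(msg, "edges must have columns from, to")
  else {
    if (!all(c(e$from, e$to) %in% object@variables))
      msg <- c(msg, "all edge endpoints must be declared variables")
    if (nrow(e) && .hasCycle(object@variables, e))
      msg <- c(msg, "path model must be acyclic")
  }
  if (length(msg)) msg else TRUE
})

.hasCycle <- function(vars, edges) {
  adj <- split(edges$to, factor(edges$from, levels = vars))
  state <- setNames(rep(0L, length(vars)), vars)  # 0 new, 1 visiting, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(vars, visit, logical(1)))
}

#' Construct a PathModel
#'
#' @param edges data.frame (or two-column matrix) of directed edges
#'   \code{from -> to}.
#' @param variables variable names; defaults to all names used in the edges.
#' @return A [PathModel-class].
#' @export
PathModel <- function(edges, variables = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(variables)) variables <- unique(c(edges$from, edges$to))
  new("PathModel", variables = as.character(variables), edges = edges)
}

#' Fitted path model
#'
#' @slot estimates data.frame of paths: from, to, est (unstandardized),
#'   se, z, p, std (standardized coefficient S), se_std (delta-method SE of
#'   std).
#' @slot chi2 model chi-square, (n-1) times the ML discrepancy.
#' @slot df model degrees of freedom.
#' @slot rmsea root mean square error of approximation.
#' @slot aic chi2 + 2 q, q = number of free parameters.
#' @slot srmr standardized root mean square residual.
#' @slot cfi comparative fit index against the independence model.
#' @slot n sample size used (complete cases).
#' @slot nFree number of free parameters.
#' @slot converged logical.
#' @slot impliedCov model-implied covariance matrix.
#'
#' @exportClass SEMFit
setClass("SEMFit",
  representation(estimates = "data.frame", chi2 = "numeric", df = "numeric",
                 rmsea = "numeric", aic = "numeric", srmr = "numeric",
                 cfi = "numeric", n = "numeric", nFree = "numeric",
                 converged = "logical", impliedCov = "matrix"))

setValidity("SEMFit", function(object) {
  msg <- character(0)
  if (object@df < 0) msg <- c(msg, "df must be >= 0")
  if (object@rmsea < 0) msg <- c(msg, "rmsea must be >= 0")
  if (length(msg)) msg else TRUE
})
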