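# Behavioural and imaging indices.

#' Cylinder-test forepaw-preference index
#'
#' Percentage of ipsilateral forepaw use:
#' \code{100 * (ipsi + 0.5 * both) / (ipsi + contra + both)}.
#' 50 indicates symmetric use of both forepaws; values above 50 indicate a
#' preference for the paw ipsilateral to the lesioned hemisphere.
#'
#' @param ipsi ipsilateral-paw wall touches (nonnegative count).
#' @param contra contralateral-paw touches.
#' @param both simultaneous both-paw touches.
#' @return percentage in [0, 100].
#' @export
#' @examples
#' cylinderIndex(12, 12, 6)  # 50: symmetric forepaw use
cylinderIndex <- function(ipsi, contra, both) {
  if (any(c(ipsi, contra, both) < 0))
    stop("touch counts must be nonnegative")
  total <- ipsi + contra + both
  if (total <= 0) stop("at least one wall touch is required for a valid trial")
  100 * (ipsi + 0.5 * both) / total
}

#' Specific tracer binding ratio
#'
#' Semi-quantitative dopamine-transporter SPECT binding of a target region
#' relative to the occipital reference:
#' \code{(region - occipital) / occipital}.
#'
#' @param region tracer value of the striatum / caudate / putamen VOI.
#' @param occipital reference-region value (> 0).
#' @return specific binding ratio (>= -1).
#' @export
#' @examples
#' specificBinding(2, 1)  # 1.0
specificBinding <- function(region, occipital) {
  if (any(occipital <= 0)) stop("occipital reference must be positive")
  (region - occipital) / occipital
}
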