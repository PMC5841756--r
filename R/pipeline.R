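# End-to-end demarcation pipeline.

#' Segment Haller's layer boundary in one B-scan
#'
#' Runs the full chain: Wiener denoising and adaptive histogram
#' equalization, exponential enhancement and Otsu binarization,
#' restriction to the \[CIB, COB\] band, morphological opening (speckle
#' debridement) then closing, watershed separation with the
#' extended-minima criterion, large-vessel
#' classification (CSI proximity + median-area rule), and two-stage
#' interpolation of the innermost large-vessel points into a smooth
#' Haller boundary clamped into the band.
#'
#' @param scan a [BScan-class].
#' @param cib,cob choroid band [BoundaryCurve-class] objects; when
#'   \code{NULL} the crude [fallbackChoroidBoundaries()] detector is used
#'   (logged as FALLBACK).
#' @param config a [PipelineConfig-class].
#' @return a [HallerSegmentation-class] holding the boundary and every
#'   intermediate stage.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 11, noiseFree = TRUE))
#' seg <- segmentHaller(ph@scan, ph@cib, ph@cob)
#' mean(abs(curveRows(hallerCurve(seg)) - curveRows(ph@hallerTruth)))
#' @export
segmentHaller <- function(scan, cib = NULL, cob = NULL,
                          config = pipelineConfig()) {
  stopifnot(is(scan, "BScan"))
  pre <- preprocessBScan(scan, config)
  if (is.null(cib) || is.null(cob)) {
    fb <- fallbackChoroidBoundaries(pre@pixels, config)
    cib <- fb$cib; cob <- fb$cob
  }
  enh <- exponentialEnhance(pre@pixels, config@exponent)
  binary <- thresholdBinarize(enh)
  bcl <- restrictToChoroid(binary, cib, cob)
  opened <- morphologicalOpen(bcl@mask, config@openingSe)
  closed <- morphologicalClose(opened, config@closingSe)
  bclClosed <- restrictToChoroid(closed, cib, cob)
  vessels <- watershedSeparate(bclClosed, h = config@hminimaDepth,
                               minVesselPx = config@minVesselPx)
  large <- withCallingHandlers(
    classifyLarge(vessels, cob, config@csiProximityPx),
    warning = function(w) invokeRestart("muffleWarning"))
  haller <- demarcateHaller(large, vessels, cib, cob, config)
  new("HallerSegmentation", haller = haller, large = large,
      vessels = vessels, bcl = bclClosed, binary = binary,
      preprocessed = pre, config = config)
}
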