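# Haller/Sattler boundary demarcation: anchors -> linear interpolation ->
# robust locally weighted regression -> band clamping.

#' Innermost anchor points of the large vessels
#'
#' One anchor per large vessel: the pixel with the minimum row index
#' (innermost, vitreous-side), ties broken by minimum column. The list is
#' sorted by column and duplicate columns are collapsed to the minimum
#' row.
#'
#' @param large a [LargeVesselSet-class].
#' @param vessels the [VesselLabelMap-class] the ids refer to.
#' @return numeric matrix with columns \code{row}, \code{col}; zero rows
#'   when the large set is empty.
#' @export
anchorPoints <- function(large, vessels) {
  stopifnot(is(large, "LargeVesselSet"), is(vessels, "VesselLabelMap"))
  ids <- large@labelIds
  if (length(ids) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  st <- vessels@stats[match(ids, vessels@stats$label), ]
  a <- cbind(row = st$innermost_row, col = st$innermost_col)
  a <- a[order(a[, "col"], a[, "row"]), , drop = FALSE]
  a[!duplicated(a[, "col"]), , drop = FALSE]
}

#' First-stage piecewise-linear boundary estimate
#'
#' Piecewise-linear interpolation through the anchors; columns outside
#' the outermost anchors take the nearest anchor's row (constant
#' extension). A single anchor yields a constant curve.
#'
#' @param anchors matrix with columns \code{row}, \code{col} (>= 1 row).
#' @param width number of image columns to span.
#' @return a [BoundaryCurve-class] of kind \code{"HALLER"}.
#' @export
interpolateLinear <- function(anchors, width) {
  if (!is.matrix(anchors) || nrow(anchors) < 1L)
    stop("need at least one anchor", call. = FALSE)
  rows <- if (nrow(anchors) == 1L) rep(anchors[1L, "row"], width) else
    stats::approx(anchors[, "col"], anchors[, "row"],
                  xout = seq_len(width), rule = 2, ties = min)$y
  boundaryCurve(rows, kind = "HALLER")
}

#' Robust locally weighted boundary smoothing
#'
#' Second-stage smoothing: robust LOWESS (degree-1 local least squares
#' with tricube distance weights and bisquare robustness reweighting,
#' 3 robustness iterations) with a span of \code{windowFrac} of the scan
#' width. Exactly reproduces affine curves. When band curves are given
#' the result is clamped into \code{[cib, cob]} column-wise.
#'
#' @param curve a [BoundaryCurve-class] defined at every column.
#' @param windowFrac span as a fraction of the width, in (0, 1]; the
#'   resulting window must cover at least 3 columns.
#' @param cib,cob optional band curves for clamping.
#' @param iter robustness iterations (default 3).
#' @return smoothed [BoundaryCurve-class], kind preserved.
#' @export
smoothRloess <- function(curve, windowFrac = 1 / 5, cib = NULL, cob = NULL,
                         iter = 3L) {
  stopifnot(is(curve, "BoundaryCurve"))
  w <- curveWidth(curve)
  if (windowFrac <= 0 || windowFrac > 1)
    stop("windowFrac must be in (0, 1]", call. = FALSE)
  if (round(windowFrac * w) < 3)
    stop("smoothing window covers fewer than 3 columns", call. = FALSE)
  sm <- stats::lowess(seq_len(w), curve@rows, f = windowFrac,
                      iter = iter, delta = 0)$y
  if (!is.null(cib)) sm <- pmax(sm, cib@rows)
  if (!is.null(cob)) sm <- pmin(sm, cob@rows)
  boundaryCurve(sm, kind = curve@kind)
}

#' Demarcate Haller's layer boundary
#'
#' Two-stage interpolation through the innermost points of the large
#' vessels: [anchorPoints()] then [interpolateLinear()] then
#' [smoothRloess()], clamped into the choroid band. With no large vessel
#' the boundary degenerates to the COB (zero-thickness Haller layer) and
#' the fallback flag is set.
#'
#' @param large a [LargeVesselSet-class].
#' @param vessels the matching [VesselLabelMap-class].
#' @param cib,cob band [BoundaryCurve-class] objects.
#' @param config a [PipelineConfig-class] (smoothing span).
#' @return a [HallerBoundary-class].
#' @export
demarcateHaller <- function(large, vessels, cib, cob,
                            config = pipelineConfig()) {
  stopifnot(is(cib, "BoundaryCurve"), is(cob, "BoundaryCurve"))
  w <- curveWidth(cob)
  if (curveWidth(cib) != w || ncol(vessels@labels) != w)
    stop("inconsistent widths between curves and label map", call. = FALSE)
  anchors <- anchorPoints(large, vessels)
  if (nrow(anchors) == 0L) {
    warning("no large vessels: Haller boundary falls back to the COB")
    return(new("HallerBoundary",
               curve = boundaryCurve(cob@rows, "HALLER"),
               anchors = anchors, fallbackUsed = TRUE))
  }
  est <- interpolateLinear(anchors, w)
  est <- smoothRloess(est, config@smoothWindowFrac, cib = cib, cob = cob)
  new("HallerBoundary", curve = est, anchors = anchors, fallbackUsed = FALSE)
}

#' Mean Haller layer thickness
#'
#' Column-wise mean of \code{cob - haller}, converted to micrometres.
#'
#' @param haller,cob [BoundaryCurve-class] objects of equal width.
#' @param axialScaleUm axial micrometres per pixel.
#' @return mean thickness in micrometres (non-negative).
#' @export
hallerThicknessUm <- function(haller, cob, axialScaleUm = 2.6) {
  if (curveWidth(haller) != curveWidth(cob))
    stop("width mismatch", call. = FALSE)
  mean(pmax(cob@rows - haller@rows, 0)) * axialScaleUm
}
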