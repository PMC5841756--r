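#' Pipeline configuration constructor
#'
#' Builds a [PipelineConfig-class] with the pipeline defaults: 5x5 Wiener
#' window, 8x8 adaptive-equalization tiling (clip limit 1.2), power-law
#' exponent 2, 5x5 opening and closing elements, extended-minima depth
#' 2 px, 5 px CSI proximity, smoothing span of one fifth of the scan
#' width, and a 2.6 um/px axial scale (overridable; device calibration
#' varies). The clip limit and extended-minima depth were calibrated on
#' synthetic phantoms (see the methods vignette).
#'
#' @param wienerKernel odd Wiener window size (pixels).
#' @param claheTiles tiles per side for adaptive histogram equalization.
#' @param claheClip clip limit (multiple of the uniform histogram level).
#' @param exponent power-law enhancement exponent.
#' @param openingSe square opening structuring-element side (pixels).
#' @param closingSe square closing structuring-element side (pixels).
#' @param hminimaDepth extended-minima depth h (distance-transform pixels).
#' @param minVesselPx minimum vessel component size kept (pixels).
#' @param csiProximityPx CSI adjacency threshold (pixels).
#' @param smoothWindowFrac smoothing span fraction of scan width.
#' @param axialScaleUm axial micrometres per pixel.
#' @param lateralScaleUm lateral micrometres per pixel.
#' @param fallbackDepthPx assumed choroid depth for the fallback detector.
#' @return a validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig(hminimaDepth = 1.5)
#' cfg
#' @export
pipelineConfig <- function(wienerKernel = 5L, claheTiles = 8L, claheClip = 1.2,
                           exponent = 2, openingSe = 5L,
                           closingSe = 5L, hminimaDepth = 2,
                           minVesselPx = 5L, csiProximityPx = 5L,
                           smoothWindowFrac = 1 / 5, axialScaleUm = 2.6,
                           lateralScaleUm = 11.7, fallbackDepthPx = 150L) {
  new("PipelineConfig",
      wienerKernel = as.integer(wienerKernel),
      claheTiles = as.integer(claheTiles), claheClip = claheClip,
      exponent = exponent, openingSe = as.integer(openingSe),
      closingSe = as.integer(closingSe),
      hminimaDepth = hminimaDepth, minVesselPx = as.integer(minVesselPx),
      csiProximityPx = as.integer(csiProximityPx),
      smoothWindowFrac = smoothWindowFrac, axialScaleUm = axialScaleUm,
      lateralScaleUm = lateralScaleUm,
      fallbackDepthPx = as.integer(fallbackDepthPx))
}

#' Boundary curve constructor
#'
#' @param rows numeric vector of 1-based row positions, one per column;
#'   fractional values allowed.
#' @param kind curve kind: \code{"CIB"}, \code{"COB"}, \code{"HALLER"} or
#'   \code{"MANUAL"}.
#' @return a [BoundaryCurve-class].
#' @export
boundaryCurve <- function(rows, kind = "MANUAL") {
  new("BoundaryCurve", rows = as.numeric(rows), kind = kind)
}

#' Read a grayscale OCT B-scan
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF raster and normalizes pixel
#' values to \[0, 1\] (8-bit divided by 255, 16-bit by 65535, as performed
#' by the underlying readers). RGB inputs are converted by the plain
#' channel average; an alpha channel, if present, is ignored.
#'
#' @param path path to a PNG or TIFF file.
#' @param config a [PipelineConfig-class] supplying the pixel scales.
#' @return a [BScan-class].
#' @export
readBScan <- function(path, config = pipelineConfig()) {
  if (!file.exists(path)) stop("cannot read B-scan: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format (need PNG or TIFF): ", path, call. = FALSE))
  if (length(dim(img)) == 3L) {
    nch <- min(dim(img)[3], 3L)            # drop alpha, average color planes
    img <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  if (!is.matrix(img) || length(img) == 0L)
    stop("image has zero area: ", path, call. = FALSE)
  new("BScan", pixels = .clip01(img),
      axialScaleUm = config@axialScaleUm,
      lateralScaleUm = config@lateralScaleUm,
      sourcePath = as.character(path))
}

#' Read a boundary-curve CSV
#'
#' The interchange dialect is a UTF-8 comma-separated file with header
#' \code{column,row}; columns are 0-based, rows are fractional pixels
#' (0-based). Missing columns are filled by linear interpolation between
#' the nearest present columns, and the ends are extended with the nearest
#' present value, so the result always spans the full image width.
#'
#' @param path CSV file path.
#' @param width image width (number of columns) the curve must span.
#' @param kind curve kind recorded on the result.
#' @param nrows optional image height; when given, rows outside
#'   \code{[0, nrows - 1]} (file convention) raise an error.
#' @return a [BoundaryCurve-class] of length \code{width} (1-based rows).
#' @export
readBoundaryCsv <- function(path, width, kind = "MANUAL", nrows = NULL) {
  if (!file.exists(path)) stop("no such boundary file: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(d) == 0L) stop("boundary file is empty: ", path, call. = FALSE)
  if (!all(c("column", "row") %in% names(d)))
    stop("boundary CSV must have a 'column,row' header: ", path, call. = FALSE)
  cols <- d$column + 1                      # 0-based on disk -> 1-based
  rowsv <- d$row + 1
  if (any(cols < 1 | cols > width))
    stop("boundary column index outside image width: ", path, call. = FALSE)
  if (!is.null(nrows) && (any(rowsv < 1) || any(rowsv > nrows)))
    stop("boundary row outside image: ", path, call. = FALSE)
  o <- order(cols)
  cols <- cols[o]; rowsv <- rowsv[o]
  full <- if (length(cols) == 1L) rep(rowsv, width) else
    stats::approx(cols, rowsv, xout = seq_len(width), rule = 2)$y
  boundaryCurve(full, kind = kind)
}

#' Write a boundary-curve CSV
#'
#' Inverse of [readBoundaryCsv()]: writes every column in the 0-based
#' \code{column,row} dialect with enough precision that a round trip
#' reproduces the curve to within 1e-9 per column.
#'
#' @param curve a [BoundaryCurve-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBoundaryCsv <- function(curve, path) {
  stopifnot(is(curve, "BoundaryCurve"))
  lines <- c("column,row",
             sprintf("%d,%.12g", seq_along(curve@rows) - 1L, curve@rows - 1))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write boundary CSV: ", path,
                                    ": ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

# ---- accessors ------------------------------------------------------------

#' @describeIn BScan pixel matrix accessor.
#' @param object,x object to access.
#' @export
setGeneric("scanPixels", function(object) standardGeneric("scanPixels"))

#' @rdname BScan-class
#' @export
setMethod("scanPixels", "BScan", function(object) object@pixels)

#' @describeIn BScan axial scale (um/pixel).
#' @export
setGeneric("axialScale", function(object) standardGeneric("axialScale"))

#' @rdname BScan-class
#' @export
setMethod("axialScale", "BScan", function(object) object@axialScaleUm)

#' @describeIn BoundaryCurve row positions (1-based, fractional).
#' @export
setGeneric("curveRows", function(object) standardGeneric("curveRows"))

#' @rdname BoundaryCurve-class
#' @export
setMethod("curveRows", "BoundaryCurve", function(object) object@rows)

#' @describeIn BoundaryCurve curve kind.
#' @export
setGeneric("curveKind", function(object) standardGeneric("curveKind"))

#' @rdname BoundaryCurve-class
#' @export
setMethod("curveKind", "BoundaryCurve", function(object) object@kind)

#' @describeIn BoundaryCurve number of columns spanned.
#' @export
setGeneric("curveWidth", function(object) standardGeneric("curveWidth"))

#' @rdname BoundaryCurve-class
#' @export
setMethod("curveWidth", "BoundaryCurve", function(object) length(object@rows))

#' @describeIn BinarizedChoroid lumen mask accessor.
#' @export
setGeneric("bclMask", function(object) standardGeneric("bclMask"))

#' @rdname BinarizedChoroid-class
#' @export
setMethod("bclMask", "BinarizedChoroid", function(object) object@mask)

#' @describeIn VesselLabelMap label raster accessor.
#' @export
setGeneric("vesselLabels", function(object) standardGeneric("vesselLabels"))

#' @rdname VesselLabelMap-class
#' @export
setMethod("vesselLabels", "VesselLabelMap", function(object) object@labels)

#' @describeIn VesselLabelMap per-label statistics table.
#' @export
setGeneric("vesselStats", function(object) standardGeneric("vesselStats"))

#' @rdname VesselLabelMap-class
#' @export
setMethod("vesselStats", "VesselLabelMap", function(object) object@stats)

#' @describeIn VesselLabelMap number of labeled vessels.
#' @export
setGeneric("nVessels", function(object) standardGeneric("nVessels"))

#' @rdname VesselLabelMap-class
#' @export
setMethod("nVessels", "VesselLabelMap", function(object) nrow(object@stats))

#' @describeIn LargeVesselSet all large-vessel label ids.
#' @export
setGeneric("largeIds", function(object) standardGeneric("largeIds"))

#' @rdname LargeVesselSet-class
#' @export
setMethod("largeIds", "LargeVesselSet", function(object) object@labelIds)

#' @describeIn HallerBoundary the demarcated curve.
#' @export
setGeneric("hallerCurve", function(object) standardGeneric("hallerCurve"))

#' @rdname HallerBoundary-class
#' @export
setMethod("hallerCurve", "HallerBoundary", function(object) object@curve)

#' @rdname HallerSegmentation-class
#' @export
setMethod("hallerCurve", "HallerSegmentation",
          function(object) object@haller@curve)

# ---- show methods ---------------------------------------------------------

setMethod("show", "BScan", function(object) {
  cat(sprintf("%s: %d x %d px, axial %.3g um/px, source: %s\n",
              class(object), nrow(object@pixels), ncol(object@pixels),
              object@axialScaleUm, object@sourcePath))
})

setMethod("show", "PreprocessedBScan", function(object) {
  callNextMethod()
  cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "BoundaryCurve", function(object) {
  cat(sprintf("BoundaryCurve[%s]: %d columns, rows %.2f..%.2f\n",
              object@kind, length(object@rows),
              min(object@rows), max(object@rows)))
})

setMethod("show", "BinarizedChoroid", function(object) {
  cat(sprintf("BinarizedChoroid: %d x %d px, %d lumen px in band\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

setMethod("show", "VesselLabelMap", function(object) {
  cat(sprintf("VesselLabelMap: %d vessels, %d labeled px\n",
              nrow(object@stats), sum(object@labels > 0L)))
})

setMethod("show", "LargeVesselSet", function(object) {
  cat(sprintf(
    "LargeVesselSet: %d large (%d CSI-adjacent + %d by area > median %.1f px)\n",
    length(object@labelIds), length(object@csiAdjacentIds),
    length(object@areaSelectedIds), object@medianAreaPx))
})

setMethod("show", "HallerBoundary", function(object) {
  cat(sprintf("HallerBoundary: %d anchors%s, rows %.2f..%.2f\n",
              nrow(object@anchors),
              if (object@fallbackUsed) " (FALLBACK: curve = COB)" else "",
              min(object@curve@rows), max(object@curve@rows)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, format(slot(object, s))))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d x %d px, %d vessels (%d large), seed %d%s\n",
    nrow(object@scan@pixels), ncol(object@scan@pixels),
    nrow(object@vesselTruth), sum(object@vesselTruth$stratum == "large"),
    object@spec@seed, if (object@spec@noiseFree) ", noise-free" else ""))
})

setMethod("show", "HallerSegmentation", function(object) {
  cat("HallerSegmentation:\n  ")
  show(object@haller)
  cat("  ")
  show(object@large)
})
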