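# Vessel delineation: morphology, distance/watershed transforms and
# large-vessel classification.

#' Morphological closing with a square structuring element
#'
#' Dilation followed by erosion with an \code{se x se} square. Closing is
#' extensive (output contains the input), fills sub-element gaps and
#' removes tiny background intrusions inside vessels.
#'
#' @param mask logical matrix.
#' @param se square structuring-element side (default 5).
#' @return logical matrix.
#' @export
morphologicalClose <- function(mask, se = 5L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  se <- as.integer(se)
  if (se < 1L) stop("structuring element size must be >= 1", call. = FALSE)
  if (se == 1L) return(mask)
  m <- mask
  storage.mode(m) <- "double"
  out <- EBImage::closing(m, EBImage::makeBrush(se, shape = "box"))
  matrix(as.numeric(out) > 0.5, nrow(mask))
}

#' Morphological opening with a square structuring element
#'
#' Erosion followed by dilation with an \code{se x se} square. Opening is
#' anti-extensive (output within the input) and debrides the mask:
#' isolated speckle residue and thin protrusions that cannot contain the
#' structuring element are removed while vessel cross-sections wider than
#' \code{se} keep their shape. Applied before [morphologicalClose()] in
#' the pipeline so that closing cannot weld residue into vessels.
#'
#' @param mask logical matrix.
#' @param se square structuring-element side (default 5).
#' @return logical matrix, a subset of the input.
#' @export
morphologicalOpen <- function(mask, se = 5L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  se <- as.integer(se)
  if (se < 1L) stop("structuring element size must be >= 1", call. = FALSE)
  if (se == 1L) return(mask)
  m <- mask
  storage.mode(m) <- "double"
  out <- EBImage::opening(m, EBImage::makeBrush(se, shape = "box"))
  matrix(as.numeric(out) > 0.5, nrow(mask))
}

#' Euclidean distance transform
#'
#' For every foreground pixel, the exact Euclidean distance to the
#' nearest background pixel; 0 on background.
#'
#' @param mask logical matrix with at least one background pixel.
#' @return numeric matrix of distances.
#' @export
distanceTransform <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (all(mask))
    stop("all-foreground mask: distance transform undefined", call. = FALSE)
  m <- mask
  storage.mode(m) <- "double"
  matrix(as.numeric(EBImage::distmap(m, metric = "euclidean")), nrow(mask))
}

#' Extended-minima transform
#'
#' Regional minima of the h-minima transform: the minima whose dynamic
#' (depth relative to the lowest ridge connecting them to a deeper
#' minimum) exceeds \code{h}. Shallow minima are suppressed, so the
#' result marks one marker region per significant basin and the marker
#' count is non-increasing in \code{h}. Computed by morphological
#' reconstruction by erosion (8-connected).
#'
#' @param surface numeric matrix (finite values).
#' @param h minimum dynamic, > 0.
#' @return logical matrix marking the marker regions.
#' @export
extendedMinima <- function(surface, h) {
  .assertMatrix(surface)
  if (any(!is.finite(surface))) stop("surface must be finite", call. = FALSE)
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive number", call. = FALSE)
  hmin <- .reconstructErode(surface + h, surface)
  if (diff(range(hmin)) == 0)
    return(matrix(TRUE, nrow(surface), ncol(surface)))  # flat: one marker
  gaps <- diff(sort(unique(as.vector(hmin))))
  delta <- min(gaps[gaps > 0]) / 2
  # raising by less than the smallest value gap fills exactly the regional
  # minima, so the difference is nonzero precisely on them
  (.reconstructErode(hmin + delta, hmin) - hmin) > delta / 2
}

#' Watershed separation of touching vessels
#'
#' Separates touching vessel cross-sections in a binarized choroid layer:
#' the Euclidean distance transform of the lumen mask is used as an
#' (inverted) relief, basins shallower than \code{h} are merged by the
#' extended-minima criterion, and the watershed of the relief splits the
#' mask along ridge lines. Final labels are the 8-connected components of
#' the mask minus the ridges, intersected with the input mask, with
#' components below \code{minVesselPx} pixels discarded as binarization
#' residue. Components touching the lateral image borders are kept.
#'
#' @param bcl a [BinarizedChoroid-class] (typically after
#'   [morphologicalClose()]).
#' @param h extended-minima depth in distance-transform pixels.
#' @param minVesselPx minimum component area kept.
#' @return a [VesselLabelMap-class]; empty mask yields zero vessels.
#' @export
watershedSeparate <- function(bcl, h = 2, minVesselPx = 5L) {
  stopifnot(is(bcl, "BinarizedChoroid"))
  if (length(h) != 1L || h <= 0) stop("h must be > 0", call. = FALSE)
  m <- bcl@mask
  if (!any(m)) {
    return(new("VesselLabelMap",
               labels = matrix(0L, nrow(m), ncol(m)),
               stats = .emptyVesselStats()))
  }
  d <- distanceTransform(m)
  ws <- EBImage::watershed(d, tolerance = h, ext = 1L)
  lab <- matrix(as.integer(ws), nrow(m))
  lab[!m] <- 0L
  # split any watershed region that the mask leaves disconnected: the final
  # id is the (8-component, watershed label) pair
  comp <- .label8(lab > 0L)
  key <- ifelse(lab > 0L, (as.numeric(comp) - 1) * (max(lab) + 1) + lab, 0)
  ids <- sort(unique(key[key > 0]))
  lab2 <- matrix(match(key, ids, nomatch = 0L), nrow(m))
  # discard tiny residue
  areas <- tabulate(lab2[lab2 > 0L])
  keep <- which(areas >= as.integer(minVesselPx))
  lab3 <- matrix(match(lab2, keep, nomatch = 0L), nrow(m))
  new("VesselLabelMap", labels = lab3,
      stats = .vesselStatsFromLabels(lab3, bcl@cob))
}

#' Construct a vessel label map from a label raster
#'
#' Builds a [VesselLabelMap-class] with per-label statistics (area,
#' innermost pixel, vertical COB distance) computed from an integer label
#' raster. Labels must be 0 (background) and consecutive ids 1..n.
#'
#' @param labels integer matrix of labels.
#' @param cob the COB [BoundaryCurve-class] spanning all columns.
#' @return a [VesselLabelMap-class].
#' @export
vesselLabelMap <- function(labels, cob) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  stopifnot(is(cob, "BoundaryCurve"))
  if (curveWidth(cob) != ncol(labels))
    stop("COB width must match the label raster", call. = FALSE)
  new("VesselLabelMap", labels = labels,
      stats = .vesselStatsFromLabels(labels, cob))
}

.emptyVesselStats <- function() {
  data.frame(label = integer(0), area_px = integer(0),
             innermost_row = integer(0), innermost_col = integer(0),
             min_dist_to_cob_px = numeric(0))
}

# Per-label area, innermost pixel (min row, ties by min column) and
# minimum vertical distance to the COB: cob(c) - r for r <= cob(c), 0 below.
.vesselStatsFromLabels <- function(labels, cob) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(.emptyVesselStats())
  nr <- nrow(labels)
  lv <- labels[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  n <- max(lv)
  area <- tabulate(lv, nbins = n)
  o <- order(lv, rr, cc)
  first <- o[!duplicated(lv[o])]
  innR <- innC <- integer(n)
  innR[lv[first]] <- rr[first]
  innC[lv[first]] <- cc[first]
  dv <- pmax(cob@rows[cc] - rr, 0)
  dmin <- rep(Inf, n)
  agg <- vapply(split(dv, lv), min, numeric(1))
  dmin[as.integer(names(agg))] <- agg
  data.frame(label = seq_len(n), area_px = area,
             innermost_row = innR, innermost_col = innC,
             min_dist_to_cob_px = dmin)
}

#' Classify large (Haller) vessels
#'
#' Two-step rule: (1) every vessel lying within \code{proximityPx} pixels
#' (vertical distance) of the choroid-sclera interface belongs to
#' Haller's layer; (2) of the remaining vessels, those with
#' cross-sectional area strictly greater than the median area of the
#' CSI-adjacent set are also labeled large. The result is the union of
#' the two steps. The median over an even count is the mean of the middle
#' pair.
#'
#' @param vessels a [VesselLabelMap-class].
#' @param cob the COB [BoundaryCurve-class] (the CSI).
#' @param proximityPx adjacency threshold in pixels (default 5).
#' @return a [LargeVesselSet-class]; when no vessel is CSI-adjacent, all
#'   sets are empty and a warning is raised (the demarcation stage will
#'   fall back to the COB).
#' @export
classifyLarge <- function(vessels, cob, proximityPx = 5L) {
  stopifnot(is(vessels, "VesselLabelMap"), is(cob, "BoundaryCurve"))
  st <- vessels@stats
  if (nrow(st) > 0L && curveWidth(cob) != ncol(vessels@labels))
    stop("COB width does not match the label map", call. = FALSE)
  # honor the supplied CSI: recompute vertical distances against it
  if (nrow(st) > 0L)
    st$min_dist_to_cob_px <- .vesselStatsFromLabels(vessels@labels,
                                                    cob)$min_dist_to_cob_px
  csi <- st$label[st$min_dist_to_cob_px <= proximityPx]
  if (length(csi) == 0L) {
    warning("no CSI-adjacent vessels; large-vessel set is empty")
    return(new("LargeVesselSet", labelIds = integer(0),
               csiAdjacentIds = integer(0), areaSelectedIds = integer(0),
               medianAreaPx = NA_real_))
  }
  medArea <- stats::median(st$area_px[st$label %in% csi])
  rest <- setdiff(st$label, csi)
  byArea <- rest[st$area_px[match(rest, st$label)] > medArea]
  new("LargeVesselSet",
      labelIds = as.integer(sort(c(csi, byArea))),
      csiAdjacentIds = as.integer(sort(csi)),
      areaSelectedIds = as.integer(sort(byArea)),
      medianAreaPx = as.numeric(medArea))
}

#' Export per-vessel statistics as CSV
#'
#' Writes one row per vessel:
#' \code{label,area_px,innermost_row,innermost_col,min_dist_to_cob_px,is_large}
#' (rows/columns 0-based in the file, matching the boundary CSV dialect).
#'
#' @param vessels a [VesselLabelMap-class].
#' @param large a [LargeVesselSet-class] (or \code{NULL} for all-false).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVesselStatsCsv <- function(vessels, large = NULL, path) {
  st <- vessels@stats
  st$is_large <- if (is.null(large)) FALSE else st$label %in% large@labelIds
  st$innermost_row <- st$innermost_row - 1L
  st$innermost_col <- st$innermost_col - 1L
  utils::write.csv(st, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
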