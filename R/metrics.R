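# Agreement statistics between two Haller boundaries / layers: absolute
# difference, Pearson correlation, Dice coefficient, cohort summaries and
# quotient measures.

#' Manual reference curve
#'
#' Column-wise arithmetic mean of two manual markings; the reference
#' against which the automated boundary is scored.
#'
#' @param m1,m2 [BoundaryCurve-class] objects of equal width.
#' @return a [BoundaryCurve-class] of kind \code{"MANUAL"}.
#' @export
manualReference <- function(m1, m2) {
  if (curveWidth(m1) != curveWidth(m2))
    stop("manual markings differ in width", call. = FALSE)
  boundaryCurve((m1@rows + m2@rows) / 2, kind = "MANUAL")
}

#' Mean absolute boundary difference (micrometres)
#'
#' Mean over columns of \code{|a(c) - b(c)|} scaled by the axial pixel
#' pitch.
#'
#' @param a,b [BoundaryCurve-class] objects of equal width.
#' @param axialScaleUm axial micrometres per pixel.
#' @return mean absolute difference in micrometres.
#' @export
absoluteDifference <- function(a, b, axialScaleUm = 2.6) {
  if (curveWidth(a) != curveWidth(b)) stop("width mismatch", call. = FALSE)
  mean(abs(a@rows - b@rows)) * axialScaleUm
}

#' Pearson correlation of two boundary curves
#'
#' Product-moment correlation between the two row vectors. Undefined for
#' a constant curve: returns \code{NA} with a warning.
#'
#' @param a,b [BoundaryCurve-class] objects of equal width.
#' @return Pearson r in \[-1, 1\], or \code{NA}.
#' @export
boundaryCorrelation <- function(a, b) {
  if (curveWidth(a) != curveWidth(b)) stop("width mismatch", call. = FALSE)
  if (stats::sd(a@rows) == 0 || stats::sd(b@rows) == 0) {
    warning("correlation undefined for a constant curve")
    return(NA_real_)
  }
  stats::cor(a@rows, b@rows)
}

#' Dice coefficient of two Haller layers
#'
#' Rasterizes each Haller layer as the pixel region between its boundary
#' and the COB, \code{\{(r, c): haller(c) <= r <= cob(c)\}} (rows
#' quantized half-up), and returns \code{2|A n B| / (|A| + |B|)}. Two
#' empty regions give 1 with a warning.
#'
#' @param hallerA,hallerB Haller [BoundaryCurve-class] objects.
#' @param cib,cob band curves; \code{cib} is accepted for interface
#'   symmetry and width validation (the layer region does not involve it).
#' @return Dice coefficient in \[0, 1\].
#' @export
diceLayers <- function(hallerA, hallerB, cib, cob) {
  w <- curveWidth(cob)
  if (curveWidth(hallerA) != w || curveWidth(hallerB) != w ||
      curveWidth(cib) != w)
    stop("width mismatch", call. = FALSE)
  ra <- .roundHalfUp(hallerA@rows)
  rb <- .roundHalfUp(hallerB@rows)
  ro <- .roundHalfUp(cob@rows)
  nA <- pmax(ro - ra + 1L, 0L)
  nB <- pmax(ro - rb + 1L, 0L)
  nI <- pmax(ro - pmax(ra, rb) + 1L, 0L)
  if (sum(nA) + sum(nB) == 0L) {
    warning("both layer regions are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(nI) / (sum(nA) + sum(nB))
}

#' Per-scan agreement between two demarcations
#'
#' Convenience wrapper computing the three agreement statistics for one
#' scan: absolute difference (micrometres), Pearson correlation and the
#' Dice coefficient of the layer regions.
#'
#' @param a,b Haller [BoundaryCurve-class] objects.
#' @param cib,cob band curves.
#' @param axialScaleUm axial micrometres per pixel.
#' @return one-row data.frame with columns \code{ad_um}, \code{cc},
#'   \code{dc} (\code{cc}, \code{dc} as fractions).
#' @export
scanAgreement <- function(a, b, cib, cob, axialScaleUm = 2.6) {
  data.frame(ad_um = absoluteDifference(a, b, axialScaleUm),
             cc = boundaryCorrelation(a, b),
             dc = diceLayers(a, b, cib, cob))
}

#' Quotient measures against manual repeatability
#'
#' Compares an automated-vs-reference summary with the intra-observer
#' summary. The quotient of coefficients of variation is
#' \code{cv_auto / cv_manual} for every metric. The quotient of means
#' depends on the metric kind: for error metrics (absolute difference)
#' it is \code{mean_auto / mean_manual}; for similarity metrics
#' (correlation, Dice, expressed as percentages) it is computed on the
#' complement scale, \code{(100 - mean_auto) / (100 - mean_manual)}, so
#' that values near 1 indicate parity with manual grading in both cases.
#'
#' @param auto,manual numeric vectors \code{c(mean, cv)} for the
#'   automated-vs-reference and manual-vs-manual comparisons.
#' @param metricKind \code{"ERROR"} or \code{"SIMILARITY"}.
#' @return named numeric vector \code{c(qm, qcv)}.
#' @export
quotientMeasures <- function(auto, manual, metricKind = c("ERROR", "SIMILARITY")) {
  metricKind <- match.arg(metricKind)
  stopifnot(length(auto) == 2L, length(manual) == 2L)
  if (manual[1] == 0 || manual[2] == 0)
    stop("manual mean and CV must be nonzero", call. = FALSE)
  if (metricKind == "SIMILARITY") {
    if (any(c(auto[1], manual[1]) < 0) || any(c(auto[1], manual[1]) > 100))
      stop("similarity means must be percentages in [0, 100]", call. = FALSE)
    if (manual[1] == 100)
      stop("manual similarity mean of 100 leaves the quotient undefined",
           call. = FALSE)
    qm <- (100 - auto[1]) / (100 - manual[1])
  } else {
    qm <- auto[1] / manual[1]
  }
  c(qm = unname(qm), qcv = unname(auto[2] / manual[2]))
}

#' Cohort-level agreement summary
#'
#' Summarizes per-scan agreement over a cohort for both comparison pairs
#' (automated vs manual reference, and manual vs manual): per metric the
#' mean, sample standard deviation (n - 1), min, max and coefficient of
#' variation, plus the quotient measures. Correlation and Dice are
#' reported as percentages; absolute difference in micrometres.
#'
#' @param autoVsRef,m1VsM2 data.frames with one row per scan and columns
#'   \code{ad_um}, \code{cc}, \code{dc} (fractions), e.g. rows from
#'   [scanAgreement()]; equal, nonzero lengths.
#' @return an object of class \code{CohortSummary}: a list with elements
#'   \code{stats} (data.frame: metric, comparison, mean, sd, min, max,
#'   cv) and \code{quotients} (data.frame: metric, qm, qcv).
#' @export
summarizeCohort <- function(autoVsRef, m1VsM2) {
  for (d in list(autoVsRef, m1VsM2)) {
    if (!is.data.frame(d) || nrow(d) == 0L ||
        !all(c("ad_um", "cc", "dc") %in% names(d)))
      stop("need non-empty data.frames with ad_um, cc, dc", call. = FALSE)
  }
  if (nrow(autoVsRef) != nrow(m1VsM2))
    stop("comparison lists must have equal length", call. = FALSE)
  one <- function(x) {
    s <- if (length(x) > 1L) stats::sd(x) else 0
    m <- mean(x)
    c(mean = m, sd = s, min = min(x), max = max(x),
      cv = if (m == 0) 0 else s / m)
  }
  build <- function(d, tag) {
    vals <- rbind(AD = one(d$ad_um), CC = one(100 * d$cc),
                  DC = one(100 * d$dc))
    data.frame(metric = rownames(vals), comparison = tag, vals,
               row.names = NULL)
  }
  st <- rbind(build(autoVsRef, "P vs M"), build(m1VsM2, "M1 vs M2"))
  q <- lapply(c(AD = "AD", CC = "CC", DC = "DC"), function(met) {
    a <- st[st$metric == met & st$comparison == "P vs M", ]
    m <- st[st$metric == met & st$comparison == "M1 vs M2", ]
    kind <- if (met == "AD") "ERROR" else "SIMILARITY"
    if (m$mean == 0 || m$cv == 0 || (kind == "SIMILARITY" && m$mean == 100))
      return(c(qm = NA_real_, qcv = NA_real_))   # degenerate cohort
    quotientMeasures(c(a$mean, a$cv), c(m$mean, m$cv), kind)
  })
  out <- list(stats = st,
              quotients = data.frame(metric = names(q),
                                     qm = vapply(q, `[`, 0, 1L),
                                     qcv = vapply(q, `[`, 0, 2L),
                                     row.names = NULL))
  class(out) <- "CohortSummary"
  out
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("Cohort agreement summary\n")
  print(x$stats, digits = 4)
  cat("Quotient measures (automated vs manual repeatability)\n")
  print(x$quotients, digits = 4)
  invisible(x)
}

#' Write a cohort summary as CSV/JSON
#'
#' @param summary a \code{CohortSummary} from [summarizeCohort()].
#' @param csvPath,jsonPath output paths (either may be \code{NULL}).
#' @return invisibly, the paths written.
#' @export
writeCohortSummary <- function(summary, csvPath = NULL, jsonPath = NULL) {
  stopifnot(inherits(summary, "CohortSummary"))
  if (!is.null(csvPath))
    utils::write.csv(summary$stats, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(unclass(summary), jsonPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(c(csvPath, jsonPath))
}
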