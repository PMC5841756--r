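# Binarized choroid layer (BCL) extraction: exponential enhancement,
# global thresholding, and restriction to the [CIB, COB] band.

#' Exponential (power-law) enhancement
#'
#' Pointwise power-law mapping \code{v^exponent} followed by rescaling to
#' the full \[0, 1\] range. Exponents above 1 darken vessel lumens
#' relative to the brighter stroma, widening the bimodal intensity gap
#' ahead of thresholding. A constant image is returned unchanged (the
#' rescale is undefined).
#'
#' @param image numeric matrix in \[0, 1\].
#' @param exponent positive power (default 2).
#' @return enhanced matrix in \[0, 1\].
#' @export
exponentialEnhance <- function(image, exponent = 2) {
  .assertMatrix(image)
  if (min(image) < 0 || max(image) > 1)
    stop("image must be in [0, 1]", call. = FALSE)
  if (length(exponent) != 1L || !is.finite(exponent) || exponent <= 0)
    stop("exponent must be a single positive number", call. = FALSE)
  e <- image^exponent
  r <- range(e)
  if (diff(r) == 0) return(image)
  (e - r[1]) / (r[2] - r[1])
}

#' Global Otsu binarization with lumen polarity
#'
#' Thresholds the (enhanced) image at the global Otsu level computed on a
#' 256-level quantization and returns the dark class as \code{TRUE}:
#' vessel lumens are dark in OCT, so the complement step that makes
#' lumens foreground is folded in here. A constant image yields an
#' all-\code{FALSE} mask with a warning.
#'
#' @param image numeric matrix in \[0, 1\].
#' @return logical matrix, \code{TRUE} = below-threshold (lumen).
#' @export
thresholdBinarize <- function(image) {
  .assertMatrix(image)
  if (diff(range(image)) == 0) {
    warning("constant image: degenerate threshold, returning all-stroma mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1), levels = 256L)
  image < thr
}

#' Restrict a binary image to the choroid band
#'
#' Zeroes everything outside the \code{[cib(c), cob(c)]} band at each
#' column and packages the result as a [BinarizedChoroid-class] with
#' lumen-\code{TRUE} polarity. Curves stay fractional; rows are quantized
#' half-up only for indexing.
#'
#' @param binary logical matrix with \code{TRUE} = lumen.
#' @param cib,cob [BoundaryCurve-class] objects spanning all columns,
#'   with \code{cib <= cob} everywhere.
#' @return a [BinarizedChoroid-class].
#' @export
restrictToChoroid <- function(binary, cib, cob) {
  if (!is.matrix(binary) || !is.logical(binary))
    stop("binary must be a logical matrix", call. = FALSE)
  stopifnot(is(cib, "BoundaryCurve"), is(cob, "BoundaryCurve"))
  w <- ncol(binary)
  if (curveWidth(cib) != w || curveWidth(cob) != w)
    stop("boundary curves must span all image columns", call. = FALSE)
  if (any(cib@rows > cob@rows))
    stop("CIB lies below COB at some column", call. = FALSE)
  if (max(cob@rows) > nrow(binary))
    stop("COB extends below the image", call. = FALSE)
  ri <- .roundHalfUp(cib@rows)
  ro <- pmin(.roundHalfUp(cob@rows), nrow(binary))
  rr <- row(binary)
  inband <- !(sweep(rr, 2L, ri, "<") | sweep(rr, 2L, ro, ">"))
  new("BinarizedChoroid", mask = binary & inband, cib = cib, cob = cob)
}

#' Crude fallback choroid boundary detector
#'
#' Plumbing so the pipeline can run without externally supplied CIB/COB
#' curves. Per column, the axially smoothed intensity profile is
#' thresholded at the midpoint of the upper-half intensity spread: the
#' CIB is the first crossing above that level (the dimmer region above
#' the choroid giving way to bright stroma), and the COB is the last row
#' whose profile exceeds the lower-half midpoint (bright stroma giving
#' way to the dimmer sclera). Columns with no crossing take the median of
#' detected columns, or CIB + \code{config@fallbackDepthPx} when nothing
#' is detected; both curves are median-filtered across columns. This is
#' a rough stand-in for a dedicated choroid segmentation method and is
#' logged as FALLBACK.
#'
#' @param image preprocessed numeric matrix in \[0, 1\].
#' @param config a [PipelineConfig-class].
#' @return list with elements \code{cib} and \code{cob}
#'   ([BoundaryCurve-class]).
#' @export
fallbackChoroidBoundaries <- function(image, config = pipelineConfig()) {
  .assertMatrix(image)
  nr <- nrow(image); w <- ncol(image)
  if (diff(range(image)) == 0) {
    warning("FALLBACK boundaries: no intensity evidence, using flat defaults")
    ci <- rep(max(1, nr %/% 4), w)
    co <- pmin(ci + config@fallbackDepthPx, nr - 1)
    return(list(cib = boundaryCurve(ci, "CIB"), cob = boundaryCurve(co, "COB")))
  }
  message("FALLBACK choroid boundaries in use; supply CIB/COB for accuracy")
  # axial smoothing of each column profile
  k <- matrix(1 / 7, 7, 1)
  sm <- EBImage::filter2(image, k, boundary = "replicate")
  half <- nr %/% 2L
  tUp <- mean(stats::quantile(sm[seq_len(half), ], c(0.1, 0.9)))
  tLo <- mean(stats::quantile(sm[(half + 1L):nr, ], c(0.1, 0.9)))
  cibRaw <- cobRaw <- rep(NA_real_, w)
  for (c in seq_len(w)) {
    up <- which(sm[seq_len(half), c] >= tUp)
    if (length(up) > 0L) cibRaw[c] <- up[1]
    lo <- which(sm[, c] >= tLo)
    lo <- lo[lo >= max(cibRaw[c], 1, na.rm = TRUE)]
    if (length(lo) > 0L) cobRaw[c] <- lo[length(lo)]
  }
  fill <- function(x, default) {
    if (all(is.na(x))) return(rep(default, w))
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    x
  }
  cibRaw <- fill(cibRaw, max(1, nr %/% 4))
  cobRaw <- fill(cobRaw, min(nr - 1, max(cibRaw) + config@fallbackDepthPx))
  kk <- min(15L, if (w %% 2L == 0L) w - 1L else w)
  ci <- stats::runmed(cibRaw, kk)
  co <- pmax(stats::runmed(cobRaw, kk), ci)
  list(cib = boundaryCurve(ci, "CIB"), cob = boundaryCurve(co, "COB"))
}
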