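# Speckle denoising and contrast enhancement of the raw B-scan.

#' Adaptive local Wiener denoising
#'
#' Pixel-wise adaptive Wiener filter driven by local statistics in a
#' square window: with local mean m, local variance v and a global noise
#' variance estimate n (the image-wide mean of the local variances),
#' the output is \code{m + max(0, v - n) / max(v, n) * (x - m)}. Flat
#' regions collapse to their mean; edges whose local variance exceeds the
#' noise floor are preserved. Borders are handled by edge replication.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param window odd window size, >= 3 and no larger than either image
#'   dimension.
#' @return denoised matrix, same shape.
#' @export
wienerDenoise <- function(image, window = 5L) {
  .assertMatrix(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (window > nrow(image) || window > ncol(image))
    stop("window larger than image", call. = FALSE)
  box <- matrix(1 / window^2, window, window)
  mu <- EBImage::filter2(image, box, boundary = "replicate")
  mu2 <- EBImage::filter2(image^2, box, boundary = "replicate")
  v <- pmax(mu2 - mu^2, 0)
  noise <- mean(v)
  denom <- pmax(v, noise)
  gain <- ifelse(denom > 0, pmax(v - noise, 0) / denom, 0)
  mu + gain * (image - mu)
}

#' Tiled adaptive histogram equalization
#'
#' Contrast-limited adaptive histogram equalization over a square tile
#' grid with bilinear interpolation between tile mappings (backed by
#' \code{EBImage::clahe}). The clip limit is expressed as a multiple of
#' the uniform histogram bin height. A constant image is returned
#' unchanged with a warning (degenerate histogram).
#'
#' @param image numeric matrix in \[0, 1\]; both dimensions must be at
#'   least \code{tiles}.
#' @param tiles tile count per side (default 8, i.e. an 8x8 grid).
#' @param clip clip limit (> 0).
#' @return equalized matrix in \[0, 1\], same shape.
#' @export
adaptiveHistEq <- function(image, tiles = 8L, clip = 2) {
  .assertMatrix(image)
  tiles <- as.integer(tiles)
  if (nrow(image) < tiles || ncol(image) < tiles)
    stop("image smaller than the tile grid", call. = FALSE)
  if (diff(range(image)) == 0) {
    warning("constant image: adaptive equalization is a no-op")
    return(image)
  }
  out <- EBImage::clahe(image, nx = tiles, ny = tiles, limit = clip)
  .clip01(matrix(as.numeric(out), nrow(image)))
}

#' Preprocess a B-scan
#'
#' Applies Wiener denoising then adaptive histogram equalization with the
#' configured parameters, recording provenance.
#'
#' @param scan a [BScan-class].
#' @param config a [PipelineConfig-class].
#' @return a [PreprocessedBScan-class].
#' @export
preprocessBScan <- function(scan, config = pipelineConfig()) {
  stopifnot(is(scan, "BScan"))
  den <- wienerDenoise(scan@pixels, config@wienerKernel)
  eq <- adaptiveHistEq(den, config@claheTiles, config@claheClip)
  new("PreprocessedBScan",
      pixels = .clip01(eq),
      axialScaleUm = scan@axialScaleUm,
      lateralScaleUm = scan@lateralScaleUm,
      sourcePath = scan@sourcePath,
      provenance = c(
        sprintf("wiener(window=%d)", config@wienerKernel),
        sprintf("clahe(tiles=%dx%d, clip=%g)",
                config@claheTiles, config@claheTiles, config@claheClip)))
}
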