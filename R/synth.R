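# Synthetic choroid phantom generator: a stromal band between smooth
# random boundaries, elliptical vessel lumens in three anatomical strata,
# multiplicative gamma speckle, and full ground truth.

#' Phantom specification constructor
#'
#' Defaults emulate a central macular swept-source B-scan: a 512 x 256
#' raster, CIB around 40 px depth, a ~150 px thick choroid, bright stroma
#' (0.65) with dark lumens (0.15), caliber increasing toward the COB
#' (choriocapillaris 1-3 px, Sattler 5-10 px, Haller 12-20 px semi-axes,
#' the Haller vessels stamped with their outer edge hugging the COB), and
#' 4-look multiplicative gamma speckle.
#'
#' @param width,height phantom size in pixels.
#' @param cibDepth mean CIB depth (pixels).
#' @param choroidThickness mean band thickness (pixels).
#' @param nLarge,nMedium,nSmall vessel counts per stratum.
#' @param largeRadius,mediumRadius,smallRadius semi-axis ranges (pixels).
#' @param stromaLevel,lumenLevel noise-free intensities.
#' @param speckleLooks gamma speckle shape L.
#' @param noiseFree disable speckle.
#' @param seed RNG seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(width = 512L, height = 256L, cibDepth = 40,
                        choroidThickness = 150, nLarge = 4L, nMedium = 8L,
                        nSmall = 30L, largeRadius = c(12, 20),
                        mediumRadius = c(5, 10), smallRadius = c(1, 3),
                        stromaLevel = 0.65, lumenLevel = 0.15,
                        speckleLooks = 4, noiseFree = FALSE, seed = 1L) {
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      cibDepth = cibDepth, choroidThickness = choroidThickness,
      nLarge = as.integer(nLarge), nMedium = as.integer(nMedium),
      nSmall = as.integer(nSmall), largeRadius = largeRadius,
      mediumRadius = mediumRadius, smallRadius = smallRadius,
      stromaLevel = stromaLevel, lumenLevel = lumenLevel,
      speckleLooks = speckleLooks, noiseFree = noiseFree,
      seed = as.integer(seed))
}

# smooth low-frequency perturbation over w columns
.lowFreqCurve <- function(w) {
  a <- stats::runif(2, c(3, 1), c(7, 4))
  p <- stats::runif(2, 0, 2 * pi)
  x <- seq_len(w)
  a[1] * sin(2 * pi * x / w + p[1]) + a[2] * sin(4 * pi * x / w + p[2])
}

# pixel set of an axis-aligned ellipse, clipped to the image
.ellipsePixels <- function(r0, c0, rRow, rCol, nr, nc) {
  rs <- max(1L, floor(r0 - rRow)):min(nr, ceiling(r0 + rRow))
  cs <- max(1L, floor(c0 - rCol)):min(nc, ceiling(c0 + rCol))
  g <- expand.grid(r = rs, c = cs)
  keep <- ((g$r - r0) / rRow)^2 + ((g$c - c0) / rCol)^2 <= 1
  g[keep, , drop = FALSE]
}

#' Generate a synthetic choroid phantom
#'
#' Deterministic given the spec's seed: draws smooth random CIB/COB
#' curves, stamps non-overlapping elliptical lumens stratum by stratum
#' (small near the CIB, medium mid-band, large adjoining the COB — the
#' outermost vessels are the largest), renders the piecewise-constant
#' scene, applies multiplicative gamma speckle (mean 1, shape
#' \code{speckleLooks}) and clips to \[0, 1\]. The ground-truth Haller
#' boundary is built by the same two-stage interpolation the pipeline
#' uses, applied to the true innermost points of the large vessels, so
#' recovery error isolates segmentation quality from curve-construction
#' convention.
#'
#' Vessels are placed with at least a 6 px gap between ellipse bounding
#' circles so the pipeline's 5x5 closing cannot merge planted vessels;
#' large vessels keep their outer edge within about 0.5-2.5 px of the
#' COB, which makes them CSI-adjacent under the 5 px rule by
#' construction.
#'
#' @param spec a [PhantomSpec-class].
#' @param config a [PipelineConfig-class]; supplies the pixel scales and
#'   the smoothing span used for the truth boundary.
#' @return a [PhantomTruth-class].
#' @export
generatePhantom <- function(spec = phantomSpec(),
                            config = pipelineConfig()) {
  stopifnot(is(spec, "PhantomSpec"))
  .withSeed(spec@seed, {
    nr <- spec@height; nc <- spec@width
    cib <- spec@cibDepth + .lowFreqCurve(nc)
    cob <- cib + spec@choroidThickness + .lowFreqCurve(nc)
    cib <- pmin(pmax(cib, 6), nr - 10)
    cob <- pmin(pmax(cob, cib + 20), nr - 6)

    placed <- data.frame(center_row = numeric(0), center_col = numeric(0),
                         radius_row = numeric(0), radius_col = numeric(0),
                         stratum = character(0))
    lumen <- matrix(FALSE, nr, nc)
    cibI <- .roundHalfUp(cib); cobI <- .roundHalfUp(cob)

    place <- function(n, rng, stratum) {
      for (i in seq_len(n)) {
        done <- FALSE
        for (att in seq_len(1000L)) {
          rRow <- stats::runif(1, rng[1], rng[2])
          rCol <- stats::runif(1, rng[1], rng[2])
          rmax <- max(rRow, rCol)
          c0 <- stats::runif(1, 1 + rmax + 2, nc - rmax - 2)
          ci <- cib[.roundHalfUp(c0)]; co <- cob[.roundHalfUp(c0)]
          r0 <- switch(stratum,
            large = co - stats::runif(1, 0.5, 2.5) - rRow,
            medium = ci + stats::runif(1, 0.35, 0.65) * (co - ci),
            small = ci + stats::runif(1, 0.08, 0.30) * (co - ci))
          # clearance from every placed vessel: closing must not merge them
          if (nrow(placed) > 0L) {
            dd <- sqrt((placed$center_row - r0)^2 + (placed$center_col - c0)^2)
            if (any(dd <= pmax(placed$radius_row, placed$radius_col) + rmax + 6))
              next
          }
          px <- .ellipsePixels(r0, c0, rRow, rCol, nr, nc)
          if (nrow(px) == 0L) next
          # fully inside the band
          if (any(px$r < cibI[px$c] + 1L) || any(px$r > cobI[px$c])) next
          # large vessels must actually touch the CSI neighborhood
          if (stratum == "large" && min(cob[px$c] - px$r) > 4) next
          lumen[cbind(px$r, px$c)] <<- TRUE
          placed[nrow(placed) + 1L, ] <<- list(r0, c0, rRow, rCol, stratum)
          done <- TRUE
          break
        }
        if (!done)
          stop("could not place all ", stratum, " vessels without overlap; ",
               "reduce the counts or enlarge the phantom", call. = FALSE)
      }
    }
    place(spec@nLarge, spec@largeRadius, "large")
    place(spec@nMedium, spec@mediumRadius, "medium")
    place(spec@nSmall, spec@smallRadius, "small")

    # piecewise-constant scene: retina proxy above, stroma band, sclera below
    rr <- row(lumen)
    inband <- !(sweep(rr, 2L, cibI, "<") | sweep(rr, 2L, cobI, ">"))
    clean <- matrix(0.45, nr, nc)
    clean[inband] <- spec@stromaLevel
    clean[sweep(rr, 2L, cobI, ">")] <- 0.08
    clean[lumen] <- spec@lumenLevel

    field <- if (spec@noiseFree) matrix(1, nr, nc) else
      matrix(stats::rgamma(nr * nc, shape = spec@speckleLooks,
                           rate = spec@speckleLooks), nr, nc)

    truthCurve <- .hallerTruthFromLumen(placed, lumen, cib, cob, nc, config)

    new("PhantomTruth",
        scan = new("BScan", pixels = .clip01(clean * field),
                   axialScaleUm = config@axialScaleUm,
                   lateralScaleUm = config@lateralScaleUm,
                   sourcePath = sprintf("phantom(seed=%d)", spec@seed)),
        cleanPixels = clean, speckleField = field,
        cib = boundaryCurve(cib, "CIB"), cob = boundaryCurve(cob, "COB"),
        hallerTruth = truthCurve, lumenMask = lumen,
        vesselTruth = placed, spec = spec)
  })
}

# truth boundary: same two-stage interpolation as the pipeline, applied to
# the true innermost pixel of each planted large vessel
.hallerTruthFromLumen <- function(placed, lumen, cib, cob, width, config) {
  lg <- placed[placed$stratum == "large", , drop = FALSE]
  if (nrow(lg) == 0L)
    return(boundaryCurve(cob, "HALLER"))
  anch <- t(vapply(seq_len(nrow(lg)), function(i) {
    px <- .ellipsePixels(lg$center_row[i], lg$center_col[i],
                         lg$radius_row[i], lg$radius_col[i],
                         nrow(lumen), ncol(lumen))
    top <- px[px$r == min(px$r), , drop = FALSE]
    c(row = min(top$r), col = min(top$c[top$r == min(top$r)]))
  }, numeric(2)))
  anch <- anch[order(anch[, "col"]), , drop = FALSE]
  anch <- anch[!duplicated(anch[, "col"]), , drop = FALSE]
  est <- interpolateLinear(anch, width)
  smoothRloess(est, config@smoothWindowFrac,
               cib = boundaryCurve(cib, "CIB"),
               cob = boundaryCurve(cob, "COB"))
}

#' Degrade phantom contrast
#'
#' Compresses the lumen/stroma intensity separation by
#' \code{contrastDrop} on the noise-free render (both levels move toward
#' their midpoint), then re-applies the phantom's stored speckle field.
#' Ground truths are unchanged; a drop of 0 returns the phantom
#' bit-identical. Models the low luminal/stromal contrast of
#' non-averaged acquisitions.
#'
#' @param phantom a [PhantomTruth-class].
#' @param contrastDrop in \[0, 1).
#' @return a degraded [PhantomTruth-class].
#' @export
degradePhantom <- function(phantom, contrastDrop) {
  stopifnot(is(phantom, "PhantomTruth"))
  if (contrastDrop < 0 || contrastDrop >= 1)
    stop("contrastDrop must be in [0, 1)", call. = FALSE)
  if (contrastDrop == 0) return(phantom)
  spec <- phantom@spec
  mid <- (spec@stromaLevel + spec@lumenLevel) / 2
  clean <- phantom@cleanPixels
  band <- clean == spec@stromaLevel | clean == spec@lumenLevel
  clean[band] <- mid + (clean[band] - mid) * (1 - contrastDrop)
  out <- phantom
  out@cleanPixels <- clean
  out@scan@pixels <- .clip01(clean * phantom@speckleField)
  out
}
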