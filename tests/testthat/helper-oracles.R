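# Independent brute-force oracles. These deliberately use naive explicit
# loops / exhaustive search so they share no code path with the package.

# Exhaustive Otsu: minimize intra-class variance over the 256-bin
# quantization on [0, 1]; returns the objective and one minimizing mask
# (the minimizer can be a plateau when the histogram has empty gaps, so
# comparisons are on the objective and the induced partition).
oracleOtsu <- function(img) {
  br <- seq(0, 1, length.out = 257)
  h <- hist(img, breaks = br, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  wcvAt <- function(k) {     # threshold between bin k and k+1
    w0 <- sum(counts[1:k]); w1 <- sum(counts[(k + 1):256])
    if (w0 == 0 || w1 == 0) return(Inf)
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v0 <- sum(counts[1:k] * (mids[1:k] - m0)^2) / w0
    v1 <- sum(counts[(k + 1):256] * (mids[(k + 1):256] - m1)^2) / w1
    (w0 * v0 + w1 * v1) / (w0 + w1)
  }
  obj <- vapply(1:255, wcvAt, numeric(1))
  k <- which.min(obj)
  list(threshold = br[k + 1], objective = obj[k],
       wcvOf = function(thr) {
         k2 <- findInterval(thr, br, rightmost.closed = TRUE)
         k2 <- min(max(k2, 1L), 255L)
         wcvAt(k2)
       },
       mask = img < br[k + 1])
}

# Exhaustive Euclidean distance transform.
oracleDistance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c])
      out[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  out
}

# Closing by explicit neighborhood loops. Dilation: TRUE if any input
# pixel in the window; erosion: TRUE if every in-image window pixel TRUE
# (out-of-image treated as foreground, matching border-preserving
# closing).
oracleClose <- function(mask, se = 5L) {
  nr <- nrow(mask); nc <- ncol(mask)
  r2 <- se %/% 2L
  dil <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- mask[max(1, r - r2):min(nr, r + r2),
                max(1, c - r2):min(nc, c + r2)]
    dil[r, c] <- any(win)
  }
  ero <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- dil[max(1, r - r2):min(nr, r + r2),
               max(1, c - r2):min(nc, c + r2)]
    ero[r, c] <- all(win)
  }
  ero
}

# Naive morphological reconstruction by erosion (explicit pixel loops)
# and h-minima markers from it; independent of the package's vectorized
# reconstruction.
oracleReconstructErode <- function(marker, mask) {
  nr <- nrow(marker); nc <- ncol(marker)
  rec <- marker
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      nb <- rec[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      v <- max(mask[r, c], min(nb))
      if (v != rec[r, c]) { rec[r, c] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  rec
}

oracleExtendedMinima <- function(surface, h) {
  hmin <- oracleReconstructErode(surface + h, surface)
  if (diff(range(hmin)) == 0) return(matrix(TRUE, nrow(surface), ncol(surface)))
  gaps <- diff(sort(unique(as.vector(hmin))))
  delta <- min(gaps[gaps > 0]) / 2
  (oracleReconstructErode(hmin + delta, hmin) - hmin) > delta / 2
}

# 8-connected labeling by breadth-first flooding (loops).
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Brute-force flooding watershed on a distance relief: markers are the
# h-maxima plateaus of the distance map (= extended minima of the
# negated relief); remaining foreground pixels are flooded in order of
# decreasing distance, taking the label of an already-labeled
# 8-neighbor; pixels first reached from two labels become ridge.
# Returns the final 8-connected labeling of mask minus ridges.
oracleFloodWatershed <- function(mask, h) {
  d <- oracleDistance(mask)
  markers <- oracleExtendedMinima(-d, h) & mask
  lab <- oracleLabel8(markers)
  ord <- order(-d[mask])
  px <- which(mask)
  px <- px[ord]
  nr <- nrow(mask)
  repeat {
    changed <- FALSE
    for (p in px) {
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      if (lab[r, c] != 0L) next
      nb <- lab[max(1, r - 1):min(nr, r + 1),
                max(1, c - 1):min(ncol(mask), c + 1)]
      ids <- unique(nb[nb > 0L])
      if (length(ids) == 1L) { lab[r, c] <- ids; changed <- TRUE }
      else if (length(ids) > 1L) { lab[r, c] <- -1L; changed <- TRUE }
    }
    if (!changed) break
  }
  ridge <- lab == -1L
  oracleLabel8(mask & !ridge & lab != 0L)
}

# Reference robust LOWESS mirroring the classical algorithm: degree-1
# weighted fits over the ns nearest neighbors (contiguous window chosen
# by sliding toward the nearer side), tricube distance weights, bisquare
# robustness with c = 6 * median |residual|.
refLowess <- function(x, y, f, iter = 3L) {
  n <- length(x)
  ns <- max(2L, min(n, as.integer(f * n + 1e-7)))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iter) {
    for (i in seq_len(n)) {
      l <- 1L
      while (l + ns - 1L < n &&
             x[i] - x[l] > x[l + ns] - x[i]) l <- l + 1L
      idx <- l:(l + ns - 1L)
      d <- abs(x[idx] - x[i])
      hmax <- max(d)
      w <- if (hmax > 0) (1 - pmin(d / hmax, 1)^3)^3 else rep(1, length(idx))
      w <- w * rw[idx]
      if (sum(w) <= 0) { fit[i] <- y[i]; next }
      xw <- sum(w * x[idx]) / sum(w)
      yw <- sum(w * y[idx]) / sum(w)
      sxx <- sum(w * (x[idx] - xw)^2)
      b <- if (sxx > 0) sum(w * (x[idx] - xw) * (y[idx] - yw)) / sxx else 0
      fit[i] <- yw + b * (x[i] - xw)
    }
    if (it < iter) {
      res <- y - fit
      cmad <- 6 * stats::median(abs(res))
      rw <- if (cmad <= 0) rep(1, n) else (1 - pmin(abs(res) / cmad, 1)^2)^2
    }
  }
  fit
}

# Brute-force Dice on explicit rasterized layer regions.
oracleDice <- function(hallerA, hallerB, cob, nrows) {
  w <- length(cob)
  mk <- function(hh) {
    m <- matrix(FALSE, nrows, w)
    for (c in seq_len(w)) {
      a <- floor(hh[c] + 0.5); b <- floor(cob[c] + 0.5)
      if (a <= b) m[a:b, c] <- TRUE
    }
    m
  }
  A <- mk(hallerA); B <- mk(hallerB)
  if (sum(A) + sum(B) == 0) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}
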