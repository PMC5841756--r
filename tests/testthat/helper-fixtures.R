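# Small fixture builders used across tests.

diskMask <- function(nr, nc, centers, radii) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radii[i]^2)
        m[r, c] <- TRUE
    }
  }
  m
}

rectLabels <- function(nr, nc, rects) {
  # rects: list of c(r1, r2, c1, c2); labels assigned in order
  L <- matrix(0L, nr, nc)
  for (i in seq_along(rects)) {
    rc <- rects[[i]]
    L[rc[1]:rc[2], rc[3]:rc[4]] <- i
  }
  L
}

flatCurve <- function(row, width, kind = "MANUAL") {
  boundaryCurve(rep(row, width), kind = kind)
}

writeGrayPng <- function(m, path = tempfile(fileext = ".png")) {
  png::writePNG(m, path)
  path
}

smallConfig <- function(...) pipelineConfig(...)

# one cached speckled phantom for tests that only inspect it
.cachedPhantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generatePhantom(phantomSpec(seed = 5L))
    ph
  }
})
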