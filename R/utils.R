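# Internal helpers shared across modules.

# Round-half-up to integer rows; boundary curves stay fractional and are
# only quantized at mask-indexing time.
.roundHalfUp <- function(x) as.integer(floor(x + 0.5))

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed))
  expr
}

.assertMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (anyNA(x)) stop(name, " contains NA", call. = FALSE)
  invisible(x)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so
# diagonal-adjacent 4-labels are merged by union-find over the (few)
# diagonal label contacts.
.label8 <- function(mask) {
  storage.mode(mask) <- "double"
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask))
  n <- max(L)
  if (n <= 1L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]    # down-right contacts
  a2 <- L[-nr, -1]; b2 <- L[-1, -nc]    # down-left contacts
  pick <- function(a, b) {
    s <- a > 0L & b > 0L & a != b
    cbind(a[s], b[s])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- dense[L[L > 0L]]
  out
}

# Minimum over the 8-neighborhood (excluding nothing; includes self),
# treating outside-image as +Inf.
.erodeMin8 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- x
  out <- x
  for (dr in -1:1) for (dc in -1:1) {
    out <- pmin(out, p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  }
  out
}

# Morphological reconstruction by erosion of marker over mask
# (marker >= mask pointwise); iterates rec <- max(mask, erode(rec)) to a
# fixed point. 8-connected.
.reconstructErode <- function(marker, mask) {
  if (any(marker < mask)) stop("marker must dominate mask", call. = FALSE)
  rec <- marker
  repeat {
    nxt <- pmax(mask, .erodeMin8(rec))
    if (all(nxt == rec)) break
    rec <- nxt
  }
  rec
}
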