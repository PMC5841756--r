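# Morphology, distance transform, extended minima, watershed separation
# and the large-vessel rule.

test_that("closing matches the explicit dilation/erosion oracle", {
  set.seed(7)
  for (i in 1:6) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    expect_identical(morphologicalClose(m, 5), oracleClose(m, 5))
  }
})

test_that("closing is extensive, merges sub-element gaps, keeps fixed points", {
  # solid rectangle >= SE is a fixed point
  solid <- matrix(FALSE, 20, 20); solid[5:12, 6:14] <- TRUE
  expect_identical(morphologicalClose(solid, 5), solid)

  # two 10x10 squares separated by a 2-px gap merge into one component
  two <- matrix(FALSE, 30, 40)
  two[10:19, 5:14] <- TRUE
  two[10:19, 17:26] <- TRUE
  merged <- morphologicalClose(two, 5)
  expect_identical(max(oracleLabel8(merged)), 1L)

  # single isolated pixel survives (extensivity)
  single <- matrix(FALSE, 15, 15); single[8, 8] <- TRUE
  expect_identical(morphologicalClose(single, 5), single)

  set.seed(8)
  for (i in 1:5) {
    m <- matrix(runif(225) < 0.4, 15, 15)
    expect_true(all(morphologicalClose(m, 5) >= m))
  }
})

test_that("opening is anti-extensive and debrides speckle residue", {
  m <- matrix(FALSE, 30, 30)
  m[10:20, 10:20] <- TRUE     # solid block survives
  m[3, 3] <- TRUE             # isolated speck vanishes
  m[25, 5:6] <- TRUE          # thin residue vanishes
  o <- morphologicalOpen(m, 5)
  expect_true(all(m[10:20, 10:20] == o[10:20, 10:20]))
  expect_false(o[3, 3])
  expect_false(any(o[25, 5:6]))
  set.seed(12)
  for (i in 1:5) {
    r <- matrix(runif(400) < 0.4, 20, 20)
    expect_true(all(morphologicalOpen(r, 5) <= r))
  }
})

test_that("distance transform is exact Euclidean distance to background", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(distanceTransform(single)[3, 3], 1)

  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  expect_equal(distanceTransform(sq)[5, 5], 3)

  disk <- diskMask(25, 25, cbind(13, 13), 10)
  expect_lt(abs(max(distanceTransform(disk)) - 10), 0.8)

  set.seed(13)
  for (i in 1:4) {
    m <- matrix(runif(30 * 30) < 0.6, 30, 30)
    m[1, 1] <- FALSE
    expect_equal(distanceTransform(m), oracleDistance(m), tolerance = 1e-9)
  }
  expect_error(distanceTransform(matrix(TRUE, 4, 4)), "all-foreground")
})

test_that("extended minima merge shallow basins and honor the depth h", {
  # 1D profile: two basins of depth 5 separated by a ridge of height 2
  prof <- c(5, 0, 1, 2, 2, 2, 1, 0, 5)
  surf <- matrix(rep(prof, 3), 3, length(prof), byrow = TRUE)

  m3 <- extendedMinima(surf, 3)
  expect_identical(m3, oracleExtendedMinima(surf, 3))
  expect_identical(max(oracleLabel8(m3)), 1L)   # merged into one marker

  m1 <- extendedMinima(surf, 1)
  expect_identical(m1, oracleExtendedMinima(surf, 1))
  expect_identical(max(oracleLabel8(m1)), 2L)   # two separate markers

  expect_true(all(extendedMinima(matrix(2, 4, 6), 1)))  # flat: one marker
  expect_error(extendedMinima(surf, 0), "positive")
})

test_that("extended-minima marker count is non-increasing in h", {
  set.seed(17)
  for (i in 1:3) {
    base <- matrix(runif(8 * 8), 8, 8)
    # smooth it slightly so plateaus are rare but structure remains
    surf <- wienerDenoise(rbind(base, base)[1:8, ], 3)
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(h) {
      max(oracleLabel8(extendedMinima(surf, h)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("watershed separation labels disjoint and touching vessels correctly", {
  w <- 64; nr <- 40
  cob <- flatCurve(38, w, "COB")
  band <- function(m) new("BinarizedChoroid", mask = m,
                          cib = flatCurve(2, w, "CIB"), cob = cob)

  # two disjoint disks: two labels with exact areas
  m <- diskMask(nr, w, rbind(c(20, 16), c(20, 48)), c(6, 6))
  v <- watershedSeparate(band(m), h = 2)
  expect_identical(nVessels(v), 2L)
  expect_setequal(vesselStats(v)$area_px, sum(diskMask(nr, w, cbind(20, 16), 6)))

  # overlapping disks split near the neck; centers keep distinct labels
  m2 <- diskMask(nr, w, rbind(c(20, 24), c(20, 36)), c(8, 8))
  v2 <- watershedSeparate(band(m2), h = 2)
  expect_identical(nVessels(v2), 2L)
  L <- vesselLabels(v2)
  expect_true(L[20, 24] != L[20, 36] && all(L[cbind(20, c(24, 36))] > 0))
  orc <- oracleFloodWatershed(m2, 2)
  expect_identical(max(orc), 2L)
  expect_true(orc[20, 24] != orc[20, 36])

  # h above the distance maximum: a single disk is never split
  m3 <- diskMask(nr, w, cbind(20, 32), 8)
  v3 <- watershedSeparate(band(m3), h = 20)
  expect_identical(nVessels(v3), 1L)
  expect_identical(max(oracleFloodWatershed(m3, 20)), 1L)

  # empty mask
  v0 <- watershedSeparate(band(matrix(FALSE, nr, w)), h = 2)
  expect_identical(nVessels(v0), 0L)
})

test_that("labeled pixels stay inside the mask and components are connected", {
  set.seed(19)
  for (i in 1:3) {
    w <- 48; nr <- 40
    m <- diskMask(nr, w,
                  cbind(sample(10:30, 4), sample(8:40, 4)),
                  sample(3:6, 4, replace = TRUE))
    bcl <- new("BinarizedChoroid", mask = m,
               cib = flatCurve(2, w, "CIB"), cob = flatCurve(38, w, "COB"))
    v <- watershedSeparate(bcl, h = 2, minVesselPx = 1)
    L <- vesselLabels(v)
    expect_true(all(L[!m] == 0L))                   # AND contract
    for (id in seq_len(nVessels(v)))                # 8-connectivity
      expect_identical(max(oracleLabel8(L == id)), 1L)
    expect_identical(sum(vesselStats(v)$area_px), sum(L > 0L))
  }
})

test_that("large-vessel rule reproduces the worked cases exactly", {
  # CSI-adjacent areas {10, 20, 30}; elsewhere {25, 15}:
  # median 20, large set = CSI ids + the area-25 vessel
  w <- 80
  cobRow <- 45
  L <- rectLabels(50, w, list(
    c(42, 43, 2, 6),      # area 10, dist 2  (CSI)
    c(40, 43, 10, 14),    # area 20, dist 2  (CSI)
    c(39, 43, 20, 25),    # area 30, dist 2  (CSI)
    c(10, 14, 30, 34),    # area 25, dist 31 (selected: 25 > 20)
    c(10, 12, 40, 44)     # area 15, dist 33 (excluded)
  ))
  v <- vesselLabelMap(L, flatCurve(cobRow, w, "COB"))
  lg <- classifyLarge(v, flatCurve(cobRow, w, "COB"), proximityPx = 5)
  expect_setequal(largeIds(lg), 1:4)
  expect_setequal(lg@csiAdjacentIds, 1:3)
  expect_identical(lg@areaSelectedIds, 4L)
  expect_identical(lg@medianAreaPx, 20)

  # all CSI-adjacent: the area rule is vacuous
  L2 <- rectLabels(50, w, list(c(42, 43, 2, 6), c(40, 43, 10, 14)))
  v2 <- vesselLabelMap(L2, flatCurve(cobRow, w, "COB"))
  lg2 <- classifyLarge(v2, flatCurve(cobRow, w, "COB"))
  expect_setequal(largeIds(lg2), 1:2)
  expect_length(lg2@areaSelectedIds, 0L)
})

test_that("even-count median uses the middle-pair mean and strict inequality", {
  w <- 60
  cobRow <- 45
  L <- rectLabels(50, w, list(
    c(42, 43, 2, 5),      # area 8,  CSI
    c(41, 43, 10, 13),    # area 12, CSI
    c(10, 14, 20, 21)     # area 10, far: 10 > 10 is FALSE -> excluded
  ))
  v <- vesselLabelMap(L, flatCurve(cobRow, w, "COB"))
  lg <- classifyLarge(v, flatCurve(cobRow, w, "COB"))
  expect_identical(lg@medianAreaPx, 10)
  expect_setequal(largeIds(lg), 1:2)

  # no CSI-adjacent vessel: empty result with a warning
  L3 <- rectLabels(50, w, list(c(10, 12, 8, 12)))
  v3 <- vesselLabelMap(L3, flatCurve(cobRow, w, "COB"))
  expect_warning(lg3 <- classifyLarge(v3, flatCurve(cobRow, w, "COB")),
                 "no CSI-adjacent")
  expect_length(largeIds(lg3), 0L)
  expect_true(is.na(lg3@medianAreaPx))
})

test_that("classification is invariant to label renumbering and translation", {
  w <- 80
  rects <- list(c(42, 43, 2, 6), c(40, 43, 10, 14), c(10, 14, 30, 34))
  L <- rectLabels(50, w, rects)
  cob <- flatCurve(45, w, "COB")
  base <- classifyLarge(vesselLabelMap(L, cob), cob)

  # renumber labels 1,2,3 -> 3,1,2
  Lp <- matrix(0L, 50, w)
  Lp[L == 1L] <- 3L; Lp[L == 2L] <- 1L; Lp[L == 3L] <- 2L
  perm <- classifyLarge(vesselLabelMap(Lp, cob), cob)
  areas <- function(v, lg) sort(vesselStats(v)$area_px[largeIds(lg)])
  expect_identical(areas(vesselLabelMap(Lp, cob), perm),
                   areas(vesselLabelMap(L, cob), base))

  # translate the whole scene 10 columns right
  Lt <- matrix(0L, 50, w)
  Lt[, 11:w] <- L[, 1:(w - 10)]
  shifted <- classifyLarge(vesselLabelMap(Lt, cob), cob)
  expect_identical(length(largeIds(shifted)), length(largeIds(base)))
  expect_identical(areas(vesselLabelMap(Lt, cob), shifted),
                   areas(vesselLabelMap(L, cob), base))
})
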