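# Agreement statistics: absolute difference, correlation, Dice, cohort
# summaries and quotient measures.

test_that("manual reference is the column-wise mean of the markings", {
  m1 <- boundaryCurve(c(100, 110, 120))
  m2 <- boundaryCurve(c(120, 110, 100))
  ref <- manualReference(m1, m2)
  expect_equal(curveRows(ref), c(110, 110, 110))
  expect_equal(curveRows(manualReference(m1, m1)), curveRows(m1))
  # equidistant from both everywhere
  expect_equal(abs(curveRows(ref) - curveRows(m1)),
               abs(curveRows(ref) - curveRows(m2)))
  expect_error(manualReference(m1, boundaryCurve(1:4)), "width")
})

test_that("absolute difference scales to micrometres and is a metric", {
  a <- boundaryCurve(c(10, 20, 30))
  b <- boundaryCurve(c(12, 18, 33))
  expect_equal(absoluteDifference(a, a, 2.6), 0)
  expect_equal(absoluteDifference(a, boundaryCurve(c(14, 24, 34)), 2.6), 10.4)
  expect_equal(absoluteDifference(a, b, 1), mean(c(2, 2, 3)))
  # symmetry and triangle inequality on toy triples
  cc <- boundaryCurve(c(11, 25, 28))
  expect_equal(absoluteDifference(a, b, 1), absoluteDifference(b, a, 1))
  expect_lte(absoluteDifference(a, b, 1),
             absoluteDifference(a, cc, 1) + absoluteDifference(cc, b, 1))
})

test_that("boundary correlation behaves like Pearson r", {
  a <- boundaryCurve(c(1, 2, 3, 4))
  expect_equal(boundaryCorrelation(a, boundaryCurve(c(1, 2, 3, 4) + 7)), 1)
  expect_equal(boundaryCorrelation(a, boundaryCurve(10 - c(1, 2, 3, 4))), -1)
  # frozen from the covariance formula: r = 6.5 / sqrt(5 * 8.75)
  expect_equal(boundaryCorrelation(a, boundaryCurve(c(1, 2, 3, 5))),
               6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  # invariant to positive affine rescaling
  expect_equal(boundaryCorrelation(boundaryCurve(2 * c(1, 2, 3, 5) + 3), a),
               boundaryCorrelation(boundaryCurve(c(1, 2, 3, 5)), a))
  expect_warning(r <- boundaryCorrelation(a, boundaryCurve(rep(2, 4))),
                 "constant")
  expect_true(is.na(r))
})

test_that("Dice of layer regions matches the set formula", {
  w <- 2
  cob <- flatCurve(10, w, "COB"); cib <- flatCurve(1, w, "CIB")
  expect_equal(diceLayers(flatCurve(7, w), flatCurve(7, w), cib, cob), 1)
  # |A| = 4, |B| = 4, |A n B| = 2
  hA <- boundaryCurve(c(9, 9)); hB <- boundaryCurve(c(7, 11))
  expect_equal(diceLayers(hA, hB, cib, cob), 0.5)
  # A empty, B non-empty -> 0
  expect_equal(diceLayers(boundaryCurve(c(11, 11)), flatCurve(7, w), cib, cob), 0)
  # both empty -> 1 with warning
  expect_warning(
    d <- diceLayers(boundaryCurve(c(11, 11)), boundaryCurve(c(12, 12)),
                    cib, cob), "empty")
  expect_equal(d, 1)
})

test_that("Dice is symmetric, bounded, and equals the raster oracle", {
  set.seed(41)
  for (i in 1:5) {
    w <- 12
    cob <- 20 + runif(w, 0, 3)
    hA <- cob - runif(w, 0, 8)
    hB <- cob - runif(w, 0, 8)
    a <- boundaryCurve(hA); b <- boundaryCurve(hB)
    cibC <- flatCurve(1, w, "CIB"); cobC <- boundaryCurve(cob, "COB")
    d1 <- diceLayers(a, b, cibC, cobC)
    expect_equal(d1, diceLayers(b, a, cibC, cobC))
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(d1, oracleDice(hA, hB, cob, 30))
  }
})

test_that("scanAgreement packages the three statistics consistently", {
  w <- 50
  cib <- flatCurve(5, w, "CIB"); cob <- flatCurve(40, w, "COB")
  a <- boundaryCurve(30 + 3 * sin(seq_len(w) / 5), "HALLER")
  b <- boundaryCurve(curveRows(a) + 2, "HALLER")
  sa <- scanAgreement(a, b, cib, cob, axialScaleUm = 2.6)
  expect_equal(sa$ad_um, 2 * 2.6)
  expect_equal(sa$cc, 1)
  expect_lt(sa$dc, 1)
  expect_gt(sa$dc, 0.5)
})

test_that("cohort summary computes sample statistics and quotients", {
  mk <- function(ad, cc, dc) data.frame(ad_um = ad, cc = cc, dc = dc)
  auto <- mk(c(10, 20), c(0.97, 0.99), c(0.88, 0.92))
  man <- mk(c(12, 24), c(0.96, 0.98), c(0.86, 0.94))
  s <- summarizeCohort(auto, man)
  adRow <- s$stats[s$stats$metric == "AD" & s$stats$comparison == "P vs M", ]
  expect_equal(adRow$mean, 15)
  expect_equal(adRow$sd, sd(c(10, 20)))
  expect_equal(adRow$cv, sd(c(10, 20)) / 15)
  expect_equal(adRow$min, 10); expect_equal(adRow$max, 20)
  qAD <- s$quotients[s$quotients$metric == "AD", ]
  expect_equal(qAD$qm, 15 / 18)
  ccA <- s$stats[s$stats$metric == "CC" & s$stats$comparison == "P vs M", ]
  expect_equal(ccA$mean, 98)  # reported as percent
  qCC <- s$quotients[s$quotients$metric == "CC", ]
  expect_equal(qCC$qm, (100 - 98) / (100 - 97))

  # single-scan cohort: SD = 0, CV = 0, quotients degenerate
  s1 <- summarizeCohort(mk(5, 0.9, 0.9), mk(6, 0.91, 0.89))
  expect_true(all(s1$stats$sd == 0))
  expect_true(all(s1$stats$cv == 0))
  expect_true(all(is.na(s1$quotients$qm)))

  # identical lists: all defined quotients are 1
  s2 <- summarizeCohort(auto, auto)
  expect_true(all(abs(na.omit(unlist(s2$quotients[, c("qm", "qcv")])) - 1)
                  < 1e-12))
  expect_error(summarizeCohort(auto, mk(1, 0.5, 0.5)), "equal length")
})

test_that("quotient measures use the complement scale for similarity metrics", {
  q <- quotientMeasures(c(17.54, 0.9379), c(19.19, 0.9218), "ERROR")
  expect_equal(unname(q["qm"]), 17.54 / 19.19, tolerance = 1e-12)
  expect_equal(unname(q["qcv"]), 0.9379 / 0.9218, tolerance = 1e-12)

  qcc <- quotientMeasures(c(98.10, 0.0163), c(98.59, 0.0114), "SIMILARITY")
  expect_equal(unname(qcc["qm"]), (100 - 98.10) / (100 - 98.59),
               tolerance = 1e-12)

  same <- quotientMeasures(c(90, 0.05), c(90, 0.05), "SIMILARITY")
  expect_equal(unname(same), c(1, 1))

  expect_error(quotientMeasures(c(1, 1), c(0, 1), "ERROR"), "nonzero")
  expect_error(quotientMeasures(c(120, 1), c(90, 1), "SIMILARITY"),
               "percentages")
})
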