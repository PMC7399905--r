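test_that("an empty significance mask yields no areas", {
  lat <- coarseLattice(); n <- nPoints(lat)
  dev <- plantedDeviation(matrix(0, n, n), matrix(FALSE, n, n), lat)
  ar <- detectSignificantAreas(dev)
  expect_equal(nrow(areaInfo(ar)), 0L)
  expect_true(all(areaLabels(ar) == 0L))
  expect_equal(nrow(measureFractions(ar, dev, buildEtdrsMasks(lat))), 0L)
})

test_that("disjoint planted blobs become distinct components with exact membership", {
  lat <- coarseLattice(); n <- nPoints(lat)
  co <- latticeCoords(lat)
  blob1 <- sqrt((co$x - 1)^2 + (co$y - 1)^2) < 0.4
  blob2 <- sqrt((co$x + 1.5)^2 + (co$y + 0.5)^2) < 0.3
  d <- matrix(0, n, n); d[blob1] <- -10; d[blob2] <- -8
  dev <- plantedDeviation(d, blob1 | blob2, lat)
  ar <- detectSignificantAreas(dev)
  expect_equal(nrow(areaInfo(ar)), 2L)
  labs <- areaLabels(ar)
  ids1 <- unique(labs[blob1]); ids2 <- unique(labs[blob2])
  expect_length(ids1, 1L); expect_length(ids2, 1L)
  expect_false(ids1 == ids2)
  expect_identical(unname(labs > 0L), unname(blob1 | blob2))
})

test_that("an annular band is one 8-connected component spanning all inner quadrants", {
  lat <- macularLattice(); n <- nPoints(lat)
  em <- buildEtdrsMasks(lat)
  co <- latticeCoords(lat)
  band <- co$r >= 0.5 & co$r < 1.5
  d <- matrix(0, n, n); d[band] <- -12
  dev <- plantedDeviation(d, band, lat)
  ar <- detectSignificantAreas(dev)
  expect_equal(nrow(areaInfo(ar)), 1L)
  expect_equal(areaInfo(ar)$sign, -1L)
  for (q in c("nasal", "superior", "temporal", "inferior"))
    expect_true(any(areaLabels(ar) > 0 & cellMask(em, paste0("IMR_", q))))
  # 4-connectivity is also available and cannot merge diagonal-only contact
  diagMask <- matrix(FALSE, n, n)
  diagMask[cbind(10:12, 10:12)] <- TRUE
  d2 <- matrix(0, n, n); d2[diagMask] <- -5
  dev2 <- plantedDeviation(d2, diagMask, lat)
  expect_equal(nrow(areaInfo(detectSignificantAreas(dev2, 8))), 1L)
  expect_equal(nrow(areaInfo(detectSignificantAreas(dev2, 4))), 3L)
})

test_that("touching thinning and thickening regions split by deviation sign", {
  lat <- coarseLattice(); n <- nPoints(lat)
  d <- matrix(0, n, n)
  d[20:30, 20:25] <- -10
  d[20:30, 26:31] <- +10
  sig <- d != 0
  ar <- detectSignificantAreas(plantedDeviation(d, sig, lat))
  expect_equal(nrow(areaInfo(ar)), 2L)
  expect_setequal(areaInfo(ar)$sign, c(-1L, 1L))
})

test_that("fraction measurement recovers a planted partial-cell defect", {
  lat <- macularLattice()
  em <- buildEtdrsMasks(lat)
  les <- lesionSpec("disk", -10, targetCell = "IMR_inferior",
                    targetCoveragePct = 30)
  lf <- lesionField(les, lat, em)
  n <- nPoints(lat)
  dev <- plantedDeviation(lf$field, lf$mask, lat)
  ar <- detectSignificantAreas(dev)
  fr <- measureFractions(ar, dev, em, coverageThresholdPct = 10)
  row <- fr[fr$cell == "IMR_inferior", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$MD_um, -10, tolerance = 1e-9)
  expect_lt(abs(row$coverage_pct - 30), 1)
  expect_true(row$passed_threshold)
  expect_equal(row$sign, -1L)
  # partition conservation: fraction point counts sum to all significant
  # points inside the 6 mm disk
  co <- latticeCoords(lat)
  expect_equal(sum(fr$n_points), sum(lf$mask & co$r < 3))
})

test_that("sub-threshold fractions are reported but not passed; threshold is monotone", {
  lat <- macularLattice()
  em <- buildEtdrsMasks(lat)
  mk <- function(pct) {
    lf <- lesionField(lesionSpec("disk", -10, targetCell = "OMR_nasal",
                                 targetCoveragePct = pct), lat, em)
    dev <- plantedDeviation(lf$field, lf$mask, lat)
    list(dev = dev, ar = detectSignificantAreas(dev))
  }
  low <- mk(5); high <- mk(15)
  frLow <- measureFractions(low$ar, low$dev, em, 10)
  frHigh <- measureFractions(high$ar, high$dev, em, 10)
  expect_false(frLow$passed_threshold[frLow$cell == "OMR_nasal"])
  expect_true(frHigh$passed_threshold[frHigh$cell == "OMR_nasal"])
  # raising the threshold never increases the number of passed fractions
  passed <- vapply(c(1, 5, 10, 20, 40, 80, 100), function(thr)
    sum(measureFractions(high$ar, high$dev, em, thr)$passed_threshold),
    numeric(1))
  expect_true(all(diff(passed) <= 0))
  expect_error(measureFractions(high$ar, high$dev, em, 0), "0, 100")
  expect_error(measureFractions(high$ar, high$dev, em, 101), "0, 100")
})

test_that("a full-coverage uniform lesion makes MA and GA agree exactly", {
  lat <- coarseLattice()
  em <- buildEtdrsMasks(lat)
  n <- nPoints(lat)
  lesion <- cellMask(em, "IMR_nasal") * (-15)
  ctrl <- matrixStack(lapply(1:3, function(i) matrix(300, n, n)), "c", lat)
  pat <- matrixStack(lapply(1:3, function(i) matrix(300, n, n) + lesion),
                     "p", lat)
  ref <- fitReference(ctrl)
  dev <- attachSignificance(deviationField(pat, ref),
                            pointwiseTTest(pat, ctrl))
  fr <- measureFractions(detectSignificantAreas(dev), dev, em)
  grid <- gridTable(gaDeviationGrid(pat, ctrl, em))
  maMD <- fr$MD_um[fr$cell == "IMR_nasal"]
  gaDev <- grid$deviation_um[grid$cell == "IMR_nasal"]
  expect_equal(fr$coverage_pct[fr$cell == "IMR_nasal"], 100)
  expect_lt(abs(maMD - gaDev), 1e-9)
})

test_that("ROI measurement pools defects across cells and matches fractions", {
  lat <- macularLattice()
  em <- buildEtdrsMasks(lat)
  co <- latticeCoords(lat)
  n <- nPoints(lat)
  # planted cluster spanning superior and temporal outer quadrants
  cluster <- (cellMask(em, "OMR_superior") | cellMask(em, "OMR_temporal")) &
    sqrt((co$x + 1.2)^2 + (co$y - 1.8)^2) < 0.8
  d <- matrix(0, n, n); d[cluster] <- -11
  dev <- plantedDeviation(d, cluster, lat)

  roi <- sqrt((co$x + 1.2)^2 + (co$y - 1.8)^2) < 1.2
  res <- measureRoi(roi, dev, em)
  expect_equal(res$MD_um, -11, tolerance = 1e-9)
  expect_equal(res$n_points, sum(cluster))
  expect_setequal(res$cells$cell, c("OMR_superior", "OMR_temporal"))

  # an ROI equal to one full significant cell-fraction reproduces it
  ar <- detectSignificantAreas(dev)
  fr <- measureFractions(ar, dev, em, 1)
  roiCell <- cluster & cellMask(em, "OMR_superior")
  resCell <- measureRoi(roiCell, dev, em)
  frRow <- fr[fr$cell == "OMR_superior", ]
  expect_equal(resCell$MD_um, frRow$MD_um, tolerance = 1e-12)
  expect_equal(resCell$n_points, frRow$n_points)

  # ROI over all significant points = point-weighted mean of fraction MDs
  resAll <- measureRoi(matrix(TRUE, n, n), dev, em)
  expect_equal(resAll$MD_um,
               sum(fr$MD_um * fr$n_points) / sum(fr$n_points),
               tolerance = 1e-12)

  # disjoint ROI -> empty defect with warning; empty ROI -> error
  far <- sqrt((co$x - 2)^2 + (co$y + 2)^2) < 0.3
  expect_warning(resEmpty <- measureRoi(far, dev, em), "no significant")
  expect_equal(resEmpty$n_points, 0L)
  expect_error(measureRoi(matrix(FALSE, n, n), dev), "empty")
})

test_that("subject-level SE is available and finite on cohort-backed results", {
  lat <- coarseLattice()
  em <- buildEtdrsMasks(lat)
  prof <- layerProfile("GCL")
  ctrl <- generateCohort(prof, cohortConfig(10, seed = 5), lat, "control",
                         em)
  les <- lesionSpec("annulus", -12, radiiMm = c(0.5, 1.5))
  pat <- generateCohort(prof, cohortConfig(8, seed = 6,
                                           lesions = list(les)),
                        lat, "pat", em)
  ref <- fitReference(ctrl$stack)
  dev <- attachSignificance(deviationField(pat$stack, ref),
                            pointwiseTTest(pat$stack, ctrl$stack))
  ar <- detectSignificantAreas(dev)
  frP <- measureFractions(ar, dev, em, se = "points")
  frS <- measureFractions(ar, dev, em, se = "subjects",
                          group = pat$stack, controls = ctrl$stack)
  expect_identical(frP$MD_um, frS$MD_um)
  expect_true(all(is.finite(frS$SE_um)))
  # subject-level SE reflects cohort size, not point count
  expect_true(all(frS$SE_um[frS$n_points > 50] >
                    frP$SE_um[frP$n_points > 50]))
})
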