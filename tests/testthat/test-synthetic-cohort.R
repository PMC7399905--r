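test_that("zero SDs and no lesions reproduce the profile exactly", {
  lat <- coarseLattice()
  prof <- layerProfile("TR")
  gen <- generateCohort(prof, cohortConfig(3, betweenSdUm = 0,
                                           noiseSdUm = 0, seed = 1),
                        lat, "g")
  b <- profileField(prof, lat)
  for (i in 1:3) expect_equal(gen$stack@data[, , i], b, tolerance = 1e-12)
  expect_equal(gen$base, b)
})

test_that("generation is bit-reproducible per seed and restores the RNG state", {
  lat <- coarseLattice()
  prof <- layerProfile("GCL")
  cfg <- cohortConfig(4, seed = 99,
                      lesions = list(lesionSpec("scattered", -8,
                                                cell = "OMR_temporal",
                                                nClusters = 3,
                                                clusterRadiusMm = 0.2)))
  set.seed(123); before <- rnorm(3)
  set.seed(123)
  g1 <- generateCohort(prof, cfg, lat, "g")
  after <- rnorm(3)
  expect_identical(before, after)          # caller RNG untouched
  g2 <- generateCohort(prof, cfg, lat, "g")
  expect_identical(g1$stack@data, g2$stack@data)
  expect_identical(g1$lesionMask, g2$lesionMask)
  gOther <- generateCohort(prof, cohortConfig(4, seed = 100,
                                              lesions = cfg@lesions),
                           lat, "g")
  expect_false(identical(g1$stack@data, gOther$stack@data))
})

test_that("the mean field equals profile plus lesions in the zero-noise limit", {
  lat <- coarseLattice()
  em <- buildEtdrsMasks(lat)
  prof <- layerProfile("IPL")
  les <- lesionSpec("wedge", -9, radiiMm = c(1.5, 3), quadrant = "nasal")
  gen <- generateCohort(prof, cohortConfig(3, betweenSdUm = 0, noiseSdUm = 0,
                                           lesions = list(les), seed = 2),
                        lat, "g", em)
  expect_equal(gen$stack@data[, , 1],
               profileField(prof, lat) + gen$lesionFields[[1]]$field,
               tolerance = 1e-12)
  # wedge support: nasal OMR quadrant only
  expect_true(all(gen$lesionMask[cellMask(em, "OMR_nasal")]))
  expect_false(any(gen$lesionMask & !cellMask(em, "OMR_nasal")))
})

test_that("lesion geometry matches its specification", {
  lat <- macularLattice()
  em <- buildEtdrsMasks(lat)
  co <- latticeCoords(lat)
  # zero amplitude -> zero field
  z <- lesionField(lesionSpec("disk", 0, centerMm = c(0, 0), radiusMm = 1),
                   lat, em)
  expect_true(all(z$field == 0) && !any(z$mask))
  # hard-edged annulus over the inner ring = exactly the IMR masks' union
  a <- lesionField(lesionSpec("annulus", -12, radiiMm = c(0.5, 1.5)),
                   lat, em)
  imr <- cellMask(em, "IMR_nasal") | cellMask(em, "IMR_superior") |
    cellMask(em, "IMR_temporal") | cellMask(em, "IMR_inferior")
  expect_identical(unname(a$mask), unname(imr))
  expect_true(all(a$field[a$mask] == -12))
  # soft edge: amplitude in the core, intermediate in the rolloff band
  s <- lesionField(lesionSpec("disk", -10, edgeSoftnessMm = 0.3,
                              centerMm = c(1, 1), radiusMm = 0.8), lat, em)
  d <- sqrt((co$x - 1)^2 + (co$y - 1)^2)
  expect_true(all(s$field[d < 0.45] == -10))
  band <- d > 0.55 & d < 0.75
  expect_true(all(s$field[band] > -10 & s$field[band] < 0))
  # coverage targeting hits the requested fraction
  t30 <- lesionField(lesionSpec("disk", -10, targetCell = "IMR_nasal",
                                targetCoveragePct = 30), lat, em)
  cov <- 100 * sum(t30$mask & cellMask(em, "IMR_nasal")) /
    cellCounts(em)[["IMR_nasal"]]
  expect_lt(abs(cov - 30), 1)
  expect_error(lesionField(lesionSpec("disk", -10, targetCell = "FC",
                                      targetCoveragePct = 150), lat, em),
               "unreachable")
})

test_that("correlated noise hits the target point-wise SD and correlation", {
  lat <- coarseLattice()
  set.seed(31)
  fields <- replicate(80, correlatedNoiseField(lat, 2.5, 0.25))
  n <- nPoints(lat); ctr <- (n + 1L) %/% 2L
  # interior point-wise SD across replicates
  centerVals <- fields[ctr, ctr, ]
  expect_lt(abs(sd(centerVals) - 2.5), 0.5)
  # neighbouring points correlate strongly, far points do not
  nb <- cor(fields[ctr, ctr, ], fields[ctr, ctr + 1L, ])
  far <- cor(fields[ctr, ctr, ], fields[ctr, ctr + 20L, ])
  expect_gt(nb, 0.5)
  expect_lt(abs(far), 0.3)
})

test_that("between-subject SD of cell means converges to the configured value", {
  lat <- coarseLattice()
  em <- buildEtdrsMasks(lat)
  # pool three independent cohorts: the single-cohort estimate of a SD from
  # 200 subjects still carries ~5% sampling error, the pooled one ~3%
  sds <- sapply(41:43, function(seed) {
    gen <- generateCohort(layerProfile("TR"),
                          cohortConfig(200, betweenSdUm = 4,
                                       noiseSdUm = 0.5,
                                       corrLengthMm = 0.25, seed = seed),
                          lat, "g")
    apply(subjectCellMeans(gen$stack, em), 1L, sd)
  })
  pooled <- sqrt(rowMeans(sds^2))
  expect_true(all(abs(pooled - 4) / 4 < 0.1))
})

test_that("the pipeline recovers a planted annulus from realistic cohorts", {
  lat <- macularLattice()
  em <- buildEtdrsMasks(lat)
  prof <- layerProfile("GCL")
  les <- lesionSpec("annulus", -12, radiiMm = c(0.5, 1.5))
  ctrl <- generateCohort(prof, cohortConfig(40, seed = 51), lat, "control")
  pat <- generateCohort(prof, cohortConfig(33, seed = 52,
                                           lesions = list(les)),
                        lat, "T2DM", em)
  ref <- fitReference(ctrl$stack)
  dev <- attachSignificance(deviationField(pat$stack, ref),
                            pointwiseTTest(pat$stack, ctrl$stack))
  ar <- detectSignificantAreas(dev)
  # best-matching component vs ground truth
  jac <- vapply(areaInfo(ar)$id, function(id) {
    comp <- areaLabels(ar) == id
    sum(comp & pat$lesionMask) / sum(comp | pat$lesionMask)
  }, numeric(1))
  expect_gt(max(jac), 0.8)
  fr <- measureFractions(ar, dev, em)
  imrRows <- fr$cell %in% c("IMR_nasal", "IMR_superior", "IMR_temporal",
                            "IMR_inferior") & fr$sign == -1
  expect_true(all(fr$passed_threshold[imrRows]))
  md <- sum(fr$MD_um[imrRows] * fr$n_points[imrRows]) /
    sum(fr$n_points[imrRows])
  se <- sqrt(4^2 + 2.5^2) * sqrt(1 / 40 + 1 / 33)
  expect_lt(abs(md - (-12)), 3 * se)
})
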