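simulateSmallStudy <- function(dir, seed = 7, threeGroups = FALSE) {
  groups <- list(
    list(label = "control", layer = "GCL", n_subjects = 10),
    list(label = "T2DM", layer = "GCL", n_subjects = 8,
         lesions = list(list(shape = "annulus", amplitude_um = -12,
                             radii_mm = c(0.5, 1.5)))))
  if (threeGroups) {
    groups[[3]] <- list(label = "DN_pos", layer = "GCL", n_subjects = 7,
                        lesions = list(list(shape = "wedge",
                                            amplitude_um = -15,
                                            radii_mm = c(0.5, 1.5),
                                            quadrant = "nasal")))
  }
  simulateCohorts(list(seed = seed, output_dir = dir,
                       lattice = list(extent_mm = 6, spacing_mm = 0.1),
                       groups = groups))
}

test_that("simulate writes loadable cohorts with ground truth", {
  dir <- withr::local_tempdir()
  manifest <- simulateSmallStudy(dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 18L)
  expect_true(file.exists(file.path(dir, "truth_T2DM_GCL.txt")))
  stacks <- loadCohorts(readManifest(file.path(dir, "manifest.csv")))
  expect_equal(nSubjects(stacks$control), 10L)
  expect_equal(nSubjects(stacks$T2DM), 8L)
})

test_that("the analysis run produces the full report bundle deterministically", {
  dir <- withr::local_tempdir()
  simulateSmallStudy(dir)
  out1 <- file.path(dir, "out1")
  cfg <- list(manifest = file.path(dir, "manifest.csv"),
              control_group = "control", compare_groups = "T2DM",
              output_dir = out1, render = FALSE)
  res <- runAnalysis(cfg)
  expect_named(res, "GCL")
  cmpLab <- "T2DM vs control"
  expect_named(res$GCL, cmpLab)
  stem <- file.path(out1, "GCL-T2DM_vs_control")
  for (suffix in c("-deviation.txt", "-pvalues.txt", "-areas.txt",
                   "-fractions.csv", "-grid.csv", "-ga-vs-ma.csv",
                   "-summary.json"))
    expect_true(file.exists(paste0(stem, suffix)))
  expect_true(file.exists(file.path(out1, "run-log.json")))
  log <- jsonlite::read_json(file.path(out1, "run-log.json"))
  expect_equal(log$alpha, 0.05)
  expect_equal(log$coverage_threshold_pct, 10)
  expect_equal(log$method, "t")

  # rerun into a second directory: bit-identical CSV/JSON outputs
  out2 <- file.path(dir, "out2")
  cfg$output_dir <- out2
  runAnalysis(cfg)
  for (suffix in c("-fractions.csv", "-grid.csv", "-ga-vs-ma.csv",
                   "-summary.json")) {
    expect_identical(
      readLines(paste0(stem, suffix)),
      readLines(paste0(file.path(out2, "GCL-T2DM_vs_control"), suffix)))
  }
})

test_that("self-comparison yields an all-null report", {
  dir <- withr::local_tempdir()
  manifest <- simulateSmallStudy(dir)
  # list the same control maps under a second label: a literal
  # self-comparison
  m <- readManifest(file.path(dir, "manifest.csv"))
  m <- m[m$group == "control", ]
  sham <- m; sham$group <- "sham"
  writeManifest(rbind(m, sham), file.path(dir, "self.csv"))
  out <- file.path(dir, "self-out")
  res <- runAnalysis(list(manifest = file.path(dir, "self.csv"),
                          control_group = "control",
                          compare_groups = "sham", output_dir = out,
                          render = FALSE))
  r <- res$GCL[["sham vs control"]]
  expect_lt(max(abs(deviation(r$deviation))), 1e-10)
  expect_lt(max(abs(colorIndex(r$deviation))), 1e-8)  # all-white map
  expect_false(any(sigMask(r$significance)))
  expect_equal(nrow(r$fractions), 0L)
  expect_false(any(gridTable(r$grid)$significant))
})

test_that("a three-group Tukey design reports every pairwise comparison", {
  dir <- withr::local_tempdir()
  simulateSmallStudy(dir, threeGroups = TRUE)
  out <- file.path(dir, "tukey-out")
  res <- runAnalysis(list(manifest = file.path(dir, "manifest.csv"),
                          control_group = "control",
                          compare_groups = c("T2DM", "DN_pos"),
                          method = "tukey", output_dir = out,
                          render = FALSE))
  expect_setequal(names(res$GCL),
                  c("control vs T2DM", "control vs DN_pos",
                    "T2DM vs DN_pos"))
})

test_that("rendered figures are written when requested", {
  dir <- withr::local_tempdir()
  simulateSmallStudy(dir)
  out <- file.path(dir, "fig-out")
  runAnalysis(list(manifest = file.path(dir, "manifest.csv"),
                   control_group = "control", compare_groups = "T2DM",
                   output_dir = out, render = TRUE))
  stem <- file.path(out, "GCL-T2DM_vs_control")
  for (suffix in c("-devm.png", "-grid.png", "-md-se.png")) {
    expect_true(file.exists(paste0(stem, suffix)))
    expect_gt(file.size(paste0(stem, suffix)), 1000)
  }
})

test_that("configuration errors are descriptive", {
  expect_error(analysisConfig(list()), "manifest")
  expect_error(analysisConfig(list(manifest = "m.csv")), "control_group")
  expect_error(analysisConfig(list(manifest = "m.csv",
                                   control_group = "c")), "compare_groups")
  expect_error(analysisConfig(list(manifest = "m.csv", control_group = "c",
                                   compare_groups = "p", alpha = 2)),
               "alpha")
  dir <- withr::local_tempdir()
  simulateSmallStudy(dir)
  expect_error(runAnalysis(list(manifest = file.path(dir, "manifest.csv"),
                                control_group = "control",
                                compare_groups = "missing_group",
                                output_dir = file.path(dir, "x"))),
               "missing")
})
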