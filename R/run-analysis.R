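#' Normalize an analysis configuration
#'
#' Accepts a YAML file path or a plain list and fills defaults. Fields:
#' \code{manifest} (path to the cohort manifest CSV), \code{control_group}
#' (label of the reference group), \code{compare_groups} (labels compared
#' against the controls; with \code{method = "tukey"} all of them share one
#' error term and the subgroup pair is tested too), \code{method} ("t" or
#' "tukey"), \code{alpha} (default 0.05), \code{coverage_threshold_pct}
#' (default 10), \code{connectivity} (8 or 4), \code{output_dir},
#' \code{render} (write PNGs, default TRUE), \code{seed}.
#'
#' @param config list or YAML path.
#' @return Normalized config list.
#' @export
analysisConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(method = "t", alpha = 0.05, coverage_threshold_pct = 10,
                   connectivity = 8L, render = TRUE, seed = 1L,
                   output_dir = "macuMap-out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$manifest)) stop("config needs a 'manifest' path")
  if (is.null(config$control_group)) stop("config needs 'control_group'")
  if (is.null(config$compare_groups)) stop("config needs 'compare_groups'")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0,1)")
  config
}

.peekLayer <- function(path) {
  l <- readLines(path, n = 2L)[2L]
  sub("^layer=", "", l)
}

#' Run the full deviation-map and grid analysis
#'
#' For every layer present in the manifest and every configured comparison
#' against the control group: fits the control reference, computes the
#' deviation field and its point-wise significance (Student's t for a
#' two-group design, Tukey HSD when the patient subgroups are analyzed
#' together), detects significant areas, measures coverage-thresholded
#' fractions per ETDRS cell (MA), computes the conventional per-cell grid
#' (GA), and pairs the two. Writes CSV/JSON reports, exchange-format grids,
#' rendered PNGs and a parameter log to the output directory; reruns with
#' the same inputs produce identical CSV/JSON output. For subgroup-vs-
#' subgroup pairs under Tukey, the deviation field of the first subgroup is
#' shown against the control reference while the test compares the pair.
#'
#' @param config list or YAML path, see [analysisConfig()].
#' @return Invisibly, a nested list of results per layer and comparison
#'   (\code{reference}, \code{deviation}, \code{significance}, \code{areas},
#'   \code{fractions}, \code{grid}, \code{comparison} records).
#' @export
runAnalysis <- function(config) {
  cfg <- analysisConfig(config)
  manifest <- readManifest(cfg$manifest)
  allGroups <- c(cfg$control_group, cfg$compare_groups)
  missing <- setdiff(allGroups, manifest$group)
  if (length(missing))
    stop("groups missing from manifest: ", paste(missing, collapse = ", "))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$layer <- vapply(manifest$file, .peekLayer, character(1))
  layers <- if (is.null(cfg$layers)) unique(manifest$layer) else cfg$layers
  results <- list()
  for (lay in layers) {
    sub <- manifest[manifest$layer == lay, , drop = FALSE]
    stacks <- loadCohorts(sub, groups = allGroups)
    controls <- stacks[[cfg$control_group]]
    masks <- buildEtdrsMasks(lattice(controls))
    ref <- fitReference(controls)
    if (cfg$method == "tukey") {
      sigs <- pointwiseTukey(stacks[allGroups], alpha = cfg$alpha)
    } else {
      sigs <- list()
      for (g in cfg$compare_groups) {
        sf <- pointwiseTTest(stacks[[g]], controls, alpha = cfg$alpha)
        sigs[[sf@comparison]] <- sf
      }
    }
    layRes <- list()
    for (lab in names(sigs)) {
      parts <- strsplit(lab, " vs ", fixed = TRUE)[[1L]]
      gA <- parts[1L]
      dev <- deviationField(stacks[[gA]], ref)
      dev <- attachSignificance(dev, sigs[[lab]])
      areas <- detectSignificantAreas(dev, connectivity = cfg$connectivity)
      fractions <- measureFractions(areas, dev, masks,
                                    coverageThresholdPct =
                                      cfg$coverage_threshold_pct)
      grid <- gaDeviationGrid(
        stacks[[gA]], stacks[[parts[2L]]], masks, alpha = cfg$alpha,
        method = cfg$method,
        otherGroups = if (cfg$method == "tukey")
          stacks[setdiff(allGroups, parts)] else list())
      cmp <- compareGaMa(grid, fractions)
      layRes[[lab]] <- list(reference = ref, deviation = dev,
                            significance = sigs[[lab]], areas = areas,
                            fractions = fractions, grid = grid,
                            comparison = cmp)
      .writeComparisonOutputs(cfg, lay, lab, layRes[[lab]], masks)
    }
    results[[lay]] <- layRes
  }
  .writeRunLog(cfg, layers, names(results[[layers[1L]]]))
  invisible(results)
}

.slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

.writeComparisonOutputs <- function(cfg, lay, lab, res, masks) {
  stem <- file.path(cfg$output_dir, paste0(.slug(lay), "-", .slug(lab)))
  lat <- res$deviation@lattice
  writeFieldGrid(res$deviation@d, paste0(stem, "-deviation.txt"), lat,
                 "deviation_um")
  writeFieldGrid(res$significance@p, paste0(stem, "-pvalues.txt"), lat,
                 "p_value")
  writeFieldGrid(res$areas@labels, paste0(stem, "-areas.txt"), lat,
                 "area_label")
  utils::write.csv(res$fractions, paste0(stem, "-fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$grid@table, paste0(stem, "-grid.csv"),
                   row.names = FALSE)
  utils::write.csv(res$comparison, paste0(stem, "-ga-vs-ma.csv"),
                   row.names = FALSE)
  summary <- list(
    layer = lay, comparison = lab, alpha = cfg$alpha,
    method = cfg$method,
    coverage_threshold_pct = cfg$coverage_threshold_pct,
    n_significant_points = sum(res$significance@sig),
    n_areas = nrow(res$areas@info),
    fractions = res$fractions,
    grid = res$grid@table)
  jsonlite::write_json(summary, paste0(stem, "-summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (isTRUE(cfg$render)) {
    plotDeviationMap(res$deviation, paste0(stem, "-devm.png"), masks)
    plotDeviationGrid(res$grid, masks, paste0(stem, "-grid.png"))
    plotMdSeComparison(res$comparison, paste0(stem, "-md-se.png"))
  }
}

.writeRunLog <- function(cfg, layers, comparisons) {
  log <- list(alpha = cfg$alpha, method = cfg$method,
              coverage_threshold_pct = cfg$coverage_threshold_pct,
              connectivity = cfg$connectivity, seed = cfg$seed,
              manifest = cfg$manifest, layers = layers,
              comparisons = comparisons)
  jsonlite::write_json(log, file.path(cfg$output_dir, "run-log.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate cohorts to disk
#'
#' Generates the configured synthetic cohorts and writes them as
#' exchange-format thickness files plus a manifest CSV and ground-truth
#' lesion masks, ready for [runAnalysis()]. Config fields: \code{seed},
#' \code{output_dir}, optional \code{lattice} (\code{extent_mm},
#' \code{spacing_mm}), and \code{groups}: a list of group blocks with
#' \code{label}, \code{layer}, \code{n_subjects}, \code{between_sd_um},
#' \code{noise_sd_um}, \code{corr_length_mm} and an optional \code{lesions}
#' list (fields matching [lesionSpec()], in snake_case). Each group's RNG
#' seed is derived as \code{seed + 1000 * group_index}.
#'
#' @param config list or YAML path.
#' @return Invisibly, the manifest data.frame.
#' @export
simulateCohorts <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% "macuMap-sim"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lat <- macularLattice(
    extentMm = config$lattice$extent_mm %||% 6.0,
    spacingMm = config$lattice$spacing_mm %||% 0.05)
  masks <- buildEtdrsMasks(lat)
  rows <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    lesions <- lapply(g$lesions %||% list(), function(ls) {
      lesionSpec(shape = ls$shape, amplitudeUm = ls$amplitude_um,
                 edgeSoftnessMm = ls$edge_softness_mm %||% 0,
                 targetCell = ls$target_cell %||% NA_character_,
                 targetCoveragePct = ls$target_coverage_pct %||% NA_real_,
                 radiiMm = unlist(ls$radii_mm),
                 quadrant = ls$quadrant,
                 centerMm = unlist(ls$center_mm),
                 radiusMm = ls$radius_mm,
                 cell = ls$cell,
                 nClusters = ls$n_clusters,
                 clusterRadiusMm = ls$cluster_radius_mm)
    })
    cc <- cohortConfig(nSubjects = g$n_subjects,
                       betweenSdUm = g$between_sd_um %||% 4,
                       noiseSdUm = g$noise_sd_um %||% 2.5,
                       corrLengthMm = g$corr_length_mm %||% 0.25,
                       lesions = lesions,
                       seed = seed + 1000L * gi)
    gen <- generateCohort(layerProfile(g$layer %||% "TR"), cc, lat,
                          groupLabel = g$label, masks = masks)
    st <- gen$stack
    for (i in seq_len(nSubjects(st))) {
      mp <- thicknessMap(st@data[, , i], subjectId = st@subjectIds[i],
                         layer = st@layer, eye = "OD", lattice = lat,
                         mask = st@mask[, , i])
      fn <- sprintf("%s_%s.txt", st@subjectIds[i], st@layer)
      writeThicknessMap(mp, file.path(outDir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = st@subjectIds[i], group = g$label, eye = "OD",
        file = fn, stringsAsFactors = FALSE)
    }
    if (any(gen$lesionMask))
      writeFieldGrid(gen$lesionMask + 0L,
                     file.path(outDir, sprintf("truth_%s_%s.txt",
                                               g$label, st@layer)),
                     lat, "lesion_mask")
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}
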