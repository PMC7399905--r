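#' Radially symmetric layer thickness profile
#'
#' The generator's model of normal macular anatomy: a rotationally symmetric
#' base thickness b(r) with a foveal pit (thin center), a peak in the inner
#' macular ring, and a peripheral decline that saturates (exponential
#' approach on a 1.2 mm scale, so thin layers stay positive out to the
#' lattice corners):
#' \deqn{b(r) = c + (p - c) e^{-(r - r_p)^2 / 2w^2} -
#'   \tau \lambda (1 - e^{-\max(0, r - r_p)/\lambda})}
#' with \eqn{\lambda = 1.2} mm and \eqn{\tau} the taper rate in um/mm.
#' All parameters in um and mm. Defaults per layer are plausible magnitudes
#' for an adult macula (e.g. total retina about 270 um at the pit, 320 um at
#' the pericentral peak; GCL peak about 50 um); only the relative shape
#' matters for the analysis.
#'
#' @slot layer layer label.
#' @slot centerUm pit thickness at r = 0 (um).
#' @slot peakUm peak thickness (um).
#' @slot peakRadiusMm radius of the peak (mm).
#' @slot widthMm Gaussian width of the pericentral mound (mm).
#' @slot taperUmPerMm linear peripheral decline beyond the peak (um/mm).
#' @export
setClass("LayerProfile",
  representation(layer = "character", centerUm = "numeric",
                 peakUm = "numeric", peakRadiusMm = "numeric",
                 widthMm = "numeric", taperUmPerMm = "numeric"))

setValidity("LayerProfile", function(object) {
  # must stay positive over the whole lattice, corners included
  r <- seq(0, 4.5, by = 0.01)
  b <- .profileValue(object, r)
  if (any(b <= 0)) return("profile must stay positive on [0, 4.5] mm")
  TRUE
})

# peripheral decline saturates (scale 1.2 mm) so thin layers cannot cross
# zero at the lattice corners
.TAPER_SCALE_MM <- 1.2

.profileValue <- function(p, r) {
  p@centerUm + (p@peakUm - p@centerUm) *
    exp(-(r - p@peakRadiusMm)^2 / (2 * p@widthMm^2)) -
    p@taperUmPerMm * .TAPER_SCALE_MM *
      (1 - exp(-pmax(0, r - p@peakRadiusMm) / .TAPER_SCALE_MM))
}

.PROFILE_DEFAULTS <- list(
  TR   = c(center = 270, peak = 320, rp = 1.7, w = 0.80, taper = 8),
  RNFL = c(center = 12,  peak = 35,  rp = 2.0, w = 1.00, taper = 2),
  GCL  = c(center = 15,  peak = 50,  rp = 1.4, w = 0.70, taper = 8),
  IPL  = c(center = 20,  peak = 40,  rp = 1.4, w = 0.70, taper = 6),
  INL  = c(center = 18,  peak = 38,  rp = 1.5, w = 0.70, taper = 6))

#' Construct a layer profile
#'
#' @param layer layer label; picks default parameters for that layer.
#' @param centerUm,peakUm,peakRadiusMm,widthMm,taperUmPerMm overrides.
#' @return A \linkS4class{LayerProfile}.
#' @export
layerProfile <- function(layer = "TR", centerUm = NULL, peakUm = NULL,
                         peakRadiusMm = NULL, widthMm = NULL,
                         taperUmPerMm = NULL) {
  if (!layer %in% .LAYERS) stop("unknown layer: ", layer)
  d <- .PROFILE_DEFAULTS[[layer]]
  new("LayerProfile", layer = layer,
      centerUm = centerUm %||% d[["center"]],
      peakUm = peakUm %||% d[["peak"]],
      peakRadiusMm = peakRadiusMm %||% d[["rp"]],
      widthMm = widthMm %||% d[["w"]],
      taperUmPerMm = taperUmPerMm %||% d[["taper"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a profile on a lattice
#'
#' @param profile a \linkS4class{LayerProfile}.
#' @param lattice a \linkS4class{MacularLattice}.
#' @return Numeric matrix b(r) in um.
#' @export
profileField <- function(profile, lattice = macularLattice()) {
  co <- latticeCoords(lattice)
  matrix(.profileValue(profile, as.vector(co$r)), nPoints(lattice))
}

#' Planted lesion specification
#'
#' Describes one localized thickness change added to every patient map:
#' shape (annulus, wedge, disk or a scattered cluster of small disks),
#' location, signed amplitude (negative = thinning), and an optional smooth
#' edge band. A disk lesion can instead be sized automatically to cover a
#' target percentage of a named ETDRS cell.
#'
#' @slot shape "annulus", "wedge", "disk" or "scattered".
#' @slot amplitudeUm signed amplitude (um); negative = thinning.
#' @slot edgeSoftnessMm width of the smooth rolloff band inside the lesion
#'   boundary (mm); 0 = hard edge.
#' @slot params shape parameters: annulus/wedge need \code{radiiMm}
#'   (c(inner, outer)); wedge also \code{quadrant}; disk needs
#'   \code{centerMm} (c(x, y)) and \code{radiusMm}; scattered needs
#'   \code{cell} (or nothing for the whole grid disk), \code{nClusters},
#'   \code{clusterRadiusMm}.
#' @slot targetCell,targetCoveragePct optional disk auto-sizing: cover this
#'   percentage (+/- 1) of this cell.
#' @export
setClass("LesionSpec",
  representation(shape = "character", amplitudeUm = "numeric",
                 edgeSoftnessMm = "numeric", params = "list",
                 targetCell = "character", targetCoveragePct = "numeric"))

setValidity("LesionSpec", function(object) {
  if (!object@shape %in% c("annulus", "wedge", "disk", "scattered"))
    return("unknown lesion shape")
  if (!is.finite(object@amplitudeUm)) return("amplitude must be finite")
  if (object@edgeSoftnessMm < 0) return("edge softness must be >= 0")
  TRUE
})

#' Construct a lesion specification
#'
#' @param shape lesion shape; see \linkS4class{LesionSpec}.
#' @param amplitudeUm signed amplitude in um (negative = thinning).
#' @param edgeSoftnessMm smooth edge band width (mm), default 0.
#' @param targetCell,targetCoveragePct optional auto-sizing of a disk to a
#'   cell coverage percentage.
#' @param ... shape parameters (\code{radiiMm}, \code{quadrant},
#'   \code{centerMm}, \code{radiusMm}, \code{cell}, \code{nClusters},
#'   \code{clusterRadiusMm}).
#' @return A \linkS4class{LesionSpec}.
#' @examples
#' lesionSpec("annulus", -12, radiiMm = c(0.5, 1.5))
#' @export
lesionSpec <- function(shape, amplitudeUm, edgeSoftnessMm = 0,
                       targetCell = NA_character_,
                       targetCoveragePct = NA_real_, ...) {
  new("LesionSpec", shape = shape, amplitudeUm = amplitudeUm,
      edgeSoftnessMm = edgeSoftnessMm, params = list(...),
      targetCell = targetCell, targetCoveragePct = targetCoveragePct)
}

# soft radial band factor in [0,1]: 1 well inside, linear ramp of width s
.ramp <- function(distInside, s) {
  if (s <= 0) as.numeric(distInside > 0) else pmax(0, pmin(1, distInside / s))
}

#' Realize a lesion on a lattice
#'
#' Builds the additive thickness field of a lesion: full amplitude in the
#' interior, a linear rolloff over the edge-softness band inside the
#' boundary, zero outside. The exact support mask (field != 0) is returned
#' alongside for ground-truth comparisons. Scattered clusters draw their
#' positions from the current RNG stream (seed via the cohort config).
#'
#' @param spec a \linkS4class{LesionSpec}.
#' @param lattice a \linkS4class{MacularLattice}.
#' @param masks an \linkS4class{EtdrsMasks}; required for wedge quadrants,
#'   scattered cells, and coverage targeting.
#' @return list with \code{field} (numeric matrix, um) and \code{mask}
#'   (logical support matrix).
#' @export
lesionField <- function(spec, lattice = macularLattice(), masks = NULL) {
  co <- latticeCoords(lattice)
  r <- co$r; x <- co$x; y <- co$y
  s <- spec@edgeSoftnessMm
  amp <- spec@amplitudeUm
  if (amp == 0) {
    z <- matrix(0, nPoints(lattice), nPoints(lattice))
    return(list(field = z, mask = z > 0))
  }
  needMasks <- function() {
    if (is.null(masks)) stop("this lesion spec requires EtdrsMasks")
    masks
  }
  factor <- switch(spec@shape,
    annulus = {
      rad <- spec@params$radiiMm
      ind <- r >= rad[1L] & r < rad[2L]
      if (s > 0)
        pmin(.ramp(r - rad[1L], s), .ramp(rad[2L] - r, s)) * ind
      else ind + 0
    },
    wedge = {
      m <- needMasks()
      rad <- spec@params$radiiMm
      q <- match(spec@params$quadrant, c("nasal", "superior", "temporal",
                                         "inferior")) - 1L
      inQuad <- ((floor((co$theta + 45) / 90)) %% 4) == q
      ind <- (r >= rad[1L] & r < rad[2L]) & inQuad
      if (s > 0)
        pmin(.ramp(r - rad[1L], s), .ramp(rad[2L] - r, s)) * ind
      else ind + 0
    },
    disk = {
      if (!is.na(spec@targetCell)) {
        m <- needMasks()
        spec <- .sizeDiskToCoverage(spec, lattice, m)
      }
      ctr <- spec@params$centerMm
      R <- spec@params$radiusMm
      d <- sqrt((x - ctr[1L])^2 + (y - ctr[2L])^2)
      .ramp(R - d, s) * (d < R)
    },
    scattered = {
      nC <- spec@params$nClusters %||% 5L
      cr <- spec@params$clusterRadiusMm %||% 0.15
      domain <- if (!is.null(spec@params$cell))
        cellMask(needMasks(), spec@params$cell) else r < 3
      idx <- which(domain)
      pick <- idx[sample.int(length(idx), nC, replace = FALSE)]
      f <- matrix(0, nrow(r), ncol(r))
      for (p in pick) {
        d <- sqrt((x - x[p])^2 + (y - y[p])^2)
        f <- pmax(f, .ramp(cr - d, s) * (d < cr))
      }
      f
    },
    stop("unknown lesion shape"))
  field <- amp * factor
  list(field = field, mask = field != 0)
}

# binary-search a disk radius so that support covers the target percentage
# of the named cell (+/- 1 percent); centered on the cell centroid unless a
# center is given
.sizeDiskToCoverage <- function(spec, lattice, masks) {
  cellM <- cellMask(masks, spec@targetCell)
  target <- spec@targetCoveragePct
  if (!is.finite(target) || target <= 0 || target > 100)
    stop("unreachable target coverage")
  co <- latticeCoords(lattice)
  ctr <- spec@params$centerMm %||%
    c(mean(co$x[cellM]), mean(co$y[cellM]))
  d <- sqrt((co$x - ctr[1L])^2 + (co$y - ctr[2L])^2)
  cellN <- sum(cellM)
  covAt <- function(R) 100 * sum(d < R & cellM) / cellN
  lo <- 0; hi <- 2 * latticeExtent(lattice)
  if (covAt(hi) < target - 1) stop("unreachable target coverage")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (covAt(mid) < target) lo <- mid else hi <- mid
  }
  R <- hi
  if (abs(covAt(R) - target) > 1) stop("unreachable target coverage")
  spec@params$centerMm <- ctr
  spec@params$radiusMm <- R
  spec@targetCell <- NA_character_
  spec
}

#' Cohort generation settings
#'
#' @slot nSubjects number of subjects.
#' @slot betweenSdUm SD of the per-subject global thickness offset (um).
#' @slot noiseSdUm point-wise SD of the within-map noise (um).
#' @slot corrLengthMm spatial correlation length of the noise (mm); the
#'   noise is Gaussian-smoothed white noise rescaled to the target
#'   point-wise SD, so neighbouring points co-vary as real maps do.
#' @slot lesions list of \linkS4class{LesionSpec} added to every subject.
#' @slot seed RNG seed; fixes the generated cohort bit-reproducibly.
#' @export
setClass("CohortConfig",
  representation(nSubjects = "integer", betweenSdUm = "numeric",
                 noiseSdUm = "numeric", corrLengthMm = "numeric",
                 lesions = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
  if (object@nSubjects < 2L) return("nSubjects must be >= 2")
  if (object@betweenSdUm < 0 || object@noiseSdUm < 0)
    return("SDs must be >= 0")
  if (object@corrLengthMm < 0) return("corrLengthMm must be >= 0")
  TRUE
})

#' Construct a cohort configuration
#'
#' @param nSubjects number of subjects (>= 2).
#' @param betweenSdUm between-subject SD of a global offset, default 4 um.
#' @param noiseSdUm within-map point-wise noise SD, default 2.5 um.
#' @param corrLengthMm noise correlation length, default 0.25 mm.
#' @param lesions list of \linkS4class{LesionSpec} (empty for controls).
#' @param seed integer RNG seed.
#' @return A \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nSubjects, betweenSdUm = 4, noiseSdUm = 2.5,
                         corrLengthMm = 0.25, lesions = list(), seed = 1L) {
  new("CohortConfig", nSubjects = as.integer(nSubjects),
      betweenSdUm = betweenSdUm, noiseSdUm = noiseSdUm,
      corrLengthMm = corrLengthMm, lesions = lesions,
      seed = as.integer(seed))
}

# separable Gaussian convolution with reflected edges; kernel sum 1
.gaussKernel <- function(sigmaPx) {
  radius <- max(1L, ceiling(3 * sigmaPx))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigmaPx^2))
  k / sum(k)
}

.convolveCols <- function(m, k) {
  p <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  padded <- rbind(m[p:1, , drop = FALSE], m, m[n:(n - p + 1L), , drop = FALSE])
  f <- stats::filter(padded, k, method = "convolution", sides = 2)
  matrix(f[(p + 1L):(p + n), ], n, ncol(m))
}

#' Spatially correlated Gaussian noise field
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel
#' (sigma = corrLengthMm), then rescaled by the exact kernel-energy factor
#' so the point-wise SD equals \code{sdUm} (edges use reflection padding;
#' their variance deviates marginally from the interior). Draws from the
#' current RNG stream.
#'
#' @param lattice a \linkS4class{MacularLattice}.
#' @param sdUm target point-wise SD (um).
#' @param corrLengthMm Gaussian correlation length (mm); 0 = white noise.
#' @return Numeric matrix.
#' @export
correlatedNoiseField <- function(lattice, sdUm, corrLengthMm) {
  n <- nPoints(lattice)
  w <- matrix(stats::rnorm(n * n), n, n)
  if (sdUm == 0) return(matrix(0, n, n))
  if (corrLengthMm > 0) {
    k <- .gaussKernel(corrLengthMm / latticeSpacing(lattice))
    w <- .convolveCols(w, k)
    w <- t(.convolveCols(t(w), k))
    # separable kernel energy: var after smoothing = (sum k^2)^2
    w <- w / sum(k^2)
  }
  sdUm * w
}

#' Generate a synthetic cohort
#'
#' Every subject's map is the layer profile b(r) plus a subject-level global
#' offset ~ N(0, betweenSd), a spatially correlated noise field, and the sum
#' of all configured lesion fields; values are floored at 0.5 um so maps
#' stay physically valid. The generation is bit-reproducible for a given
#' seed (the caller's RNG state is saved and restored). Ground-truth lesion
#' masks are returned for recovery tests.
#'
#' @param profile a \linkS4class{LayerProfile}.
#' @param config a \linkS4class{CohortConfig}.
#' @param lattice a \linkS4class{MacularLattice}.
#' @param groupLabel group label for the resulting stack.
#' @param masks optional \linkS4class{EtdrsMasks} (built on demand when a
#'   lesion needs one).
#' @return list with \code{stack} (\linkS4class{CohortStack}),
#'   \code{lesionMask} (logical union of lesion supports),
#'   \code{lesionFields} (list of per-lesion fields), \code{base} (the
#'   noise-free mean field including lesions).
#' @export
generateCohort <- function(profile, config, lattice = macularLattice(),
                           groupLabel = "group", masks = NULL) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config@seed)
  n <- nPoints(lattice)
  base <- profileField(profile, lattice)
  lf <- list(); lesionSum <- matrix(0, n, n)
  lesionMask <- matrix(FALSE, n, n)
  if (length(config@lesions)) {
    if (is.null(masks)) masks <- buildEtdrsMasks(lattice)
    for (i in seq_along(config@lesions)) {
      li <- lesionField(config@lesions[[i]], lattice, masks)
      lf[[i]] <- li
      lesionSum <- lesionSum + li$field
      lesionMask <- lesionMask | li$mask
    }
  }
  meanField <- base + lesionSum
  maps <- vector("list", config@nSubjects)
  for (i in seq_len(config@nSubjects)) {
    off <- stats::rnorm(1, 0, config@betweenSdUm)
    noise <- correlatedNoiseField(lattice, config@noiseSdUm,
                                  config@corrLengthMm)
    vals <- pmax(meanField + off + noise, 0.5)
    maps[[i]] <- thicknessMap(vals,
                              subjectId = sprintf("%s%03d", groupLabel, i),
                              layer = profile@layer, eye = "OD",
                              lattice = lattice)
  }
  list(stack = buildCohort(maps, groupLabel = groupLabel),
       lesionMask = lesionMask, lesionFields = lf, base = meanField)
}
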