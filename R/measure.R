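#' Connected significant areas on a deviation map
#'
#' Connected components (8-neighbourhood by default) of the point-wise
#' significance mask, split by the sign of the deviation so thinning and
#' thickening areas are always separate components even when adjacent.
#'
#' @slot lattice the \linkS4class{MacularLattice}.
#' @slot labels integer matrix, 0 = not significant, k = member of area k.
#' @slot info data.frame with one row per area: \code{id}, \code{sign}
#'   (-1 thinning, +1 thickening), \code{n_points}.
#' @export
setClass("SignificantAreas",
  representation(lattice = "MacularLattice", labels = "matrix",
                 info = "data.frame"))

setValidity("SignificantAreas", function(object) {
  ids <- sort(unique(object@labels[object@labels > 0L]))
  if (length(ids) && !identical(as.integer(ids), object@info$id))
    return("info must have one row per label id")
  TRUE
})

# label connected components of a logical matrix (8- or 4-connectivity)
# flood fill with an integer stack; matrices here are small (<= a few 10^4)
.labelComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  nextId <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextId <- nextId + 1L
    top <- 1L; stack[1L] <- start; lab[start] <- nextId
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (kk in seq_along(dr)) {
        r2 <- r + dr[kk]; c2 <- cl + dc[kk]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          i2 <- (c2 - 1L) * nr + r2
          if (mask[i2] && lab[i2] == 0L) {
            lab[i2] <- nextId
            top <- top + 1L; stack[top] <- i2
          }
        }
      }
    }
  }
  lab
}

#' Detect statistically significant areas on a deviation map
#'
#' Step (i) of the map-based measurement: the significance mask is split
#' into thinning (d < 0) and thickening (d >= 0) point sets, and each set is
#' decomposed into maximal connected components. 8-connectivity is the
#' default so diagonal bands (e.g. an annulus crossing quadrant diagonals)
#' are not artificially split; 4-connectivity is available.
#'
#' @param dev a \linkS4class{DeviationResult} with significance attached
#'   (see [attachSignificance()]).
#' @param connectivity 8 (default) or 4.
#' @return A \linkS4class{SignificantAreas}.
#' @export
detectSignificantAreas <- function(dev, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  sig <- dev@sig & is.finite(dev@d)
  neg <- sig & dev@d < 0
  pos <- sig & dev@d >= 0
  labNeg <- .labelComponents(neg, connectivity)
  labPos <- .labelComponents(pos, connectivity)
  nNeg <- max(labNeg)
  lab <- labNeg
  lab[labPos > 0L] <- labPos[labPos > 0L] + nNeg
  ids <- seq_len(max(lab, 0L))
  if (length(ids)) {
    info <- data.frame(
      id = as.integer(ids),
      sign = ifelse(ids <= nNeg, -1L, 1L),
      n_points = as.integer(tabulate(lab[lab > 0L], nbins = max(ids))))
  } else {
    info <- data.frame(id = integer(0), sign = integer(0),
                       n_points = integer(0))
  }
  new("SignificantAreas", lattice = dev@lattice, labels = lab, info = info)
}

#' Area label field accessor
#' @param x a \linkS4class{SignificantAreas}.
#' @return Integer matrix.
#' @export
areaLabels <- function(x) x@labels

#' Area summary table accessor
#' @param x a \linkS4class{SignificantAreas}.
#' @return data.frame (id, sign, n_points).
#' @export
areaInfo <- function(x) x@info

#' @describeIn SignificantAreas compact display
#' @param object a \linkS4class{SignificantAreas}.
#' @export
setMethod("show", "SignificantAreas", function(object) {
  cat(sprintf("SignificantAreas: %d components (%d thinning, %d thickening), %d points\n",
              nrow(object@info), sum(object@info$sign < 0),
              sum(object@info$sign > 0), sum(object@info$n_points)))
})

# MD +/- SE over a set of significant points; SE either across points
# (dispersion of the group-difference field) or across subjects (difference
# of per-subject means over the same points)
.mdSe <- function(sel, d, se, group, controls) {
  dv <- d[sel]
  np <- length(dv)
  md <- mean(dv)
  if (se == "points") {
    sev <- if (np > 1L) stats::sd(dv) / sqrt(np) else NA_real_
  } else {
    subjMeans <- function(st) {
      k <- nSubjects(st)
      v <- vapply(seq_len(k), function(i) {
        vi <- st@data[, , i][sel & st@mask[, , i]]
        if (length(vi)) mean(vi) else NA_real_
      }, numeric(1))
      v[is.finite(v)]
    }
    ga <- subjMeans(group); gc <- subjMeans(controls)
    sev <- sqrt(stats::var(ga) / length(ga) + stats::var(gc) / length(gc))
  }
  list(md = md, se = sev, n = np)
}

#' Measure significant fractions per ETDRS grid cell
#'
#' Steps (ii)-(iv) of the map-based measurement: significant points are
#' partitioned by ETDRS cell; within each cell and deviation sign the
#' significant fraction is measured as MD (mean of the deviation field over
#' those points, um) +/- SE, together with its coverage (percent of the
#' cell's full geometric area); fractions covering less than the coverage
#' threshold (default 10 percent) are still reported but flagged
#' \code{passed_threshold = FALSE}, i.e. not admissible as findings.
#'
#' @param areas a \linkS4class{SignificantAreas}.
#' @param dev the matching \linkS4class{DeviationResult}.
#' @param masks an \linkS4class{EtdrsMasks}.
#' @param coverageThresholdPct minimum cell coverage in percent, in (0, 100].
#' @param se "points" (default): SE of the deviation values across the
#'   fraction's points; "subjects": SE of the group difference of
#'   per-subject means over those points (requires \code{group} and
#'   \code{controls}).
#' @param group,controls the \linkS4class{CohortStack}s behind \code{dev};
#'   only needed for \code{se = "subjects"}.
#' @return data.frame with columns \code{cell}, \code{sign},
#'   \code{coverage_pct}, \code{MD_um}, \code{SE_um}, \code{n_points},
#'   \code{passed_threshold}; one row per (cell, sign) containing
#'   significant points.
#' @export
measureFractions <- function(areas, dev, masks, coverageThresholdPct = 10,
                             se = c("points", "subjects"),
                             group = NULL, controls = NULL) {
  se <- match.arg(se)
  if (coverageThresholdPct <= 0 || coverageThresholdPct > 100)
    stop("coverage threshold must lie in (0, 100]")
  if (se == "subjects" && (is.null(group) || is.null(controls)))
    stop("se = 'subjects' requires the group and control stacks")
  if (!sameLattice(areas@lattice, masks@lattice))
    stop("areas and masks on different lattices")
  rows <- list()
  for (sgn in c(-1L, 1L)) {
    ids <- areas@info$id[areas@info$sign == sgn]
    if (!length(ids)) next
    ptsAll <- matrix(areas@labels %in% ids, nrow(areas@labels))
    parts <- partitionPointsByCell(ptsAll, masks)
    for (cell in masks@cellNames) {
      sel <- parts[[cell]]
      np <- sum(sel)
      if (np == 0L) next
      cov <- cellCoverage(np, cellCounts(masks)[[cell]])
      ms <- .mdSe(sel, dev@d, se, group, controls)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell, sign = sgn, coverage_pct = cov,
        MD_um = ms$md, SE_um = ms$se, n_points = np,
        passed_threshold = cov >= coverageThresholdPct,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell = character(0), sign = integer(0),
                      coverage_pct = numeric(0), MD_um = numeric(0),
                      SE_um = numeric(0), n_points = integer(0),
                      passed_threshold = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measure a user-selected region of interest as a single defect
#'
#' Pools all significant points inside an arbitrary region (which may span
#' several quadrants or rings) into one MD +/- SE measurement — the manual
#' workflow for irregular defects that the per-cell threshold would
#' fragment. A per-cell coverage breakdown of the region's significant
#' points is attached when masks are given.
#'
#' @param roi logical matrix selecting the region.
#' @param dev a \linkS4class{DeviationResult} with significance attached.
#' @param masks optional \linkS4class{EtdrsMasks} for the per-cell
#'   breakdown.
#' @param se,group,controls as in [measureFractions()].
#' @return list with \code{MD_um}, \code{SE_um}, \code{n_points}, and
#'   \code{cells} (data.frame of per-cell coverage of the ROI's significant
#'   points, or NULL). An ROI with no significant points returns
#'   \code{n_points = 0} with a warning.
#' @export
measureRoi <- function(roi, dev, masks = NULL, se = c("points", "subjects"),
                       group = NULL, controls = NULL) {
  se <- match.arg(se)
  if (!any(roi)) stop("roi is empty")
  sel <- roi & dev@sig & is.finite(dev@d)
  if (!any(sel)) {
    warning("roi contains no significant points; empty defect")
    return(list(MD_um = NA_real_, SE_um = NA_real_, n_points = 0L,
                cells = NULL))
  }
  ms <- .mdSe(sel, dev@d, se, group, controls)
  cells <- NULL
  if (!is.null(masks)) {
    parts <- partitionPointsByCell(sel, masks)
    cnt <- vapply(masks@cellNames, function(cl) sum(parts[[cl]]), integer(1))
    keep <- cnt > 0L
    cells <- data.frame(cell = masks@cellNames[keep],
                        n_points = as.integer(cnt[keep]),
                        coverage_pct = 100 * cnt[keep] /
                          cellCounts(masks)[keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(MD_um = ms$md, SE_um = ms$se, n_points = ms$n, cells = cells)
}
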