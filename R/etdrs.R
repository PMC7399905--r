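.ETDRS_CELLS <- c("FC",
                  "IMR_nasal", "IMR_superior", "IMR_temporal", "IMR_inferior",
                  "OMR_nasal", "OMR_superior", "OMR_temporal", "OMR_inferior")

#' ETDRS grid cell masks on a lattice
#'
#' The ETDRS macular grid partitions the central 6 mm disk into nine cells: a
#' 1 mm-diameter foveal center (FC), and inner (pericentral, 1-3 mm diameter)
#' and outer (peripheral, 3-6 mm diameter) macular rings each split into
#' nasal, superior, temporal and inferior quadrants on the 45-degree
#' diagonals. Ring radii are therefore 0.5, 1.5 and 3.0 mm. Ring intervals
#' are half-open (inner radius included) and quadrant sectors are half-open
#' counterclockwise, so every point inside the disk belongs to exactly one
#' cell.
#'
#' @slot lattice the \linkS4class{MacularLattice} the masks live on.
#' @slot labels integer matrix: 0 = outside the 3 mm-radius disk, 1..9 =
#'   index into \code{cellNames}.
#' @slot cellNames the nine cell names, FC first.
#' @slot counts integer vector of per-cell point counts.
#' @slot areasMm2 per-cell area estimates, counts x spacing^2.
#' @export
setClass("EtdrsMasks",
  representation(lattice = "MacularLattice", labels = "matrix",
                 cellNames = "character", counts = "integer",
                 areasMm2 = "numeric"))

setValidity("EtdrsMasks", function(object) {
  if (!identical(object@cellNames, .ETDRS_CELLS))
    return("cellNames must be the nine canonical ETDRS cells")
  if (any(object@counts <= 0L))
    return("every cell must contain at least one lattice point")
  lab <- object@labels
  if (!all(lab %in% 0:9)) return("labels must be integers 0..9")
  TRUE
})

#' Build the ETDRS cell masks
#'
#' Assigns every lattice point with center-distance r < 3 mm to one of the
#' nine ETDRS cells: FC if r < 0.5, inner ring if 0.5 <= r < 1.5, outer ring
#' if 1.5 <= r < 3.0; quadrants by polar angle with boundaries on the
#' 45-degree diagonals, half-open counterclockwise (nasal covers
#' [-45, 45) degrees in the canonical OD frame, superior [45, 135), and so
#' on). Points on a diagonal boundary go to the counterclockwise-next sector;
#' the convention is arbitrary but fixed, and guarantees a disjoint,
#' exhaustive partition.
#'
#' @param lattice a \linkS4class{MacularLattice} with extent >= 6 mm.
#' @return An \linkS4class{EtdrsMasks}.
#' @examples
#' em <- buildEtdrsMasks(macularLattice())
#' cellCounts(em)
#' @export
buildEtdrsMasks <- function(lattice = macularLattice()) {
  if (lattice@extentMm < 6 - 1e-9) stop("grid does not fit: extent < 6 mm")
  co <- latticeCoords(lattice)
  r <- co$r; th <- co$theta
  ring <- matrix(NA_integer_, nrow(r), ncol(r))
  ring[r < 0.5] <- 0L
  ring[r >= 0.5 & r < 1.5] <- 1L
  ring[r >= 1.5 & r < 3.0] <- 2L
  # quadrant index: 0 nasal, 1 superior, 2 temporal, 3 inferior
  quad <- (floor((th + 45) / 90)) %% 4
  lab <- matrix(0L, nrow(r), ncol(r))
  lab[ring == 0L & !is.na(ring)] <- 1L
  for (q in 0:3) {
    lab[!is.na(ring) & ring == 1L & quad == q] <- 2L + q
    lab[!is.na(ring) & ring == 2L & quad == q] <- 6L + q
  }
  counts <- as.integer(tabulate(lab[lab > 0L], nbins = 9L))
  new("EtdrsMasks", lattice = lattice, labels = lab,
      cellNames = .ETDRS_CELLS, counts = counts,
      areasMm2 = counts * lattice@spacingMm^2)
}

#' Cell names of an ETDRS mask set
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return Character vector of nine names.
#' @export
cellNames <- function(masks) masks@cellNames

#' Per-cell lattice point counts
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return Named integer vector.
#' @export
cellCounts <- function(masks) stats::setNames(masks@counts, masks@cellNames)

#' Per-cell areas in mm^2
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return Named numeric vector.
#' @export
cellAreas <- function(masks) stats::setNames(masks@areasMm2, masks@cellNames)

#' Logical mask of one cell
#' @param masks an \linkS4class{EtdrsMasks}.
#' @param cell cell name (see [cellNames()]).
#' @return Logical matrix.
#' @export
cellMask <- function(masks, cell) {
  i <- match(cell, masks@cellNames)
  if (is.na(i)) stop("unknown cell: ", cell)
  masks@labels == i
}

#' Integer label field of the grid
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return Integer matrix, 0 outside the grid, 1..9 per cell.
#' @export
cellLabels <- function(masks) masks@labels

#' Partition a point set by ETDRS cell
#'
#' Every TRUE point of the input field is assigned to exactly one cell, or to
#' "outside" if it lies beyond the 3 mm radius. The per-cell counts sum to
#' the total inside-grid count by construction.
#'
#' @param points logical matrix on the masks' lattice.
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return Named list of 10 logical matrices: nine cells plus
#'   \code{"outside"}.
#' @export
partitionPointsByCell <- function(points, masks) {
  if (!identical(dim(points), dim(masks@labels)))
    stop("points field does not match the mask lattice")
  out <- lapply(seq_len(9L), function(i) points & masks@labels == i)
  names(out) <- masks@cellNames
  out$outside <- points & masks@labels == 0L
  out
}

#' Coverage percentage of a cell
#'
#' @param pointsInCell number of (significant) points falling in the cell.
#' @param cellSize total point count of the cell; the denominator is the
#'   full geometric cell size so the threshold meaning does not drift with
#'   scan-edge masking.
#' @return Percentage in [0, 100].
#' @export
cellCoverage <- function(pointsInCell, cellSize) {
  if (cellSize <= 0) stop("cellSize must be positive")
  if (pointsInCell > cellSize) stop("pointsInCell exceeds cellSize")
  100 * pointsInCell / cellSize
}

#' Mirror masks about the vertical midline
#'
#' Used to check laterality handling: mirroring the lattice swaps nasal and
#' temporal cells exactly and leaves superior/inferior and FC fixed.
#'
#' @param masks an \linkS4class{EtdrsMasks}.
#' @return An \linkS4class{EtdrsMasks} with mirrored labels.
#' @export
mirrorMasks <- function(masks) {
  lab <- masks@labels[, ncol(masks@labels):1]
  swap <- c(1L, 4L, 3L, 2L, 5L, 8L, 7L, 6L, 9L)  # nasal <-> temporal
  lab2 <- lab
  for (i in 1:9) lab2[lab == i] <- swap[i]
  counts <- as.integer(tabulate(lab2[lab2 > 0L], nbins = 9L))
  new("EtdrsMasks", lattice = masks@lattice, labels = lab2,
      cellNames = masks@cellNames, counts = counts,
      areasMm2 = counts * masks@lattice@spacingMm^2)
}

#' @describeIn EtdrsMasks compact display
#' @param object an \linkS4class{EtdrsMasks}.
#' @export
setMethod("show", "EtdrsMasks", function(object) {
  cat("EtdrsMasks (9 cells) on:\n")
  show(object@lattice)
  print(round(cellAreas(object), 3))
})
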