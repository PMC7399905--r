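#' Fovea-centered square lattice for thickness maps
#'
#' All maps in one analysis live on a common uniform square lattice centered
#' on the fovea. The side length (\code{extentMm}) and point spacing
#' (\code{spacingMm}) must be commensurate so that the point count per axis,
#' \code{extentMm / spacingMm + 1}, is an odd integer: the fovea then falls
#' exactly on the central lattice point.
#'
#' Orientation convention (canonical right eye, OD): row 1 is the superior
#' edge, column 1 the temporal edge, so x increases towards nasal and y
#' increases towards superior.
#'
#' @slot extentMm side length of the square field in mm.
#' @slot spacingMm lattice spacing in mm.
#'
#' @seealso [macularLattice()], [latticeCoords()]
#' @export
setClass("MacularLattice",
  representation(extentMm = "numeric", spacingMm = "numeric"),
  prototype(extentMm = 6.0, spacingMm = 0.05))

setValidity("MacularLattice", function(object) {
  e <- object@extentMm; s <- object@spacingMm
  if (length(e) != 1L || !is.finite(e) || e <= 0)
    return("extentMm must be a single positive number")
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    return("spacingMm must be a single positive number")
  n <- e / s + 1
  if (abs(n - round(n)) > 1e-8)
    return("extentMm must be an integer multiple of spacingMm")
  if (round(n) %% 2L != 1L)
    return("extentMm/spacingMm + 1 must be odd so the fovea is a lattice point")
  TRUE
})

#' Construct a macular lattice
#'
#' @param extentMm side length in mm; the default 6 mm covers the full ETDRS
#'   grid disk exactly.
#' @param spacingMm point spacing in mm (default 0.05 mm, i.e. 121 x 121
#'   points).
#' @return A \linkS4class{MacularLattice}.
#' @examples
#' lat <- macularLattice()
#' nPoints(lat)
#' @export
macularLattice <- function(extentMm = 6.0, spacingMm = 0.05) {
  new("MacularLattice", extentMm = extentMm, spacingMm = spacingMm)
}

#' @rdname nPoints
#' @export
setMethod("nPoints", "MacularLattice", function(x) {
  as.integer(round(x@extentMm / x@spacingMm)) + 1L
})

#' Spacing accessor
#' @param x a \linkS4class{MacularLattice}.
#' @return Numeric, spacing in mm.
#' @export
latticeSpacing <- function(x) x@spacingMm

#' Extent accessor
#' @param x a \linkS4class{MacularLattice}.
#' @return Numeric, extent in mm.
#' @export
latticeExtent <- function(x) x@extentMm

#' Point coordinates of a lattice
#'
#' Returns per-point coordinate fields in the canonical OD frame: x in mm
#' (positive = nasal), y in mm (positive = superior), polar radius r from the
#' lattice center, and polar angle theta in degrees in (-180, 180], measured
#' counterclockwise from the nasal (+x) axis.
#'
#' @param lat a \linkS4class{MacularLattice}.
#' @return A list of four numeric matrices: \code{x}, \code{y}, \code{r},
#'   \code{theta}.
#' @export
latticeCoords <- function(lat) {
  n <- nPoints(lat)
  ctr <- (n + 1L) / 2L
  s <- lat@spacingMm
  colx <- (seq_len(n) - ctr) * s          # x, nasal positive
  rowy <- (ctr - seq_len(n)) * s          # y, superior positive (row 1 top)
  x <- matrix(colx, n, n, byrow = TRUE)
  y <- matrix(rowy, n, n)
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) * 180 / pi
  list(x = x, y = y, r = r, theta = theta)
}

#' @describeIn MacularLattice compact display
#' @param object a \linkS4class{MacularLattice}.
#' @export
setMethod("show", "MacularLattice", function(object) {
  n <- nPoints(object)
  cat(sprintf("MacularLattice: %.2f x %.2f mm, spacing %.3f mm (%d x %d points)\n",
              object@extentMm, object@extentMm, object@spacingMm, n, n))
})

sameLattice <- function(a, b) {
  isTRUE(all.equal(a@extentMm, b@extentMm)) &&
    isTRUE(all.equal(a@spacingMm, b@spacingMm))
}
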