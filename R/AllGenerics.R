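#' @import methods
NULL

#' Number of lattice points per axis
#'
#' @param x a \linkS4class{MacularLattice} or an object carrying one.
#' @return Integer, the (odd) number of points per axis.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Lattice accessor
#'
#' @param x an object carrying a \linkS4class{MacularLattice}.
#' @return The \linkS4class{MacularLattice}.
#' @export
setGeneric("lattice", function(x) standardGeneric("lattice"))

#' Layer label accessor
#'
#' @param x an object with a retinal-layer label.
#' @return Character scalar, one of \code{"TR"}, \code{"RNFL"}, \code{"GCL"},
#'   \code{"IPL"}, \code{"INL"}.
#' @export
setGeneric("layer", function(x) standardGeneric("layer"))

#' Number of subjects in a cohort
#'
#' @param x a \linkS4class{CohortStack}.
#' @return Integer.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Thickness values accessor
#'
#' @param x a \linkS4class{ThicknessMap}.
#' @return Numeric matrix of thickness values (um).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Validity mask accessor
#'
#' @param x a \linkS4class{ThicknessMap}.
#' @return Logical matrix, \code{TRUE} where the point lies inside the
#'   scanned area.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
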