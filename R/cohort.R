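#' Aligned thickness maps of one group and one layer
#'
#' Holds the canonicalized, registered maps of all subjects in one study
#' group for one retinal layer as a dense points x subjects stack
#' (internally a row x col x subject array), the unit on which all group
#' statistics operate. One map per subject (unilateral eyes).
#'
#' @slot groupLabel group name, e.g. "control", "T2DM", "DN_pos", "DN_neg".
#' @slot layer retinal layer label.
#' @slot lattice shared \linkS4class{MacularLattice}.
#' @slot data numeric array (rows x cols x subjects), NA at invalid points.
#' @slot mask logical array of the same shape.
#' @slot subjectIds character vector, one id per subject.
#' @export
setClass("CohortStack",
  representation(groupLabel = "character", layer = "character",
                 lattice = "MacularLattice", data = "array",
                 mask = "array", subjectIds = "character"))

setValidity("CohortStack", function(object) {
  n <- nPoints(object@lattice)
  d <- dim(object@data)
  if (length(d) != 3L || d[1L] != n || d[2L] != n)
    return("data must be an nPoints x nPoints x nSubjects array")
  if (!identical(dim(object@mask), d))
    return("mask must match data dimensions")
  if (d[3L] < 2L) return("a cohort needs at least 2 subjects")
  if (length(object@subjectIds) != d[3L])
    return("one subjectId per subject required")
  if (anyDuplicated(object@subjectIds))
    return("duplicate subject ids (one map per subject)")
  if (!object@layer %in% .LAYERS)
    return("invalid layer label")
  TRUE
})

#' Assemble a cohort stack from individual maps
#'
#' All maps must share one lattice and one layer and be canonicalized to the
#' OD frame (mixing eyes without canonicalization would scramble
#' nasal/temporal sides). Points valid in fewer than 2 subjects are unusable
#' for group testing; their count is available via [validCount()].
#'
#' @param maps list of \linkS4class{ThicknessMap} (>= 2).
#' @param groupLabel group name.
#' @return A \linkS4class{CohortStack}.
#' @examples
#' maps <- replicate(3, thicknessMap(matrix(300, 121, 121)), simplify = FALSE)
#' for (i in 1:3) maps[[i]]@subjectId <- paste0("S", i)
#' st <- buildCohort(maps, "control")
#' nSubjects(st)
#' @export
buildCohort <- function(maps, groupLabel = "group") {
  if (length(maps) < 2L) stop("a cohort needs at least 2 maps")
  lat <- maps[[1L]]@lattice; lay <- maps[[1L]]@layer
  for (m in maps) {
    if (!sameLattice(m@lattice, lat)) stop("maps on mixed lattices")
    if (!identical(m@layer, lay)) stop("maps of mixed layers")
    if (m@eye != "OD")
      stop("maps must be canonicalized to the OD frame first")
  }
  n <- nPoints(lat); k <- length(maps)
  dat <- array(NA_real_, c(n, n, k)); msk <- array(FALSE, c(n, n, k))
  for (i in seq_len(k)) {
    dat[, , i] <- maps[[i]]@values
    msk[, , i] <- maps[[i]]@mask
  }
  new("CohortStack", groupLabel = groupLabel, layer = lay, lattice = lat,
      data = dat, mask = msk,
      subjectIds = vapply(maps, subjectId, character(1)))
}

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "CohortStack", function(x) dim(x@data)[3L])

#' @rdname lattice
#' @export
setMethod("lattice", "CohortStack", function(x) x@lattice)

#' @rdname layer
#' @export
setMethod("layer", "CohortStack", function(x) x@layer)

#' Group label accessor
#' @param x a \linkS4class{CohortStack}.
#' @return Character scalar.
#' @export
groupLabel <- function(x) x@groupLabel

#' Per-point count of subjects with valid data
#'
#' @param x a \linkS4class{CohortStack}.
#' @return Integer matrix; points with count < 2 are unusable for testing.
#' @export
validCount <- function(x) {
  n <- dim(x@mask)[1L]
  matrix(as.integer(rowSums(matrix(x@mask, n * n))), n, n)
}

#' Per-point group mean thickness
#'
#' @param x a \linkS4class{CohortStack}.
#' @return Numeric matrix (um); NA where no subject is valid.
#' @export
groupMean <- function(x) {
  pm <- .pointMoments(x)
  pm$mean
}

# per-point n, mean, variance from a stack (masked)
.pointMoments <- function(x) {
  n <- dim(x@data)[1L]; k <- dim(x@data)[3L]
  V <- matrix(x@data, n * n, k)
  M <- matrix(x@mask, n * n, k)
  V[!M] <- 0
  cnt <- rowSums(M)
  s1 <- rowSums(V)
  s2 <- rowSums(V * V)
  mu <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  va <- ifelse(cnt > 1, pmax(0, (s2 - cnt * mu^2) / (cnt - 1)), NA_real_)
  list(n = matrix(cnt, n, n), mean = matrix(mu, n, n),
       var = matrix(va, n, n))
}

# stack with a constant added to every subject (used in tests and simulation)
.shiftStack <- function(x, deltaUm) {
  x@data <- x@data + deltaUm
  x
}

#' @describeIn CohortStack compact display
#' @param object a \linkS4class{CohortStack}.
#' @export
setMethod("show", "CohortStack", function(object) {
  cat(sprintf("CohortStack '%s' | layer %s | n = %d subjects\n",
              object@groupLabel, object@layer, nSubjects(object)))
  show(object@lattice)
})
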