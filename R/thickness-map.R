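.LAYERS <- c("TR", "RNFL", "GCL", "IPL", "INL")
.EYES <- c("OD", "OS")

#' One subject's thickness field for one retinal layer
#'
#' A dense 2D field of layer thickness (um) on a fovea-centered
#' \linkS4class{MacularLattice}, with a per-point validity mask marking the
#' scanned area. Layers follow the usual inner-retina nomenclature: total
#' retina (TR), retinal nerve fiber layer (RNFL), ganglion cell layer (GCL),
#' inner plexiform layer (IPL) and inner nuclear layer (INL).
#'
#' @slot subjectId subject identifier.
#' @slot layer one of TR, RNFL, GCL, IPL, INL.
#' @slot eye "OD" (right) or "OS" (left); after
#'   [canonicalizeLaterality()] all maps are in the OD frame.
#' @slot values numeric matrix of thickness in um.
#' @slot mask logical matrix; \code{TRUE} inside the scanned area.
#' @slot lattice the shared \linkS4class{MacularLattice}.
#' @export
setClass("ThicknessMap",
  representation(subjectId = "character", layer = "character",
                 eye = "character", values = "matrix", mask = "matrix",
                 lattice = "MacularLattice"))

setValidity("ThicknessMap", function(object) {
  n <- nPoints(object@lattice)
  if (!identical(dim(object@values), c(n, n)))
    return(sprintf("values must be %d x %d to match the lattice", n, n))
  if (!identical(dim(object@mask), c(n, n)) || !is.logical(object@mask))
    return("mask must be a logical matrix matching the lattice")
  if (!object@layer %in% .LAYERS)
    return(paste("layer must be one of", paste(.LAYERS, collapse = ", ")))
  if (!object@eye %in% .EYES)
    return("eye must be 'OD' or 'OS'")
  v <- object@values[object@mask]
  if (any(!is.finite(v)) || any(v <= 0))
    return("values must be finite and > 0 um wherever mask is TRUE")
  TRUE
})

#' Construct a ThicknessMap
#'
#' @param values numeric matrix of thickness (um); \code{NA} entries are
#'   treated as invalid points.
#' @param subjectId subject identifier.
#' @param layer retinal layer label.
#' @param eye "OD" or "OS".
#' @param lattice a \linkS4class{MacularLattice}; defaults to the standard
#'   6 mm / 0.05 mm lattice.
#' @param mask optional logical validity matrix; defaults to
#'   \code{is.finite(values)}.
#' @return A \linkS4class{ThicknessMap}.
#' @export
thicknessMap <- function(values, subjectId = "S", layer = "TR", eye = "OD",
                         lattice = macularLattice(), mask = NULL) {
  if (is.null(mask)) mask <- is.finite(values)
  values[!mask] <- NA_real_
  new("ThicknessMap", subjectId = subjectId, layer = layer, eye = eye,
      values = values, mask = mask, lattice = lattice)
}

#' @rdname values
#' @export
setMethod("values", "ThicknessMap", function(x) x@values)

#' @rdname validMask
#' @export
setMethod("validMask", "ThicknessMap", function(x) x@mask)

#' @rdname lattice
#' @export
setMethod("lattice", "ThicknessMap", function(x) x@lattice)

#' @rdname layer
#' @export
setMethod("layer", "ThicknessMap", function(x) x@layer)

#' Eye laterality accessor
#' @param x a \linkS4class{ThicknessMap}.
#' @return "OD" or "OS".
#' @export
eye <- function(x) x@eye

#' Subject id accessor
#' @param x a \linkS4class{ThicknessMap}.
#' @return Character scalar.
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn ThicknessMap compact display
#' @param object a \linkS4class{ThicknessMap}.
#' @export
setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap %s | layer %s | eye %s | %d/%d valid points\n",
              object@subjectId, object@layer, object@eye,
              sum(object@mask), length(object@mask)))
  show(object@lattice)
})

#' Resample sparse B-scan rows onto the analysis lattice
#'
#' OCT volume scans sample the macula densely along each B-scan but sparsely
#' across B-scans (one row per scan). This resamples a set of thickness rows
#' with known vertical positions onto the dense lattice by linear
#' interpolation, first along each row (over its own horizontal sample
#' positions) and then across rows. Linear interpolation is used deliberately:
#' it is monotone and cannot overshoot the measured thickness range. Lattice
#' points outside the supplied row coverage get \code{mask = FALSE}.
#'
#' @param rawRows list with components \code{yMm} (numeric vector of strictly
#'   increasing row positions in mm, superior positive), \code{xMm} (numeric
#'   vector of within-row sample positions in mm, nasal positive, strictly
#'   increasing), and \code{thickness} (matrix, one row per B-scan, columns
#'   matching \code{xMm}).
#' @param target a \linkS4class{MacularLattice}.
#' @param subjectId,layer,eye metadata for the resulting map.
#' @return A \linkS4class{ThicknessMap} on \code{target}.
#' @export
resampleToLattice <- function(rawRows, target = macularLattice(),
                              subjectId = "S", layer = "TR", eye = "OD") {
  yMm <- rawRows$yMm; xMm <- rawRows$xMm; th <- rawRows$thickness
  if (length(yMm) < 2L) stop("insufficient coverage: need at least 2 raw rows")
  if (any(diff(yMm) <= 0)) stop("row positions must be strictly increasing")
  if (any(diff(xMm) <= 0)) stop("in-row positions must be strictly increasing")
  if (!is.matrix(th) || nrow(th) != length(yMm) || ncol(th) != length(xMm))
    stop("thickness must be a length(yMm) x length(xMm) matrix")

  n <- nPoints(target)
  co <- latticeCoords(target)
  gx <- co$x[1L, ]                       # column x positions
  gy <- co$y[, 1L]                       # row y positions (decreasing)

  # interpolate each raw row onto the lattice columns (NA outside coverage)
  rowInterp <- matrix(NA_real_, length(yMm), n)
  for (i in seq_along(yMm)) {
    rowInterp[i, ] <- stats::approx(xMm, th[i, ], xout = gx,
                                    method = "linear", rule = 1)$y
  }
  # interpolate across rows for each lattice column
  vals <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    vals[, j] <- stats::approx(yMm, rowInterp[, j], xout = gy,
                               method = "linear", rule = 1)$y
  }
  thicknessMap(vals, subjectId = subjectId, layer = layer, eye = eye,
               lattice = target)
}

#' Mirror left-eye maps into the canonical right-eye frame
#'
#' Nasal and temporal sides are anatomically mirrored between eyes. Before
#' point-wise pooling across subjects with randomly chosen eyes, every OS map
#' is reflected about the vertical midline and relabeled OD so that nasal is
#' always on the same lattice side. OD maps are returned unchanged. The
#' operation is an involution on the underlying field.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @return A \linkS4class{ThicknessMap} in the canonical OD frame.
#' @export
canonicalizeLaterality <- function(map) {
  if (map@eye == "OD") return(map)
  n <- ncol(map@values)
  idx <- n:1
  thicknessMap(map@values[, idx], subjectId = map@subjectId,
               layer = map@layer, eye = "OD", lattice = map@lattice,
               mask = map@mask[, idx])
}

#' Register a map so the fovea sits on the lattice center
#'
#' The ETDRS grid is placed on the center of each fovea, so every map is
#' translated by an integer lattice shift putting the detected foveal point
#' at the central lattice point. No subpixel interpolation is performed: at
#' 0.05 mm spacing the rounding error is below the lateral resolution of the
#' acquisition, and integer shifts introduce no smoothing. Points shifted in
#' from outside the field are marked invalid.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @param foveaRc integer vector \code{c(row, col)} of the foveal point in
#'   the map's current frame.
#' @return A registered \linkS4class{ThicknessMap}.
#' @export
registerToFovea <- function(map, foveaRc) {
  n <- nrow(map@values)
  ctr <- (n + 1L) %/% 2L
  fr <- as.integer(foveaRc[1L]); fc <- as.integer(foveaRc[2L])
  if (fr < 1L || fr > n || fc < 1L || fc > n)
    stop("fovea index outside the field")
  dr <- ctr - fr; dc <- ctr - fc
  if (abs(dr) > n %/% 2L || abs(dc) > n %/% 2L)
    stop("fovea too eccentric")
  vals <- matrix(NA_real_, n, n)
  msk <- matrix(FALSE, n, n)
  srcR <- seq_len(n) - dr; srcC <- seq_len(n) - dc
  okR <- srcR >= 1L & srcR <= n; okC <- srcC >= 1L & srcC <= n
  vals[okR, okC] <- map@values[srcR[okR], srcC[okC]]
  msk[okR, okC] <- map@mask[srcR[okR], srcC[okC]]
  thicknessMap(vals, subjectId = map@subjectId, layer = map@layer,
               eye = map@eye, lattice = map@lattice, mask = msk)
}
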