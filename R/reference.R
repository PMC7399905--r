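#' Control-referenced normative model
#'
#' Per-lattice-point summary of the control cohort's thickness distribution:
#' the mean and the empirical 2.5th and 97.5th percentiles. Deviation maps
#' are colored against the interval between these percentiles: white at the
#' control mean, darkest blue/red at or beyond the lower/upper percentile.
#' Points with fewer than 2 valid controls are undefined (NA).
#'
#' @slot lattice the \linkS4class{MacularLattice}.
#' @slot mean,p025,p975 numeric matrices (um).
#' @slot n integer matrix of per-point control counts.
#' @export
setClass("ReferenceModel",
  representation(lattice = "MacularLattice", mean = "matrix",
                 p025 = "matrix", p975 = "matrix", n = "matrix"))

setValidity("ReferenceModel", function(object) {
  ok <- is.finite(object@mean)
  if (any(object@p025[ok] > object@mean[ok] + 1e-9) ||
      any(object@p975[ok] < object@mean[ok] - 1e-9))
    return("percentiles must bracket the mean at every defined point")
  TRUE
})

# row-wise quantiles by linear interpolation between order statistics
# (the classical 'type 7' definition: h = (n-1)p + 1). X is points x subjects
# with NA for masked entries.
.rowQuantiles <- function(X, probs) {
  cnt <- rowSums(!is.na(X))
  out <- matrix(NA_real_, nrow(X), length(probs))
  full <- cnt == ncol(X)
  if (any(full)) {
    S <- t(apply(X[full, , drop = FALSE], 1L, sort))
    n <- ncol(X)
    for (j in seq_along(probs)) {
      h <- (n - 1) * probs[j] + 1
      lo <- floor(h); hi <- ceiling(h); g <- h - lo
      out[full, j] <- (1 - g) * S[, lo] + g * S[, hi]
    }
  }
  part <- which(!full & cnt >= 2L)
  for (i in part) {
    x <- sort(X[i, !is.na(X[i, ])])
    n <- length(x)
    for (j in seq_along(probs)) {
      h <- (n - 1) * probs[j] + 1
      lo <- floor(h); hi <- ceiling(h); g <- h - lo
      out[i, j] <- (1 - g) * x[lo] + g * x[hi]
    }
  }
  out
}

#' Fit the normative reference from a control cohort
#'
#' Computes, at every lattice point with at least 2 valid controls, the
#' control mean and the empirical 2.5th / 97.5th percentiles. Percentiles
#' use linear interpolation between order statistics (the h = (n-1)p + 1
#' definition, R's default quantile type 7).
#'
#' @param controls a \linkS4class{CohortStack} of the control group.
#' @return A \linkS4class{ReferenceModel}.
#' @export
fitReference <- function(controls) {
  n <- nPoints(controls@lattice); k <- nSubjects(controls)
  V <- matrix(controls@data, n * n, k)
  M <- matrix(controls@mask, n * n, k)
  V[!M] <- NA_real_
  cnt <- rowSums(M)
  mu <- rowSums(ifelse(M, V, 0)) / ifelse(cnt > 0, cnt, NA_real_)
  mu[cnt < 2L] <- NA_real_
  qs <- .rowQuantiles(V, c(0.025, 0.975))
  qs[cnt < 2L, ] <- NA_real_
  new("ReferenceModel", lattice = controls@lattice,
      mean = matrix(mu, n, n), p025 = matrix(qs[, 1L], n, n),
      p975 = matrix(qs[, 2L], n, n), n = matrix(as.integer(cnt), n, n))
}

#' @rdname lattice
#' @export
setMethod("lattice", "ReferenceModel", function(x) x@lattice)

#' Reference accessors
#'
#' @param ref a \linkS4class{ReferenceModel}.
#' @return Numeric (or integer, for \code{refN}) matrix.
#' @export
refMean <- function(ref) ref@mean

#' @rdname refMean
#' @export
refLower <- function(ref) ref@p025

#' @rdname refMean
#' @export
refUpper <- function(ref) ref@p975

#' @rdname refMean
#' @export
refN <- function(ref) ref@n

#' @describeIn ReferenceModel compact display
#' @param object a \linkS4class{ReferenceModel}.
#' @export
setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf("ReferenceModel: %d defined points, control n up to %d\n",
              sum(is.finite(object@mean)), max(object@n)))
  show(object@lattice)
})

#' Point-wise deviation of a group from the reference
#'
#' The deviation map (DevM) field: d(x) = group mean(x) - control mean(x) at
#' every mutually defined point, with the normalized color index of
#' [encodeColor()]. Significance (p-values and flags) is filled in from a
#' separately computed significance field, if supplied.
#'
#' @slot lattice the \linkS4class{MacularLattice}.
#' @slot d deviation field (um).
#' @slot colorIndex normalized index in [-1, 1].
#' @slot p per-point p-values (NA until testing is attached).
#' @slot sig logical significance flags.
#' @slot comparison label "group vs reference-group".
#' @export
setClass("DeviationResult",
  representation(lattice = "MacularLattice", d = "matrix",
                 colorIndex = "matrix", p = "matrix", sig = "matrix",
                 comparison = "character"))

setValidity("DeviationResult", function(object) {
  ok <- is.finite(object@d) & is.finite(object@colorIndex)
  if (any(sign(object@colorIndex[ok]) * sign(object@d[ok]) < 0))
    return("color index sign must match deviation sign")
  if (any(abs(object@colorIndex[ok]) > 1 + 1e-12))
    return("color index must lie in [-1, 1]")
  TRUE
})

#' Normalized deviation color index
#'
#' Maps a deviation d (um) at one reference point onto [-1, 1]: 0 (white) at
#' the control mean, +1 (darkest red, thickening) where the group mean
#' reaches or exceeds the upper percentile, -1 (darkest blue, thinning) at
#' or below the lower percentile, linear in between. Each side is scaled by
#' its own half-interval (upper - mean, mean - lower), since the empirical
#' percentiles generally sit at unequal distances from the mean. A
#' degenerate (zero-width) half-interval with a nonzero deviation saturates
#' to +/-1. All arguments are vectorized.
#'
#' @param d deviation in um (group mean minus control mean).
#' @param mean,p025,p975 reference point summary (um).
#' @return Numeric color index in [-1, 1]; NA where the reference is
#'   undefined.
#' @examples
#' encodeColor(10, mean = 300, p025 = 280, p975 = 320)  # +0.5
#' @export
encodeColor <- function(d, mean, p025, p975) {
  n <- max(length(d), length(mean), length(p025), length(p975))
  dd <- rep_len(as.vector(d), n)
  up <- rep_len(as.vector(p975 - mean), n)
  dn <- rep_len(as.vector(mean - p025), n)
  c <- numeric(n)
  pos <- !is.na(dd) & dd > 0
  neg <- !is.na(dd) & dd < 0
  c[pos] <- ifelse(up[pos] > 0, dd[pos] / up[pos], 1)
  c[neg] <- ifelse(dn[neg] > 0, dd[neg] / dn[neg], -1)
  c <- pmax(-1, pmin(1, c))
  c[!is.finite(dd) | !is.finite(rep_len(as.vector(mean), n))] <- NA_real_
  if (is.matrix(d)) dim(c) <- dim(d)
  c
}

#' Compute the point-wise deviation field of a group
#'
#' @param group a \linkS4class{CohortStack}.
#' @param ref a \linkS4class{ReferenceModel} on the same lattice.
#' @return A \linkS4class{DeviationResult} (significance slots empty; see
#'   [attachSignificance()]).
#' @export
deviationField <- function(group, ref) {
  if (!sameLattice(group@lattice, ref@lattice))
    stop("group and reference on different lattices")
  gm <- groupMean(group)
  d <- gm - ref@mean
  if (!any(is.finite(d))) stop("no overlap of valid points")
  ci <- encodeColor(d, ref@mean, ref@p025, ref@p975)
  n <- nPoints(group@lattice)
  new("DeviationResult", lattice = group@lattice, d = d, colorIndex = ci,
      p = matrix(NA_real_, n, n), sig = matrix(FALSE, n, n),
      comparison = group@groupLabel)
}

#' Deviation field accessor
#' @param x a \linkS4class{DeviationResult}.
#' @return Numeric matrix (um).
#' @export
deviation <- function(x) x@d

#' Color-index field accessor
#' @param x a \linkS4class{DeviationResult}.
#' @return Numeric matrix in [-1, 1].
#' @export
colorIndex <- function(x) x@colorIndex

#' Attach point-wise significance to a deviation result
#'
#' @param dev a \linkS4class{DeviationResult}.
#' @param sig a \linkS4class{SignificanceField} from [pointwiseTTest()] or
#'   [pointwiseTukey()].
#' @return The updated \linkS4class{DeviationResult}.
#' @export
attachSignificance <- function(dev, sig) {
  if (!sameLattice(dev@lattice, sig@lattice))
    stop("deviation and significance on different lattices")
  dev@p <- sig@p
  dev@sig <- sig@sig
  dev@comparison <- sig@comparison
  dev
}

#' @describeIn DeviationResult compact display
#' @param object a \linkS4class{DeviationResult}.
#' @export
setMethod("show", "DeviationResult", function(object) {
  ok <- is.finite(object@d)
  cat(sprintf("DeviationResult '%s': d in [%.2f, %.2f] um, %d significant points\n",
              object@comparison, suppressWarnings(min(object@d[ok])),
              suppressWarnings(max(object@d[ok])), sum(object@sig)))
})
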