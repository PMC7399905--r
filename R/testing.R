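#' Point-wise significance field
#'
#' Per-lattice-point p-values and significance flags for one pairwise group
#' comparison. A point is testable if both groups have at least 2 valid
#' subjects there; untestable points have NA p and FALSE flag. Degenerate
#' zero-variance points follow a fixed convention: equal means give p = 1,
#' unequal means p = 0.
#'
#' @slot lattice the \linkS4class{MacularLattice}.
#' @slot statistic per-point test statistic (t, or studentized range q).
#' @slot p per-point p-values.
#' @slot sig logical flags, \code{p < alpha} at testable points.
#' @slot alpha significance level.
#' @slot comparison label, e.g. "T2DM vs control".
#' @slot method "t" or "tukey".
#' @export
setClass("SignificanceField",
  representation(lattice = "MacularLattice", statistic = "matrix",
                 p = "matrix", sig = "matrix", alpha = "numeric",
                 comparison = "character", method = "character"))

setValidity("SignificanceField", function(object) {
  pv <- object@p[is.finite(object@p)]
  if (any(pv < 0 | pv > 1)) return("p-values must lie in [0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (any(object@sig & !is.finite(object@p)))
    return("significant flags require a defined p-value")
  TRUE
})

#' p-value field accessor
#' @param x a \linkS4class{SignificanceField}.
#' @return Numeric matrix.
#' @export
pValues <- function(x) x@p

#' Significance mask accessor
#' @param x a \linkS4class{SignificanceField}.
#' @return Logical matrix.
#' @export
sigMask <- function(x) x@sig

#' @describeIn SignificanceField compact display
#' @param object a \linkS4class{SignificanceField}.
#' @export
setMethod("show", "SignificanceField", function(object) {
  cat(sprintf("SignificanceField '%s' (%s, alpha = %g): %d significant of %d testable points\n",
              object@comparison, object@method, object@alpha,
              sum(object@sig), sum(is.finite(object@p))))
})

# pooled-variance two-sample t on vectors of per-point summaries
.pooledT <- function(n1, m1, v1, n2, m2, v2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # zero pooled variance: p by mean equality
  degen <- is.finite(sp2) & sp2 <= 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  t[degen & m1 == m2] <- 0
  list(t = t, p = p, df = df)
}

#' Point-wise two-group Student's t-test
#'
#' Classical pooled-variance (equal-variance) two-sided t-test at every
#' lattice point where both cohorts have at least 2 valid subjects, flagged
#' at level alpha (default 0.05). No multiple-testing correction is applied
#' across points by default — each point is tested at the nominal level, the
#' convention of per-point deviation-map significance outlines; an optional
#' Benjamini-Hochberg adjustment over testable points is available.
#'
#' @param a,b \linkS4class{CohortStack}s on the same lattice.
#' @param alpha significance level, default 0.05.
#' @param adjust "none" (default) or "BH" for Benjamini-Hochberg across all
#'   testable points.
#' @return A \linkS4class{SignificanceField}.
#' @export
pointwiseTTest <- function(a, b, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!sameLattice(a@lattice, b@lattice)) stop("cohorts on different lattices")
  pa <- .pointMoments(a); pb <- .pointMoments(b)
  n <- nPoints(a@lattice)
  testable <- pa$n >= 2L & pb$n >= 2L
  res <- .pooledT(pa$n, pa$mean, pa$var, pb$n, pb$mean, pb$var)
  p <- res$p; t <- res$t
  p[!testable] <- NA_real_; t[!testable] <- NA_real_
  if (adjust == "BH") {
    idx <- which(is.finite(p))
    p[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  sig <- is.finite(p) & p < alpha
  new("SignificanceField", lattice = a@lattice, statistic = t, p = p,
      sig = sig, alpha = alpha,
      comparison = paste(a@groupLabel, "vs", b@groupLabel), method = "t")
}

# per-point one-way pooled MSE and df over a list of moment summaries
.pooledMSE <- function(moms) {
  sse <- 0; N <- 0
  for (pm in moms) {
    sse <- sse + ifelse(pm$n > 1L, (pm$n - 1L) * pm$var, 0)
    N <- N + pm$n
  }
  df <- N - length(moms)
  list(mse = sse / df, df = df)
}

#' Point-wise Tukey HSD over two or more groups
#'
#' One-way pooled mean-square error across all groups at each point, then
#' for every group pair the Tukey-Kramer studentized-range statistic
#' q = |m_i - m_j| / sqrt((MSE/2) (1/n_i + 1/n_j)) with p-values from the
#' studentized-range distribution (base R's \code{ptukey}, k = number of
#' groups). With exactly two groups this reduces analytically to the pooled
#' t-test (q = |t| sqrt(2)). Points need at least 2 valid subjects in every
#' group.
#'
#' @param groups list of >= 2 \linkS4class{CohortStack}s on one lattice.
#' @param alpha family significance level, default 0.05.
#' @return Named list of \linkS4class{SignificanceField}, one per unordered
#'   pair, names "A vs B".
#' @export
pointwiseTukey <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  lat <- groups[[1L]]@lattice
  for (g in groups) if (!sameLattice(g@lattice, lat))
    stop("cohorts on different lattices")
  moms <- lapply(groups, .pointMoments)
  testable <- Reduce(`&`, lapply(moms, function(pm) pm$n >= 2L))
  pooled <- .pooledMSE(moms)
  labels <- vapply(groups, function(g) g@groupLabel, character(1))
  out <- list()
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    mi <- moms[[i]]; mj <- moms[[j]]
    se <- sqrt((pooled$mse / 2) * (1 / mi$n + 1 / mj$n))
    q <- abs(mi$mean - mj$mean) / se
    p <- stats::ptukey(q, nmeans = k, df = pooled$df, lower.tail = FALSE)
    degen <- is.finite(pooled$mse) & pooled$mse <= 0
    p[degen & mi$mean == mj$mean] <- 1
    p[degen & mi$mean != mj$mean] <- 0
    q[degen & mi$mean == mj$mean] <- 0
    p[!testable] <- NA_real_; q[!testable] <- NA_real_
    lab <- paste(labels[i], "vs", labels[j])
    out[[lab]] <- new("SignificanceField", lattice = lat, statistic = q,
                      p = p, sig = is.finite(p) & p < alpha, alpha = alpha,
                      comparison = lab, method = "tukey")
  }
  out
}

#' Per-subject mean thickness over each ETDRS cell
#'
#' The grid-analysis data reduction: one mean per subject per cell, averaging
#' all valid points of the cell mask.
#'
#' @param stack a \linkS4class{CohortStack}.
#' @param masks an \linkS4class{EtdrsMasks} on the same lattice.
#' @return Numeric matrix, 9 cells x nSubjects, rownames = cell names.
#' @export
subjectCellMeans <- function(stack, masks) {
  if (!sameLattice(stack@lattice, masks@lattice))
    stop("stack and masks on different lattices")
  n <- nPoints(stack@lattice); k <- nSubjects(stack)
  V <- matrix(stack@data, n * n, k)
  M <- matrix(stack@mask, n * n, k)
  lab <- as.vector(masks@labels)
  out <- matrix(NA_real_, 9L, k, dimnames = list(masks@cellNames,
                                                 stack@subjectIds))
  for (i in 1:9) {
    inCell <- lab == i
    Vi <- V[inCell, , drop = FALSE]; Mi <- M[inCell, , drop = FALSE]
    cnt <- colSums(Mi)
    Vi[!Mi] <- 0
    out[i, ] <- ifelse(cnt > 0, colSums(Vi) / cnt, NA_real_)
  }
  out
}

#' Per-ETDRS-cell group test on subject cell means
#'
#' Each subject is first reduced to nine cell means; the chosen test then
#' compares groups cell by cell, keeping subjects (not points) as the unit
#' of inference. With \code{method = "t"} exactly two stacks are compared by
#' the pooled-variance t-test; with \code{method = "tukey"} all supplied
#' stacks enter a one-way pooled MSE and every pair is tested against the
#' studentized-range distribution.
#'
#' @param groups list of >= 2 \linkS4class{CohortStack}s.
#' @param masks an \linkS4class{EtdrsMasks}.
#' @param alpha significance level, default 0.05.
#' @param method "t" (two groups) or "tukey" (two or more).
#' @return data.frame with columns \code{comparison}, \code{cell},
#'   \code{delta_um} (difference of group mean cell means), \code{p},
#'   \code{significant}.
#' @export
cellTest <- function(groups, masks, alpha = 0.05, method = c("t", "tukey")) {
  method <- match.arg(method)
  if (method == "t" && length(groups) != 2L)
    stop("method 't' requires exactly two groups")
  if (length(groups) < 2L) stop("need at least two groups")
  cm <- lapply(groups, subjectCellMeans, masks = masks)
  for (x in cm) if (any(!is.finite(x))) stop("empty or fully masked cell")
  labels <- vapply(groups, function(g) g@groupLabel, character(1))
  k <- length(groups)
  res <- list()
  if (method == "t") {
    a <- cm[[1L]]; b <- cm[[2L]]
    tt <- .pooledT(ncol(a), rowMeans(a), apply(a, 1L, stats::var),
                   ncol(b), rowMeans(b), apply(b, 1L, stats::var))
    res[[1L]] <- data.frame(
      comparison = paste(labels[1L], "vs", labels[2L]),
      cell = masks@cellNames,
      delta_um = rowMeans(a) - rowMeans(b),
      p = tt$p, significant = tt$p < alpha,
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    ns <- vapply(cm, ncol, integer(1))
    N <- sum(ns); df <- N - k
    means <- vapply(cm, rowMeans, numeric(9))            # 9 x k
    vars <- vapply(cm, function(x) apply(x, 1L, stats::var), numeric(9))
    mse <- as.vector(vars %*% (ns - 1L)) / df
    idx <- 0L
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      se <- sqrt((mse / 2) * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[, i] - means[, j]) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      degen <- mse <= 0
      p[degen] <- ifelse(means[degen, i] == means[degen, j], 1, 0)
      idx <- idx + 1L
      res[[idx]] <- data.frame(
        comparison = paste(labels[i], "vs", labels[j]),
        cell = masks@cellNames,
        delta_um = means[, i] - means[, j],
        p = p, significant = p < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
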