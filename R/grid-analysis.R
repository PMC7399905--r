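#' Conventional grid-based deviation summary
#'
#' The per-ETDRS-cell analysis (GA): every subject is reduced to nine cell
#' means, cells are compared between groups on those means, and each cell is
#' colored against the control distribution of cell means with the same
#' normalized encoding as the point-wise maps. GA averages normal and
#' abnormal points alike within a cell, which is exactly why it dilutes
#' localized defects relative to the map-based measurement.
#'
#' @slot table data.frame with one row per cell: \code{cell},
#'   \code{deviation_um}, \code{SE_um}, \code{p}, \code{significant},
#'   \code{color_index}.
#' @slot comparison comparison label.
#' @slot alpha significance level.
#' @slot method "t" or "tukey".
#' @export
setClass("DeviationGrid",
  representation(table = "data.frame", comparison = "character",
                 alpha = "numeric", method = "character"))

setValidity("DeviationGrid", function(object) {
  tb <- object@table
  if (nrow(tb) != 9L) return("grid must have nine cells")
  ok <- is.finite(tb$color_index) & is.finite(tb$deviation_um)
  if (any(sign(tb$color_index[ok]) * sign(tb$deviation_um[ok]) < 0))
    return("color sign must match deviation sign")
  TRUE
})

#' Grid table accessor
#' @param x a \linkS4class{DeviationGrid}.
#' @return data.frame of nine cells.
#' @export
gridTable <- function(x) x@table

#' @describeIn DeviationGrid compact display
#' @param object a \linkS4class{DeviationGrid}.
#' @export
setMethod("show", "DeviationGrid", function(object) {
  cat(sprintf("DeviationGrid '%s' (%s, alpha = %g)\n", object@comparison,
              object@method, object@alpha))
  print(object@table, digits = 4)
})

#' Grid-based (GA) deviation grid of a group versus controls
#'
#' Per-subject cell means, group difference per cell, per-cell significance
#' test on the subject cell means (pooled t, or Tukey HSD when additional
#' groups share the error term), subject-level SE of the difference, and a
#' color index referenced to the control distribution of cell means (mean
#' and 2.5/97.5 percentiles across control subjects).
#'
#' @param group a \linkS4class{CohortStack}.
#' @param controls the control \linkS4class{CohortStack}.
#' @param masks an \linkS4class{EtdrsMasks}.
#' @param alpha significance level, default 0.05.
#' @param method "t" or "tukey".
#' @param otherGroups optional list of further \linkS4class{CohortStack}s
#'   entering the pooled error term for \code{method = "tukey"}.
#' @return A \linkS4class{DeviationGrid} for \code{group} vs
#'   \code{controls}.
#' @export
gaDeviationGrid <- function(group, controls, masks, alpha = 0.05,
                            method = c("t", "tukey"), otherGroups = list()) {
  method <- match.arg(method)
  stacks <- c(list(group, controls), otherGroups)
  ct <- cellTest(stacks, masks, alpha = alpha, method = method)
  lab <- paste(group@groupLabel, "vs", controls@groupLabel)
  ct <- ct[ct$comparison == lab, , drop = FALSE]
  cmG <- subjectCellMeans(group, masks)
  cmC <- subjectCellMeans(controls, masks)
  dev <- rowMeans(cmG) - rowMeans(cmC)
  sev <- sqrt(apply(cmG, 1L, stats::var) / ncol(cmG) +
              apply(cmC, 1L, stats::var) / ncol(cmC))
  # control distribution of cell means -> cell-level reference for coloring
  cMean <- rowMeans(cmC)
  cQ <- t(apply(cmC, 1L, stats::quantile, probs = c(0.025, 0.975),
                type = 7, names = FALSE))
  ci <- encodeColor(dev, cMean, cQ[, 1L], cQ[, 2L])
  tb <- data.frame(cell = masks@cellNames,
                   deviation_um = as.numeric(dev),
                   SE_um = as.numeric(sev),
                   p = ct$p[match(masks@cellNames, ct$cell)],
                   significant = ct$significant[match(masks@cellNames, ct$cell)],
                   color_index = as.numeric(ci),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("DeviationGrid", table = tb, comparison = lab, alpha = alpha,
      method = method)
}

#' Pair GA cells with MA fraction measurements
#'
#' Produces the per-cell records behind the MD +/- SE comparison plots: each
#' ETDRS cell's GA deviation +/- SE next to the MA fraction measurement of
#' the same cell (absent — NA — where no fraction passed the coverage
#' threshold). When a cell holds passed fractions of both signs, the one
#' with more points is paired and the sign is recorded.
#'
#' @param grid a \linkS4class{DeviationGrid}.
#' @param fractions data.frame from [measureFractions()].
#' @param comparison optional label; must match the grid's if supplied.
#' @return data.frame with columns \code{cell}, \code{ga_dev_um},
#'   \code{ga_se_um}, \code{ga_sig}, \code{ma_md_um}, \code{ma_se_um},
#'   \code{ma_coverage_pct}, \code{ma_sign}, \code{ma_n_points}.
#' @export
compareGaMa <- function(grid, fractions, comparison = NULL) {
  if (!is.null(comparison) && !identical(comparison, grid@comparison))
    stop("comparison label mismatch: grid is '", grid@comparison, "'")
  tb <- grid@table
  out <- data.frame(cell = tb$cell, ga_dev_um = tb$deviation_um,
                    ga_se_um = tb$SE_um, ga_sig = tb$significant,
                    ma_md_um = NA_real_, ma_se_um = NA_real_,
                    ma_coverage_pct = NA_real_, ma_sign = NA_integer_,
                    ma_n_points = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)
  fr <- fractions[fractions$passed_threshold, , drop = FALSE]
  if (nrow(fr)) {
    fr <- fr[order(fr$cell, -fr$n_points), , drop = FALSE]
    fr <- fr[!duplicated(fr$cell), , drop = FALSE]
    i <- match(fr$cell, out$cell)
    out$ma_md_um[i] <- fr$MD_um
    out$ma_se_um[i] <- fr$SE_um
    out$ma_coverage_pct[i] <- fr$coverage_pct
    out$ma_sign[i] <- fr$sign
    out$ma_n_points[i] <- fr$n_points
  }
  out
}
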