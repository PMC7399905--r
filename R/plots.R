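.DIVERGING <- c("#053061", "#2166ac", "#4393c3", "#92c5de", "#d1e5f0",
                "#ffffff", "#fddbc7", "#f4a582", "#d6604d", "#b2182b",
                "#67001f")

# map color indices in [-1, 1] to the diverging blue-white-red palette
.divergingColors <- function(ci, nShades = 255L) {
  pal <- grDevices::colorRampPalette(.DIVERGING)(nShades)
  idx <- round((pmax(-1, pmin(1, ci)) + 1) / 2 * (nShades - 1L)) + 1L
  out <- rep(NA_character_, length(ci))
  ok <- is.finite(ci)
  out[ok] <- pal[idx[ok]]
  out
}

# boundary points of a logical mask (TRUE points with a FALSE/edge 4-neighbor)
.maskOutline <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

.drawEtdrsOutline <- function(col = "grey30", lwd = 1) {
  th <- seq(0, 2 * pi, length.out = 241L)
  for (R in c(0.5, 1.5, 3.0))
    graphics::lines(R * cos(th), R * sin(th), col = col, lwd = lwd)
  for (a in c(45, 135, 225, 315) * pi / 180) {
    graphics::segments(0.5 * cos(a), 0.5 * sin(a),
                       3.0 * cos(a), 3.0 * sin(a), col = col, lwd = lwd)
  }
}

#' Render a deviation map (DevM) to PNG
#'
#' Diverging blue-white-red image of the normalized color index (white =
#' at the control mean, darkest shades at/beyond the control percentile
#' interval), with the significance mask outlined in black, the ETDRS grid
#' overlaid, and optional regions of interest circled in green.
#'
#' @param dev a \linkS4class{DeviationResult}.
#' @param file output PNG path.
#' @param masks optional \linkS4class{EtdrsMasks} for the grid overlay.
#' @param rois optional list of logical ROI matrices, outlined in green.
#' @param widthPx,heightPx PNG size.
#' @return \code{file}, invisibly.
#' @export
plotDeviationMap <- function(dev, file, masks = NULL, rois = NULL,
                             widthPx = 700L, heightPx = 700L) {
  n <- nPoints(dev@lattice)
  co <- latticeCoords(dev@lattice)
  xs <- co$x[1L, ]; ys <- rev(co$y[, 1L])
  grDevices::png(file, widthPx, heightPx)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 2, 1))
  # image() wants x ascending and z[i,j] at x[i], y[j]
  z <- t(dev@colorIndex)[, n:1]
  zcol <- matrix(.divergingColors(as.vector(z)), n, n)
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                 xlab = "temporal - nasal (mm)", ylab = "inferior - superior (mm)",
                 main = paste("DevM:", dev@comparison))
  graphics::rasterImage(grDevices::as.raster(t(zcol)[n:1, ]),
                        min(xs), min(ys), max(xs), max(ys),
                        interpolate = FALSE)
  outline <- .maskOutline(dev@sig)
  if (any(outline))
    graphics::points(co$x[outline], co$y[outline], pch = ".", col = "black",
                     cex = 1.4)
  if (!is.null(masks)) .drawEtdrsOutline()
  if (!is.null(rois)) {
    for (roi in rois) {
      ol <- .maskOutline(roi)
      graphics::points(co$x[ol], co$y[ol], pch = ".", col = "green3",
                       cex = 2)
    }
  }
  invisible(file)
}

#' Render a GA deviation grid to PNG
#'
#' ETDRS grid schematic with each cell filled by its deviation color,
#' significant cells marked with orange borders and black labels (the
#' conventional grid-report style); labels show the cell deviation in um.
#'
#' @param grid a \linkS4class{DeviationGrid}.
#' @param masks the \linkS4class{EtdrsMasks} used for the analysis.
#' @param file output PNG path.
#' @param widthPx,heightPx PNG size.
#' @return \code{file}, invisibly.
#' @export
plotDeviationGrid <- function(grid, masks, file, widthPx = 700L,
                              heightPx = 700L) {
  tb <- grid@table
  n <- nPoints(masks@lattice)
  co <- latticeCoords(masks@lattice)
  cellCol <- .divergingColors(tb$color_index)
  field <- matrix(NA_character_, n, n)
  for (i in 1:9) field[masks@labels == i] <- cellCol[i]
  grDevices::png(file, widthPx, heightPx)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 2, 1))
  xs <- co$x[1L, ]; ys <- rev(co$y[, 1L])
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                 xlab = "temporal - nasal (mm)", ylab = "inferior - superior (mm)",
                 main = paste("GA grid:", grid@comparison))
  rast <- field; rast[is.na(rast)] <- "#f5f5f5"
  graphics::rasterImage(grDevices::as.raster(rast), min(xs), min(ys),
                        max(xs), max(ys), interpolate = FALSE)
  .drawEtdrsOutline()
  # orange borders on significant cells
  for (i in which(tb$significant)) {
    ol <- .maskOutline(masks@labels == i)
    graphics::points(co$x[ol], co$y[ol], pch = ".", col = "orange",
                     cex = 2.5)
  }
  for (i in 1:9) {
    m <- masks@labels == i
    graphics::text(mean(co$x[m]), mean(co$y[m]),
                   sprintf("%s\n%.1f", tb$cell[i], tb$deviation_um[i]),
                   cex = 0.8, col = "black")
  }
  invisible(file)
}

#' Paired GA-versus-MA MD +/- SE bar plot
#'
#' One bar pair per ETDRS cell: the GA cell deviation and the MA fraction
#' MD, each with an SE whisker; cells without a passed MA fraction show
#' only the GA bar.
#'
#' @param cmp data.frame from [compareGaMa()].
#' @param file output PNG path.
#' @param widthPx,heightPx PNG size.
#' @return \code{file}, invisibly.
#' @export
plotMdSeComparison <- function(cmp, file, widthPx = 900L, heightPx = 500L) {
  grDevices::png(file, widthPx, heightPx)
  on.exit(grDevices::dev.off())
  h <- rbind(cmp$ga_dev_um, cmp$ma_md_um)
  se <- rbind(cmp$ga_se_um, cmp$ma_se_um)
  graphics::par(mar = c(8, 4, 2, 1))
  bp <- graphics::barplot(h, beside = TRUE, names.arg = cmp$cell,
                          las = 2, col = c("grey70", "steelblue"),
                          ylab = "MD (um)",
                          ylim = range(0, h + 2 * se, h - 2 * se,
                                       na.rm = TRUE),
                          legend.text = c("GA", "MA"))
  ok <- is.finite(h) & is.finite(se)
  graphics::arrows(bp[ok], (h - se)[ok], bp[ok], (h + se)[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0)
  invisible(file)
}
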