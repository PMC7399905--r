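#' Write a thickness map in the plain-text exchange format
#'
#' The exchange format is a plain-text file with five header lines
#' (\code{subject=}, \code{layer=}, \code{eye=}, \code{extent_mm=},
#' \code{spacing_mm=}) followed by the dense numeric grid, one lattice row
#' per line, whitespace-separated, \code{NaN} for invalid points. Values are
#' written with full precision (\code{format C "\%.17g"}) so the
#' reader/writer round trip is bit-stable for finite values.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeThicknessMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("subject=", map@subjectId),
               paste0("layer=", map@layer),
               paste0("eye=", map@eye),
               paste0("extent_mm=", format(map@lattice@extentMm, digits = 17)),
               paste0("spacing_mm=", format(map@lattice@spacingMm, digits = 17))),
             con)
  v <- map@values
  v[!map@mask] <- NA_real_
  txt <- apply(v, 1L, function(row) {
    s <- sprintf("%.17g", row)
    s[!is.finite(row)] <- "NaN"
    paste(s, collapse = " ")
  })
  writeLines(txt, con)
  invisible(path)
}

#' Read a thickness map from the exchange format
#'
#' @param path file written by [writeThicknessMap()] (or any conforming
#'   producer).
#' @return A \linkS4class{ThicknessMap}.
#' @export
readThicknessMap <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:5]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  need <- c("subject", "layer", "eye", "extent_mm", "spacing_mm")
  if (!identical(keys, need))
    stop("malformed exchange header; expected keys: ",
         paste(need, collapse = ", "))
  lat <- macularLattice(extentMm = as.numeric(vals[4L]),
                        spacingMm = as.numeric(vals[5L]))
  n <- nPoints(lat)
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop(sprintf("expected %d grid rows, found %d", n, length(body)))
  rows <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1L]]))
  if (any(lengths(rows) != n)) stop("ragged grid rows in exchange file")
  v <- do.call(rbind, rows)
  thicknessMap(v, subjectId = vals[1L], layer = vals[2L], eye = vals[3L],
               lattice = lat)
}

#' Write a numeric or integer field in the exchange grid layout
#'
#' Utility for exporting derived fields (deviation, p-values, masks, ETDRS
#' labels) in the same dense-grid text layout, with a minimal header.
#'
#' @param field numeric or integer matrix.
#' @param path output file path.
#' @param lattice the \linkS4class{MacularLattice} of the field.
#' @param what short content label written into the header.
#' @return \code{path}, invisibly.
#' @export
writeFieldGrid <- function(field, path, lattice, what = "field") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("field=", what),
               paste0("extent_mm=", format(lattice@extentMm, digits = 17)),
               paste0("spacing_mm=", format(lattice@spacingMm, digits = 17))),
             con)
  txt <- apply(field, 1L, function(row) {
    s <- sprintf("%.17g", as.numeric(row))
    s[!is.finite(as.numeric(row))] <- "NaN"
    paste(s, collapse = " ")
  })
  writeLines(txt, con)
  invisible(path)
}

#' Write a cohort manifest CSV
#'
#' @param manifest data.frame with columns \code{subject_id}, \code{group},
#'   \code{eye}, \code{file}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' @param path CSV with columns \code{subject_id}, \code{group}, \code{eye},
#'   \code{file} (paths relative to the manifest's directory or absolute).
#' @return data.frame with those columns; \code{file} resolved to absolute
#'   paths.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "eye", "file")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m$file[rel] <- file.path(dirname(normalizePath(path)), m$file[rel])
  m
}

#' Load cohorts listed in a manifest
#'
#' Reads every map, canonicalizes laterality to the OD frame, and assembles
#' one \linkS4class{CohortStack} per group label. All files of one call must
#' hold the same layer on the same lattice.
#'
#' @param manifest data.frame as returned by [readManifest()].
#' @param groups optional character vector restricting/ordering the groups.
#' @return Named list of \linkS4class{CohortStack}.
#' @export
loadCohorts <- function(manifest, groups = NULL) {
  if (is.null(groups)) groups <- unique(manifest$group)
  missing <- setdiff(groups, manifest$group)
  if (length(missing))
    stop("groups absent from manifest: ", paste(missing, collapse = ", "))
  out <- lapply(groups, function(g) {
    rows <- manifest[manifest$group == g, , drop = FALSE]
    maps <- lapply(seq_len(nrow(rows)), function(i) {
      mp <- readThicknessMap(rows$file[i])
      if (!identical(mp@eye, rows$eye[i]))
        stop(sprintf("eye mismatch for subject %s: manifest says %s, file says %s",
                     rows$subject_id[i], rows$eye[i], mp@eye))
      canonicalizeLaterality(mp)
    })
    buildCohort(maps, groupLabel = g)
  })
  names(out) <- groups
  out
}
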