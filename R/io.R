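#' @include enrichgraph.R
NULL

.writeTsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], .sigfmt, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write / read plate layouts as TSV
#'
#' Flat layout interchange: columns plate_id, row, col, gene_id,
#' source_plate_id, source_row, source_col, replicate_index; an empty gene_id
#' marks a blank position. All plates go into one file; the format of each
#' plate is inferred from its grid extent.
#'
#' @param layouts list of [PlateLayout-class] objects
#' @param path TSV file
#' @return `path` invisibly (write); list of [PlateLayout-class] (read)
#' @export
writeLayoutTsv <- function(layouts, path) {
  df <- do.call(rbind, lapply(layouts, function(l)
    cbind(plate_id = plateId(l), layoutEntries(l))))
  .writeTsv(df, path)
}

#' @rdname writeLayoutTsv
#' @export
readLayoutTsv <- function(path) {
  df <- .readTsv(path)
  lapply(split(df, df$plate_id), function(d) {
    fmt <- if (max(d$row) < 16 && max(d$col) < 24) 384L else 1536L
    plateLayout(d$plate_id[1], fmt, d[, .layoutCols])
  })
}

#' Write / read a synthetic ground truth table as TSV
#'
#' Gene-effect interchange: gene_id, pigment_effect, fitness_effect,
#' planted_group. Only the gene effects travel through this format; biases
#' and contamination stay with the [SyntheticTruth-class] object.
#'
#' @param truth a [SyntheticTruth-class]
#' @param path TSV file
#' @return `path` invisibly (write); the gene-effect data.frame (read)
#' @export
writeTruthTsv <- function(truth, path) {
  .writeTsv(geneEffects(truth), path, digits = 10)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) .readTsv(path)

#' Write / read colony measurement tables as TSV
#'
#' @param records colony-record data.frame (any pipeline stage)
#' @param path TSV file
#' @param digits significant digits for floating-point columns (default 6,
#'   the pipeline's canonical TSV precision)
#' @return `path` invisibly (write); data.frame (read)
#' @export
writeMeasurementsTsv <- function(records, path, digits = 6) {
  .writeTsv(records, path, digits = digits)
}

#' @rdname writeMeasurementsTsv
#' @export
readMeasurementsTsv <- function(path) .readTsv(path)

#' Write / read gene summaries as TSV
#'
#' @param summaries gene-summary data.frame ([combineScreens()] /
#'   [callHits()])
#' @param path TSV file
#' @return `path` invisibly (write); data.frame (read)
#' @export
writeGeneSummariesTsv <- function(summaries, path) .writeTsv(summaries, path)

#' @rdname writeGeneSummariesTsv
#' @export
readGeneSummariesTsv <- function(path) .readTsv(path)

#' Write / read a plate image
#'
#' 8-bit RGB PNG (default) or TIFF, one file per plate. Reading requires the
#' grid geometry, which the image file does not carry.
#'
#' @param image a [PlateImage-class]
#' @param path output file; extension selects the format (.png or
#'   .tif/.tiff)
#' @return `path` invisibly (write); a [PlateImage-class] (read)
#' @export
writePlateImage <- function(image, path) {
  arr <- pixelData(image) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname writePlateImage
#' @param geom the [GridGeometry-class] of the plate grid
#' @param plateId plate label; default is the file name without extension
#' @export
readPlateImage <- function(path, geom, plateId = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path) else
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
      stop("unsupported image format: ", ext)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3]
  if (is.null(plateId))
    plateId <- sub("^.*_", "", tools::file_path_sans_ext(basename(path)))
  new("PlateImage", pixels = round(arr * 255), geometry = geom,
      plateId = plateId,
      meta = data.frame())
}

#' Read a gene-to-term annotation TSV
#'
#' One row per (term, gene) pair: columns term_id, description, gene_id.
#' Optional is-a parents come either from a two-column TSV (term_id,
#' parent_id) or from [readOboSubset()].
#'
#' @param path annotation TSV
#' @param parentsPath optional parent TSV
#' @return an [AnnotationSet-class]
#' @export
readAnnotationTsv <- function(path, parentsPath = NULL) {
  df <- .readTsv(path)
  terms <- unique(df[, c("term_id", "description")])
  geneSets <- lapply(split(df$gene_id, df$term_id), unique)
  parents <- list()
  if (!is.null(parentsPath)) {
    pf <- .readTsv(parentsPath)
    parents <- lapply(split(pf$parent_id, pf$term_id), unique)
  }
  annotationSet(terms[order(terms$term_id), ],
                geneSets[sort(names(geneSets))], parents)
}

#' Minimal OBO stanza reader (id / name / is_a only)
#'
#' Parses `[Term]` stanzas of an OBO file, keeping only the `id:`, `name:`
#' and `is_a:` tags - enough to supply term descriptions and the acyclic
#' parent mapping used for ancestor-based coloring. Obsolete-term handling,
#' relationship types beyond is_a and all other tags are out of scope.
#'
#' @param path OBO file
#' @return list with `terms` (data.frame term_id, description) and `parents`
#'   (named list of parent ids)
#' @export
readOboSubset <- function(path) {
  lines <- readLines(path)
  terms <- data.frame(term_id = character(), description = character(),
                      stringsAsFactors = FALSE)
  parents <- list()
  cur <- NULL; curName <- NA_character_; curIsa <- character()
  inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      terms <<- rbind(terms, data.frame(term_id = cur, description = curName,
                                        stringsAsFactors = FALSE))
      if (length(curIsa)) parents[[cur]] <<- curIsa
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; curName <- NA; curIsa <- character(); inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) curName <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:"))
      curIsa <- c(curIsa, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
  }
  flush()
  list(terms = terms, parents = parents)
}
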