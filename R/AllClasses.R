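#' @include AllGenerics.R
NULL

# Supported array formats: rows x cols.
.FORMATS <- list(`384` = c(16L, 24L), `1536` = c(32L, 48L))

#' Colony-grid geometry of a plate image
#'
#' Pins the colony array to pixel space: number of grid rows/columns, the pixel
#' pitch between neighbouring cell centers, and the pixel coordinates of the
#' top-left cell center. Grid coordinates are 0-based, row-major, with row 0 at
#' the top of the image.
#'
#' @slot nRows integer, colony rows (16 for 384 format, 32 for 1536)
#' @slot nCols integer, colony columns (24 for 384 format, 48 for 1536)
#' @slot cellPx integer, pixel pitch per grid cell (>= 8)
#' @slot originPx numeric length-2, (y, x) pixel coordinates of the top-left
#'   cell center (0-based pixel coordinates)
#' @export
setClass("GridGeometry",
  representation(nRows = "integer", nCols = "integer",
                 cellPx = "integer", originPx = "numeric"),
  validity = function(object) {
    fmt <- object@nRows * object@nCols
    key <- as.character(fmt)
    if (!key %in% names(.FORMATS))
      return("nRows*nCols must be 384 or 1536")
    if (!identical(c(object@nRows, object@nCols), .FORMATS[[key]]))
      return(sprintf("format %d requires a %dx%d grid", fmt,
                     .FORMATS[[key]][1], .FORMATS[[key]][2]))
    if (object@cellPx < 8L) return("cellPx must be >= 8")
    if (length(object@originPx) != 2L || any(object@originPx < 0))
      return("originPx must be two non-negative pixel coordinates")
    TRUE
  })

#' Construct a GridGeometry
#'
#' @param format array format, 384 or 1536
#' @param cellPx pixel pitch per cell (default 12)
#' @param originPx (y, x) of the top-left cell center; default centers the grid
#'   with a half-pitch margin
#' @return a [GridGeometry-class] object
#' @examples
#' gridGeometry(1536, cellPx = 10)
#' @export
gridGeometry <- function(format = 1536, cellPx = 12L, originPx = NULL) {
  key <- as.character(format)
  if (!key %in% names(.FORMATS)) stop("format must be 384 or 1536")
  dims <- .FORMATS[[key]]
  cellPx <- as.integer(cellPx)
  if (is.null(originPx)) originPx <- rep(cellPx / 2, 2L)
  new("GridGeometry", nRows = dims[1], nCols = dims[2], cellPx = cellPx,
      originPx = as.numeric(originPx))
}

#' @rdname crispa-generics
#' @export
setMethod("plateFormat", "GridGeometry", function(x) x@nRows * x@nCols)

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d format (%dx%d), %d px pitch, origin (%g, %g)\n",
              plateFormat(object), object@nRows, object@nCols, object@cellPx,
              object@originPx[1], object@originPx[2]))
})

# image height/width implied by a geometry (half-pitch margin on each side)
.imageDims <- function(geom) {
  h <- ceiling(geom@originPx[1] + (geom@nRows - 1L) * geom@cellPx + geom@cellPx / 2)
  w <- ceiling(geom@originPx[2] + (geom@nCols - 1L) * geom@cellPx + geom@cellPx / 2)
  c(h, w)
}

.layoutCols <- c("row", "col", "gene_id", "source_plate_id",
                 "source_row", "source_col", "replicate_index")

#' Plate layout: position-to-gene mapping
#'
#' One arrayed plate's mapping from 0-based (row, col) grid positions to gene
#' identifiers, with source-plate provenance for 1536-format screen plates
#' assembled from 384-format library plates. Blank positions carry
#' `NA` gene identifiers. On a 1536 plate every entry satisfies
#' `row == 2*source_row + dr`, `col == 2*source_col + dc` with interleave
#' offset `(dr, dc)` in {0,1}^2.
#'
#' @slot plateId character plate label
#' @slot format integer, 384 or 1536
#' @slot entries data.frame with columns row, col, gene_id, source_plate_id,
#'   source_row, source_col, replicate_index (1-4)
#' @export
setClass("PlateLayout",
  representation(plateId = "character", format = "integer",
                 entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    if (!all(.layoutCols %in% names(e)))
      return(paste("entries must have columns:", paste(.layoutCols, collapse = ", ")))
    if (anyDuplicated(e[, c("row", "col")]))
      return("duplicated (row, col) positions")
    key <- as.character(object@format)
    if (!key %in% names(.FORMATS)) return("format must be 384 or 1536")
    dims <- .FORMATS[[key]]
    if (nrow(e) && (any(e$row < 0 | e$row >= dims[1]) ||
                    any(e$col < 0 | e$col >= dims[2])))
      return("entries outside the plate grid")
    if (object@format == 1536L) {
      filled <- !is.na(e$gene_id) & !is.na(e$source_row)
      dr <- e$row[filled] - 2L * e$source_row[filled]
      dc <- e$col[filled] - 2L * e$source_col[filled]
      if (length(dr) && (any(!dr %in% 0:1) || any(!dc %in% 0:1)))
        return("1536 positions must interleave source positions at 2x2 offsets")
    }
    TRUE
  })

plateLayout <- function(plateId, format, entries) {
  entries <- entries[order(entries$row, entries$col), , drop = FALSE]
  rownames(entries) <- NULL
  new("PlateLayout", plateId = as.character(plateId),
      format = as.integer(format), entries = entries)
}

#' @rdname crispa-generics
#' @export
setMethod("plateId", "PlateLayout", function(x) x@plateId)

#' @rdname crispa-generics
#' @export
setMethod("plateFormat", "PlateLayout", function(x) x@format)

#' @rdname crispa-generics
#' @export
setMethod("layoutEntries", "PlateLayout", function(x) x@entries)

setMethod("show", "PlateLayout", function(object) {
  e <- object@entries
  cat(sprintf("PlateLayout '%s': %d format, %d/%d positions filled\n",
              object@plateId, object@format, sum(!is.na(e$gene_id)), nrow(e)))
})

#' Ground truth of a synthetic screen
#'
#' Planted per-gene pigment and fitness effects (z-scale), multiplicative plate
#' and edge-ring biases, and the contaminated/missing colony lists, all
#' reproducible from the stored seed.
#'
#' @slot geneEffects data.frame: gene_id, pigment_effect, fitness_effect,
#'   planted_group (bulk/yellow/white)
#' @slot plateBias named numeric, multiplicative factor per plate
#' @slot edgeBias numeric, multiplicative factor per outer frame ring
#'   (element 1 = outermost)
#' @slot contamination data.frame: plate_id, row, col, white_fraction in [0,1]
#' @slot missing data.frame: plate_id, row, col
#' @slot params list of generator parameters (see [truthParams()])
#' @slot seed integer seed the truth was drawn with
#' @export
setClass("SyntheticTruth",
  representation(geneEffects = "data.frame", plateBias = "numeric",
                 edgeBias = "numeric", contamination = "data.frame",
                 missing = "data.frame", params = "list", seed = "integer"),
  validity = function(object) {
    g <- object@geneEffects
    if (!all(c("gene_id", "pigment_effect", "fitness_effect", "planted_group")
             %in% names(g)))
      return("geneEffects must have gene_id, pigment_effect, fitness_effect, planted_group")
    if (nrow(object@contamination) &&
        (any(object@contamination$white_fraction < 0) ||
         any(object@contamination$white_fraction > 1)))
      return("white_fraction must lie in [0,1]")
    TRUE
  })

#' @rdname crispa-generics
#' @export
setMethod("geneEffects", "SyntheticTruth", function(x) x@geneEffects)

setMethod("show", "SyntheticTruth", function(object) {
  g <- object@geneEffects
  cat(sprintf(paste0("SyntheticTruth: %d genes (%d yellow, %d white planted), ",
                     "%d contaminated, %d missing, seed %d\n"),
              nrow(g), sum(g$planted_group == "yellow"),
              sum(g$planted_group == "white"),
              nrow(object@contamination), nrow(object@missing), object@seed))
})

#' RGB plate image
#'
#' 8-bit RGB pixel grid of one plate photograph together with its colony-grid
#' geometry. Pixel values are stored as numbers in 0..255; the background is
#' darker than any colony foreground under the default renderer.
#'
#' @slot pixels H x W x 3 numeric array of 8-bit values
#' @slot geometry the [GridGeometry-class]
#' @slot plateId character plate label
#' @slot meta data.frame of renderer bookkeeping (one row per drawn colony),
#'   empty for images read from disk
#' @export
setClass("PlateImage",
  representation(pixels = "array", geometry = "GridGeometry",
                 plateId = "character", meta = "data.frame"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L) return("pixels must be H x W x 3")
    if (any(object@pixels < 0) || any(object@pixels > 255))
      return("pixel values must lie in 0..255")
    geom <- object@geometry
    maxy <- geom@originPx[1] + (geom@nRows - 1L) * geom@cellPx
    maxx <- geom@originPx[2] + (geom@nCols - 1L) * geom@cellPx
    if (maxy > d[1] - 1 || maxx > d[2] - 1)
      return("cell centers fall outside the image")
    TRUE
  })

#' @rdname crispa-generics
#' @export
setMethod("plateId", "PlateImage", function(x) x@plateId)

#' @rdname crispa-generics
#' @export
setMethod("geometry", "PlateImage", function(x) x@geometry)

#' @rdname crispa-generics
#' @export
setMethod("pixelData", "PlateImage", function(x) x@pixels)

setMethod("show", "PlateImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PlateImage '%s': %dx%d px, %d format grid\n",
              object@plateId, d[1], d[2], plateFormat(object@geometry)))
})

#' Colony masks of one segmented plate
#'
#' Pixel-to-colony assignment stored as an integer label matrix: 0 marks
#' background, label `k` marks the colony in grid cell `k` (row-major,
#' `k = row * nCols + col + 1`). Labels of distinct colonies are disjoint by
#' construction and every labelled pixel lies within one cell pitch of its
#' cell center.
#'
#' @slot labels integer H x W matrix
#' @slot geometry the [GridGeometry-class]
#' @slot plateId character
#' @slot threshold numeric, the foreground threshold used (grayscale 0..1)
#' @export
setClass("ColonyMasks",
  representation(labels = "matrix", geometry = "GridGeometry",
                 plateId = "character", threshold = "numeric"))

#' @rdname crispa-generics
#' @export
setMethod("maskLabels", "ColonyMasks", function(x) x@labels)

#' @rdname crispa-generics
#' @export
setMethod("geometry", "ColonyMasks", function(x) x@geometry)

#' @rdname crispa-generics
#' @export
setMethod("plateId", "ColonyMasks", function(x) x@plateId)

setMethod("show", "ColonyMasks", function(object) {
  cat(sprintf("ColonyMasks '%s': %d foreground px over %d occupied cells (threshold %.3f)\n",
              object@plateId, sum(object@labels > 0),
              length(unique(object@labels[object@labels > 0])), object@threshold))
})

.SCREEN_STATES <- c("raw", "edge_corrected", "normalized")

#' Measurement table of one screen
#'
#' All colony records of a single screen (several 1536 plates), with a
#' normalization state machine: `raw` -> `edge_corrected` (frame-median
#' matching adds `yellowness_corrected`, `size_corrected`) -> `normalized`
#' (screen z-scores add `z_yellow`, `z_size`). In the normalized state the
#' z-columns have mean ~0 and sd ~1 over non-missing records.
#'
#' @slot screenId character
#' @slot records data.frame with at least plate_id, row, col, size_px,
#'   yellowness_raw, flags
#' @slot state one of raw, edge_corrected, normalized
#' @export
setClass("ScreenTable",
  representation(screenId = "character", records = "data.frame",
                 state = "character"),
  validity = function(object) {
    if (!object@state %in% .SCREEN_STATES)
      return("state must be raw, edge_corrected or normalized")
    need <- c("plate_id", "row", "col", "size_px", "yellowness_raw")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (object@state %in% c("edge_corrected", "normalized") &&
        !all(c("yellowness_corrected", "size_corrected") %in% names(object@records)))
      return("edge_corrected state requires corrected columns")
    if (object@state == "normalized" &&
        !all(c("z_yellow", "z_size") %in% names(object@records)))
      return("normalized state requires z columns")
    TRUE
  })

#' Construct a ScreenTable from colony records
#'
#' @param screenId screen label
#' @param records colony-record data.frame (from [scorePlate()], one or more
#'   plates row-bound)
#' @param state normalization state, default `"raw"`
#' @return a [ScreenTable-class]
#' @export
screenTable <- function(screenId, records, state = "raw") {
  if (!"flags" %in% names(records)) records$flags <- ""
  new("ScreenTable", screenId = as.character(screenId),
      records = records, state = state)
}

#' @rdname crispa-generics
#' @export
setMethod("screenId", "ScreenTable", function(x) x@screenId)

#' @rdname crispa-generics
#' @export
setMethod("screenRecords", "ScreenTable", function(x) x@records)

#' @rdname crispa-generics
#' @export
setMethod("normState", "ScreenTable", function(x) x@state)

setMethod("show", "ScreenTable", function(object) {
  r <- object@records
  cat(sprintf("ScreenTable '%s' [%s]: %d records on %d plates (%d missing)\n",
              object@screenId, object@state, nrow(r),
              length(unique(r$plate_id)), sum(r$size_px == 0)))
})

#' Gene-to-term annotation set
#'
#' Term descriptions, their associated gene sets, and an optional acyclic
#' is-a parent mapping used for ancestor-based coloring of term graphs.
#'
#' @slot terms data.frame: term_id, description
#' @slot geneSets named list of character gene-id vectors (names = term_id)
#' @slot parents named list of character parent term-id vectors
#' @export
setClass("AnnotationSet",
  representation(terms = "data.frame", geneSets = "list", parents = "list"),
  validity = function(object) {
    if (!all(c("term_id", "description") %in% names(object@terms)))
      return("terms must have term_id and description")
    if (!setequal(names(object@geneSets), object@terms$term_id))
      return("geneSets names must match term_id")
    if (any(lengths(object@geneSets) == 0))
      return("gene sets must be nonempty")
    if (length(object@parents)) {
      # acyclicity: repeated parent expansion must terminate
      g <- igraph::graph_from_data_frame(
        data.frame(from = rep(names(object@parents), lengths(object@parents)),
                   to = unlist(object@parents, use.names = FALSE)),
        directed = TRUE)
      if (!igraph::is_dag(g)) return("parent mapping must be acyclic")
    }
    TRUE
  })

#' Construct an AnnotationSet
#'
#' @param terms data.frame with term_id, description
#' @param geneSets named list of gene-id vectors
#' @param parents optional named list of parent term ids
#' @return an [AnnotationSet-class]
#' @export
annotationSet <- function(terms, geneSets, parents = list()) {
  new("AnnotationSet", terms = terms, geneSets = geneSets, parents = parents)
}

#' @rdname crispa-generics
#' @export
setMethod("termInfo", "AnnotationSet", function(x) x@terms)

#' @rdname crispa-generics
#' @export
setMethod("termGenes", "AnnotationSet", function(x, ...) {
  args <- list(...)
  if (length(args)) x@geneSets[[args[[1]]]] else x@geneSets
})

#' @rdname crispa-generics
#' @export
setMethod("termParents", "AnnotationSet", function(x) x@parents)

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d terms, %d gene-term links, parents for %d terms\n",
              nrow(object@terms), sum(lengths(object@geneSets)),
              length(object@parents)))
})
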