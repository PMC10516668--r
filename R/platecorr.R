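#' @include imgquant.R
NULL

#' Edge (outer-frame) correction of a screen
#'
#' High-density colony arrays grow systematically larger/brighter colonies
#' near the plate border. Per plate and per frame ring `r` (ring 0 outermost;
#' ring = minimum grid distance to the border), every value in the ring is
#' multiplied by `median(center) / median(ring r)`, where the center is all
#' colonies at border distance >= `nFrames`. Missing colonies are ignored when
#' computing medians; rings whose median is zero or undefined are left
#' uncorrected with a warning. After correction the median of every corrected
#' ring equals the center median, and reapplying the correction is a no-op.
#'
#' @param table a [ScreenTable-class] in `raw` state
#' @param nFrames number of outer frame rings to correct (default 2)
#' @param metric which measurements to correct: `"both"` (default),
#'   `"yellowness"` or `"size"`
#' @param pooled correct all `nFrames` rings as one pooled outer zone instead
#'   of per ring
#' @return the table in `edge_corrected` state with `yellowness_corrected`
#'   and `size_corrected` columns
#' @export
edgeCorrect <- function(table, nFrames = 2L, metric = c("both", "yellowness",
                                                        "size"),
                        pooled = FALSE) {
  metric <- match.arg(metric)
  if (normState(table) != "raw")
    stop("edgeCorrect expects a table in raw state")
  r <- screenRecords(table)
  fmt <- max(r$row) < 16  # TRUE -> 384 grid
  dims <- if (fmt) .FORMATS[["384"]] else .FORMATS[["1536"]]
  if (nFrames < 1 || 2 * nFrames >= min(dims))
    stop("nFrames leaves no center region")
  r$yellowness_corrected <- r$yellowness_raw
  r$size_corrected <- as.numeric(r$size_px)
  ring <- .ringOf(r$row, r$col, dims[1], dims[2])
  valid <- !.isMissingRecord(r)
  cols <- switch(metric,
                 both = c("yellowness_corrected", "size_corrected"),
                 yellowness = "yellowness_corrected",
                 size = "size_corrected")
  for (pid in unique(r$plate_id)) {
    onPlate <- r$plate_id == pid
    center <- onPlate & ring >= nFrames & valid
    for (cl in cols) {
      medC <- stats::median(r[[cl]][center])
      if (!sum(center) || is.na(medC)) {
        warning(sprintf("plate %s: no valid center colonies; left uncorrected",
                        pid))
        next
      }
      ringsToFix <- if (pooled) 0L else 0:(nFrames - 1L)
      for (rg in ringsToFix) {
        inRing <- if (pooled) onPlate & ring < nFrames else
          onPlate & ring == rg
        medR <- stats::median(r[[cl]][inRing & valid])
        if (!sum(inRing & valid) || is.na(medR)) {
          warning(sprintf("plate %s ring %d (%s): all missing; left uncorrected",
                          pid, rg, cl))
          next
        }
        if (medR == 0) {
          warning(sprintf("plate %s ring %d (%s): zero median; left uncorrected",
                          pid, rg, cl))
          next
        }
        r[[cl]][inRing] <- r[[cl]][inRing] * (medC / medR)
      }
    }
  }
  new("ScreenTable", screenId = screenId(table), records = r,
      state = "edge_corrected")
}

#' Screen z-normalization
#'
#' Centers and scales each measurement over the whole screen (all plates
#' pooled): `z = (value - screen mean) / screen sd`, with the sample standard
#' deviation (denominator n-1), computed over non-missing colonies, applied
#' independently to yellowness and size. A constant screen (sd = 0) is an
#' error. Normalizing an already-normalized table is the identity.
#'
#' @param table a [ScreenTable-class] in `edge_corrected` (or `normalized`)
#'   state
#' @return the table in `normalized` state with `z_yellow`, `z_size` columns
#' @export
normalizeScreen <- function(table) {
  st <- normState(table)
  if (st == "raw")
    stop("normalizeScreen expects an edge-corrected table")
  r <- screenRecords(table)
  src <- if (st == "normalized") c("z_yellow", "z_size") else
    c("yellowness_corrected", "size_corrected")
  valid <- !.isMissingRecord(r)
  z <- lapply(src, function(cl) {
    v <- r[[cl]]
    mu <- mean(v[valid])
    sdv <- stats::sd(v[valid])
    if (is.na(sdv) || sdv == 0)
      stop("degenerate screen: standard deviation is zero")
    (v - mu) / sdv
  })
  r$z_yellow <- z[[1]]
  r$z_size <- z[[2]]
  new("ScreenTable", screenId = screenId(table), records = r,
      state = "normalized")
}

#' Invert the position randomization
#'
#' Maps every colony record back to its gene through the screen layouts,
#' keying records by `(gene_id, replicate_index)`. Records at blank layout
#' positions are dropped (their count is reported in a message); a record at
#' a position absent from the layouts is an error.
#'
#' @param tables a [ScreenTable-class] or list of them
#' @param layouts list of the screen [PlateLayout-class] objects
#' @return gene-keyed data.frame: screen_id, gene_id, replicate_index,
#'   source_plate_id, plus the measurement columns present in the records
#' @export
derandomize <- function(tables, layouts) {
  if (methods::is(tables, "ScreenTable")) tables <- list(tables)
  lk <- do.call(rbind, lapply(layouts, function(l) {
    e <- layoutEntries(l)
    data.frame(plate_id = plateId(l), row = e$row, col = e$col,
               gene_id = e$gene_id, source_plate_id = e$source_plate_id,
               replicate_index = e$replicate_index, stringsAsFactors = FALSE)
  }))
  out <- lapply(tables, function(tb) {
    r <- screenRecords(tb)
    r$gene_id <- NULL; r$replicate_index <- NULL
    m <- match(paste(r$plate_id, r$row, r$col),
               paste(lk$plate_id, lk$row, lk$col))
    if (anyNA(m))
      stop(sprintf("%d records at positions absent from the layouts",
                   sum(is.na(m))))
    r$gene_id <- lk$gene_id[m]
    r$replicate_index <- lk$replicate_index[m]
    r$source_plate_id <- lk$source_plate_id[m]
    blank <- is.na(r$gene_id)
    if (any(blank))
      message(sprintf("screen %s: dropped %d records at blank positions",
                      screenId(tb), sum(blank)))
    cbind(screen_id = screenId(tb), r[!blank, , drop = FALSE])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
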