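#' @include render.R
NULL

#' Per-pixel yellowness score
#'
#' The pigment readout of a pixel: the geometric mean `sqrt(S * V)` of
#' Saturation and Value in HSV space (both scaled to [0,1]). Under the
#' fixed-yellow-hue assumption this rises with pigment concentration, is 1 for
#' pure saturated bright color, 0 for any gray, and invariant to hue.
#' Saturation is defined 0 when Value is 0.
#'
#' @param r,g,b 8-bit channel values in 0..255 (vectorized)
#' @return numeric yellowness in [0,1]
#' @examples
#' yellownessPixel(255, 255, 0)    # 1
#' yellownessPixel(128, 128, 128)  # 0
#' @export
yellownessPixel <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255))
    stop("channel values must lie in 0..255")
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  unname(sqrt(hsv["s", ] * hsv["v", ]))
}

#' Segment the colony grid of a plate image
#'
#' Foreground is obtained by global intensity thresholding of the grayscale
#' image (Otsu by default); each foreground pixel is assigned to the grid cell
#' whose center is nearest, capped at one cell pitch so a large colony cannot
#' annex a neighbouring cell. Cells without foreground pixels yield empty
#' masks.
#'
#' @param image a [PlateImage-class]
#' @param geom a [GridGeometry-class]; defaults to the image's own
#' @param method `"otsu"` (global Otsu threshold) or `"fixed"`
#' @param threshold grayscale threshold in [0,1] when `method = "fixed"`
#' @return a [ColonyMasks-class]
#' @export
segmentColonies <- function(image, geom = geometry(image),
                            method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- pixelData(image)
  d <- dim(px)
  gd <- .imageDims(geom)
  if (d[1] < gd[1] || d[2] < gd[2])
    stop("image dimensions inconsistent with geometry")
  gray <- .grayscale(px[, , 1], px[, , 2], px[, , 3])
  th <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("fixed method requires a threshold")
    threshold
  }
  fg <- which(gray > th, arr.ind = TRUE)
  labels <- matrix(0L, d[1], d[2])
  if (nrow(fg)) {
    y <- fg[, 1] - 1
    x <- fg[, 2] - 1
    cr <- round((y - geom@originPx[1]) / geom@cellPx)
    cc <- round((x - geom@originPx[2]) / geom@cellPx)
    cr <- pmin(pmax(cr, 0), geom@nRows - 1L)
    cc <- pmin(pmax(cc, 0), geom@nCols - 1L)
    dy <- abs(y - (geom@originPx[1] + cr * geom@cellPx))
    dx <- abs(x - (geom@originPx[2] + cc * geom@cellPx))
    ok <- dy <= geom@cellPx & dx <= geom@cellPx
    labels[fg[ok, , drop = FALSE]] <- as.integer(cr[ok] * geom@nCols + cc[ok] + 1L)
  }
  new("ColonyMasks", labels = labels, geometry = geom,
      plateId = plateId(image), threshold = as.numeric(th))
}

# internal: score one label's pixel set
.scoreCell <- function(rch, gch, bch, filterQuantile, contamSdFlag) {
  n <- length(rch)
  gray <- .grayscale(rch, gch, bch)
  keep <- if (filterQuantile > 0 && n > 1) {
    gray >= stats::quantile(gray, filterQuantile, names = FALSE)
  } else rep(TRUE, n)
  yl <- yellownessPixel(rch[keep], gch[keep], bch[keep])
  flag <- ""
  if (length(yl) > 1 && stats::sd(yl) > contamSdFlag)
    flag <- "contaminated-suspect"
  list(size_px = n, yellowness_raw = mean(yl), flags = flag)
}

#' Score one colony
#'
#' Filters the colony's mask pixels, keeping those whose grayscale intensity
#' lies at or above the given quantile of the mask's intensities (default: the
#' brighter half, excluding dim rim/background bleed), and reports the mean
#' per-pixel yellowness over the retained pixels. Size is the full, unfiltered
#' mask pixel count. An empty mask yields a record with `size_px = 0`, a
#' `missing` flag and no yellowness.
#'
#' @param image a [PlateImage-class]
#' @param masks a [ColonyMasks-class] of the same plate
#' @param row,col 0-based grid position
#' @param filterQuantile intensity quantile below which mask pixels are
#'   dropped before averaging (0 disables the filter)
#' @param contamSdFlag flag the record `contaminated-suspect` when the sd of
#'   retained pixel yellowness exceeds this
#' @return one-row data.frame: plate_id, row, col, size_px, yellowness_raw,
#'   flags
#' @export
scoreColony <- function(image, masks, row, col, filterQuantile = 0.5,
                        contamSdFlag = 0.15) {
  geom <- geometry(masks)
  lab <- as.integer(row * geom@nCols + col + 1L)
  sel <- which(maskLabels(masks) == lab)
  base <- data.frame(plate_id = plateId(image), row = row, col = col,
                     size_px = 0L, yellowness_raw = NA_real_,
                     flags = "missing", stringsAsFactors = FALSE)
  if (!length(sel)) return(base)
  px <- pixelData(image)
  hw <- dim(px)[1] * dim(px)[2]
  sc <- .scoreCell(px[sel], px[sel + hw], px[sel + 2 * hw],
                   filterQuantile, contamSdFlag)
  base$size_px <- sc$size_px
  base$yellowness_raw <- sc$yellowness_raw
  base$flags <- sc$flags
  base
}

#' Score every colony of a plate
#'
#' Applies [scoreColony()] to all grid positions, attaching gene identifiers
#' from a layout when given. Positions with empty masks come back with
#' `size_px = 0` and a `missing` flag.
#'
#' @inheritParams scoreColony
#' @param layout optional [PlateLayout-class] supplying gene_id and
#'   replicate_index per position
#' @return data.frame of colony records, one row per grid cell
#' @export
scorePlate <- function(image, masks, layout = NULL, filterQuantile = 0.5,
                       contamSdFlag = 0.15) {
  geom <- geometry(masks)
  labels <- maskLabels(masks)
  px <- pixelData(image)
  hw <- dim(px)[1] * dim(px)[2]
  ncell <- geom@nRows * geom@nCols
  recs <- data.frame(
    plate_id = plateId(image),
    row = rep(0:(geom@nRows - 1L), each = geom@nCols),
    col = rep(0:(geom@nCols - 1L), times = geom@nRows),
    size_px = 0L, yellowness_raw = NA_real_, flags = "missing",
    stringsAsFactors = FALSE)
  sel <- which(labels > 0)
  if (length(sel)) {
    byCell <- split(sel, labels[sel])
    for (k in names(byCell)) {
      s <- byCell[[k]]
      sc <- .scoreCell(px[s], px[s + hw], px[s + 2 * hw],
                       filterQuantile, contamSdFlag)
      i <- as.integer(k)
      recs$size_px[i] <- sc$size_px
      recs$yellowness_raw[i] <- sc$yellowness_raw
      recs$flags[i] <- sc$flags
    }
  }
  if (!is.null(layout)) {
    e <- layoutEntries(layout)
    m <- match(paste(recs$row, recs$col), paste(e$row, e$col))
    recs$gene_id <- e$gene_id[m]
    recs$replicate_index <- e$replicate_index[m]
  }
  recs
}
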