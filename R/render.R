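#' @include synthgen.R
NULL

#' Renderer parameters
#'
#' The color model follows the fixed-hue assumption of the screen readout: a
#' colony can only take variants of yellow, so Hue is pinned at 1/6 (yellow),
#' Value sits near maximal, and the planted pigment effect drives Saturation
#' through a logistic map. Disc area grows exponentially with the planted
#' fitness effect so radius stays monotone in it.
#'
#' @param background background grayscale level in [0,1] (darker than any
#'   colony foreground)
#' @param value colony HSV Value (near-maximal)
#' @param satSlope logistic slope mapping pigment effect to Saturation
#' @param baseRadiusFrac baseline disc radius as a fraction of the cell pitch
#' @param sizeSlope log-area gain per unit fitness effect
#' @return named list of parameters
#' @export
renderParams <- function(background = 0.15, value = 0.9, satSlope = 0.9,
                         baseRadiusFrac = 0.32, sizeSlope = 0.15) {
  as.list(environment())
}

# quantized RGB triple of a yellow-hue colony pixel (vectorized over S)
.yellowRGB <- function(S, value) {
  v255 <- round(255 * value)
  b <- round(v255 * (1 - S))
  cbind(r = rep(v255, length(S)), g = rep(v255, length(S)), b = b)
}

#' Closed-form yellowness planted by the renderer
#'
#' The yellowness score the scorer recovers from a noise-free, unbiased
#' rendered colony: `sqrt(S * V)` of the colony color after the logistic
#' pigment-to-Saturation map and 8-bit channel quantization. Used as the
#' oracle for scorer/renderer round-trip checks.
#'
#' @param pigment planted pigment effect (z-scale)
#' @param params renderer parameters from [renderParams()]
#' @param quantized include 8-bit quantization (default TRUE); FALSE gives the
#'   ideal continuous `sqrt(S*V)`
#' @return numeric yellowness in [0,1]
#' @export
plantedYellowness <- function(pigment, params = renderParams(),
                              quantized = TRUE) {
  S <- .logistic(params$satSlope * pigment)
  if (!quantized) return(sqrt(S * params$value))
  v255 <- round(255 * params$value)
  b <- round(v255 * (1 - S))
  Sq <- (v255 - b) / v255
  sqrt(Sq * v255 / 255)
}

#' Render a plate image from layout and ground truth
#'
#' Draws each non-missing colony as a filled disc on a uniform dark
#' background. Disc radius is monotone in baseline + fitness effect +
#' plate/edge bias + noise (the biases scale colony area multiplicatively);
#' colony color has fixed yellow hue with Saturation monotone in pigment
#' concentration through the logistic map and near-maximal Value. Contaminated
#' colonies mix in white-colony pixels at their stated fraction. Discs whose
#' radius would exceed the cell pitch are clipped and flagged in the image
#' metadata.
#'
#' @param layout a 1536- or 384-format [PlateLayout-class]
#' @param truth a [SyntheticTruth-class]
#' @param geom a [GridGeometry-class] matching the layout format
#' @param seed integer seed for per-colony noise
#' @param params renderer parameters from [renderParams()]
#' @return a [PlateImage-class]; slot `meta` records per-colony draws
#' @export
renderPlate <- function(layout, truth, geom, seed = 1L,
                        params = renderParams()) {
  if (plateFormat(layout) != plateFormat(geom))
    stop("layout format does not match geometry")
  set.seed(as.integer(seed))
  dims <- .imageDims(geom)
  bg <- round(255 * params$background)
  img <- array(bg, dim = c(dims[1], dims[2], 3L))

  pid <- plateId(layout)
  e <- layoutEntries(layout)
  e <- e[!is.na(e$gene_id), , drop = FALSE]
  eff <- geneEffects(truth)
  idx <- match(e$gene_id, eff$gene_id)
  if (anyNA(idx)) stop("layout genes missing from truth")
  noiseSd <- truth@params$noiseSd

  missKey <- paste(truth@missing$plate_id, truth@missing$row, truth@missing$col)
  contKey <- paste(truth@contamination$plate_id, truth@contamination$row,
                   truth@contamination$col)
  plateFac <- if (pid %in% names(truth@plateBias)) truth@plateBias[[pid]] else 1
  ring <- .ringOf(e$row, e$col, geom@nRows, geom@nCols)
  ringFac <- ifelse(ring < length(truth@edgeBias),
                    truth@edgeBias[pmin(ring + 1L, length(truth@edgeBias))], 1)

  r0 <- params$baseRadiusFrac * geom@cellPx
  rmax <- geom@cellPx / 2 - 1
  n <- nrow(e)
  pigNoise <- stats::rnorm(n, 0, noiseSd)
  sizNoise <- stats::rnorm(n, 0, noiseSd)

  meta <- data.frame(plate_id = pid, row = e$row, col = e$col,
                     gene_id = e$gene_id, radius = NA_real_, S = NA_real_,
                     V = params$value, clipped = FALSE, contaminated = FALSE,
                     missing = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    key <- paste(pid, e$row[i], e$col[i])
    if (key %in% missKey) { meta$missing[i] <- TRUE; next }
    fac <- plateFac * ringFac[i]
    pig <- eff$pigment_effect[idx[i]] + pigNoise[i]
    fit <- eff$fitness_effect[idx[i]] + sizNoise[i]
    # plate/edge bias acts multiplicatively on colony area; color carries
    # only the logistic pigment map (fixed hue, near-maximal value)
    S <- .logistic(params$satSlope * pig)
    area <- pi * r0^2 * exp(params$sizeSlope * fit) * fac
    rad <- sqrt(area / pi)
    if (rad > rmax) { rad <- rmax; meta$clipped[i] <- TRUE }
    cy <- geom@originPx[1] + e$row[i] * geom@cellPx
    cx <- geom@originPx[2] + e$col[i] * geom@cellPx
    ys <- max(0, floor(cy - rad)):min(dims[1] - 1, ceiling(cy + rad))
    xs <- max(0, floor(cx - rad)):min(dims[2] - 1, ceiling(cx + rad))
    dy2 <- (ys - cy)^2
    dx2 <- (xs - cx)^2
    inside <- outer(dy2, dx2, "+") <= rad^2
    npix <- sum(inside)
    if (!npix) next
    rgb <- .yellowRGB(S, params$value)
    px <- matrix(rep(rgb, each = npix), nrow = npix)
    ci <- match(key, contKey)
    if (!is.na(ci)) {
      wf <- truth@contamination$white_fraction[ci]
      white <- stats::runif(npix) < wf
      if (any(white)) {
        wrgb <- .yellowRGB(0, params$value)
        px[white, ] <- matrix(rep(wrgb, each = sum(white)), nrow = sum(white))
      }
      meta$contaminated[i] <- TRUE
    }
    sub <- which(inside, arr.ind = TRUE)
    yy <- ys[sub[, 1]] + 1L
    xx <- xs[sub[, 2]] + 1L
    for (ch in 1:3) img[cbind(yy, xx, ch)] <- px[, ch]
    meta$radius[i] <- rad
    meta$S[i] <- S
  }
  new("PlateImage", pixels = img, geometry = geom, plateId = pid, meta = meta)
}
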