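#' @include utils.R
NULL

#' Generate a 384-format library layout
#'
#' Assigns gene identifiers left-to-right, top-to-bottom across as many
#' 384-position plates as needed; positions beyond the last gene are blank.
#'
#' @param nGenes number of genes (>= 1); ignored if `geneIds` is given
#' @param seed integer seed (kept for interface symmetry; assignment is
#'   deterministic)
#' @param geneIds optional explicit gene identifiers
#' @return list of 384-format [PlateLayout-class] objects
#' @examples
#' lib <- generateLibrary(500)
#' length(lib)  # 2 plates
#' @export
generateLibrary <- function(nGenes, seed = 1L, geneIds = NULL) {
  if (is.null(geneIds)) {
    if (length(nGenes) != 1L || is.na(nGenes) || nGenes < 1)
      stop("nGenes must be >= 1")
    geneIds <- sprintf("g%05d", seq_len(nGenes))
  }
  nGenes <- length(geneIds)
  dims <- .FORMATS[["384"]]
  nPlates <- ceiling(nGenes / 384)
  lapply(seq_len(nPlates), function(p) {
    idx <- ((p - 1L) * 384L + 1L):(p * 384L)
    ids <- ifelse(idx <= nGenes, geneIds[pmin(idx, nGenes)], NA_character_)
    pid <- sprintf("L%02d", p)
    entries <- data.frame(
      row = rep(0:(dims[1] - 1L), each = dims[2]),
      col = rep(0:(dims[2] - 1L), times = dims[1]),
      gene_id = ids,
      source_plate_id = pid,
      source_row = rep(0:(dims[1] - 1L), each = dims[2]),
      source_col = rep(0:(dims[2] - 1L), times = dims[1]),
      replicate_index = NA_integer_,
      stringsAsFactors = FALSE)
    plateLayout(pid, 384L, entries)
  })
}

# empty 384 library plate used for padding
.emptyLibraryPlate <- function(pid) {
  dims <- .FORMATS[["384"]]
  entries <- data.frame(
    row = rep(0:(dims[1] - 1L), each = dims[2]),
    col = rep(0:(dims[2] - 1L), times = dims[1]),
    gene_id = NA_character_, source_plate_id = pid,
    source_row = rep(0:(dims[1] - 1L), each = dims[2]),
    source_col = rep(0:(dims[2] - 1L), times = dims[1]),
    replicate_index = NA_integer_, stringsAsFactors = FALSE)
  plateLayout(pid, 384L, entries)
}

# seeded 4x4 Latin square: rows = library plates in a group,
# cols = screen plates, entry = interleave-offset slot 1..4
.latinSquare4 <- function() {
  base <- outer(0:3, 0:3, function(i, j) (i + j) %% 4L) + 1L
  base[sample(4L), sample(4L)]
}

#' Assemble 1536-format screen plates from a 384-format library
#'
#' Every library plate is pinned in quadruplicate into the 1536 format, each
#' replicate interleaved at one of the four 2x2 offsets
#' `(dr, dc) in {0,1}^2`, so a source position `(r, c)` lands at
#' `(2r + dr, 2c + dc)`. Within-array row/column positions are never altered.
#'
#' Under `scheme = "randomized"` the four replicate arrays of each library
#' plate are pinned on four distinct screen plates, and the offsets a library
#' plate takes across those plates follow a seeded Latin-square assignment, so
#' each screen plate holds one replicate of each of four library plates and
#' all four offsets. Under `scheme = "block"` all four replicates of a colony
#' sit as a 2x2 block on a single screen plate.
#'
#' @param library list of 384-format [PlateLayout-class]; padded with blank
#'   plates to a multiple of 4
#' @param scheme `"randomized"` or `"block"`
#' @param seed integer seed for the Latin-square draw
#' @param platePrefix prefix for screen-plate labels
#' @return list of 1536-format [PlateLayout-class] objects
#' @seealso [derandomize()] for the inverse mapping on measurements
#' @export
randomizeLayout <- function(library, scheme = c("randomized", "block"),
                            seed = 1L, platePrefix = "P") {
  scheme <- match.arg(scheme)
  if (!length(library)) stop("empty library")
  if (any(vapply(library, plateFormat, 0L) != 384L))
    stop("library plates must be 384 format")
  npad <- (4L - length(library) %% 4L) %% 4L
  if (npad)
    library <- c(library, lapply(seq_len(npad), function(i)
      .emptyLibraryPlate(sprintf("PAD%02d", i))))
  nGroups <- length(library) %/% 4L
  dims <- .FORMATS[["1536"]]
  set.seed(as.integer(seed))
  out <- list()
  for (g in seq_len(nGroups)) {
    plates <- library[((g - 1L) * 4L + 1L):(g * 4L)]
    square <- if (scheme == "randomized") .latinSquare4() else NULL
    screens <- vector("list", 4L)
    for (j in 1:4) {  # screen plate j of this group
      parts <- lapply(1:4, function(i) {
        src <- layoutEntries(plates[[i]])
        if (scheme == "randomized") {
          slot <- square[i, j]
          rep_idx <- j
        } else {
          # block: library plate i goes (all four offsets) onto screen plate i
          if (i != j) return(NULL)
          slot <- NULL
          rep_idx <- NULL
        }
        if (scheme == "block") {
          do.call(rbind, lapply(1:4, function(s) {
            data.frame(row = 2L * src$row + .OFFSETS[s, "dr"],
                       col = 2L * src$col + .OFFSETS[s, "dc"],
                       gene_id = src$gene_id,
                       source_plate_id = plateId(plates[[i]]),
                       source_row = src$row, source_col = src$col,
                       replicate_index = s, stringsAsFactors = FALSE)
          }))
        } else {
          data.frame(row = 2L * src$row + .OFFSETS[slot, "dr"],
                     col = 2L * src$col + .OFFSETS[slot, "dc"],
                     gene_id = src$gene_id,
                     source_plate_id = plateId(plates[[i]]),
                     source_row = src$row, source_col = src$col,
                     replicate_index = rep_idx, stringsAsFactors = FALSE)
        }
      })
      entries <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
      pid <- sprintf("%s%02d", platePrefix, (g - 1L) * 4L + j)
      screens[[j]] <- plateLayout(pid, 1536L, entries)
    }
    out <- c(out, screens)
  }
  out
}

#' Parameters of the synthetic ground truth
#'
#' Defaults encode the statistical structure the downstream analysis assumes:
#' a three-part pigment-effect mixture (bulk near zero, a yellow tail, a white
#' tail), a fitness penalty tied to the strongest yellow effects, mild
#' multiplicative plate bias, a two-ring edge bias, and sparse
#' contamination/missingness.
#'
#' @param bulkSd sd of the bulk pigment/fitness effects (z-scale)
#' @param yellowProp,whiteProp mixture proportions of the yellow/white tails
#' @param yellowMean,whiteMean tail effect means (z-scale)
#' @param tailSd sd of tail effects
#' @param fitnessPenalty multiplier linking yellow-tail pigment effect to a
#'   negative fitness effect
#' @param noiseSd per-colony measurement noise sd applied at render time
#' @param plateBiasSd sd of log plate bias (multiplicative, centered on 1)
#' @param edgeBias multiplicative bias per outer frame ring, outermost first
#' @param contaminationRate fraction of colonies carrying white contamination
#' @param missingRate fraction of colonies missing entirely
#' @param whiteFractionShape Beta shape parameters of the contaminated white
#'   fraction
#' @param plantedYellow,plantedWhite optional explicit gene-id vectors planted
#'   at fixed effects
#' @param plantedYellowEffect,plantedWhiteEffect pigment effects of planted
#'   genes
#' @return named list of parameters for [simulateTruth()]
#' @export
truthParams <- function(bulkSd = 0.3, yellowProp = 0.05, whiteProp = 0.05,
                        yellowMean = 3, whiteMean = -3, tailSd = 0.5,
                        fitnessPenalty = 0.6, noiseSd = 0.3,
                        plateBiasSd = 0.05, edgeBias = c(1.25, 1.25),
                        contaminationRate = 0.01, missingRate = 0.01,
                        whiteFractionShape = c(1, 9),
                        plantedYellow = NULL, plantedWhite = NULL,
                        plantedYellowEffect = 3, plantedWhiteEffect = -3) {
  p <- as.list(environment())
  rates <- c(p$contaminationRate, p$missingRate, p$noiseSd, p$bulkSd, p$tailSd,
             p$plateBiasSd)
  if (any(rates < 0)) stop("rates and standard deviations must be non-negative")
  if (p$contaminationRate > 1 || p$missingRate > 1)
    stop("contamination and missing rates must lie in [0,1]")
  p
}

#' Draw the ground truth for a set of screen plates
#'
#' Samples per-gene pigment and fitness effects from the three-part mixture
#' (or plants the explicit hit lists in `params`), plate and edge biases, and
#' the contaminated/missing colony positions. Deterministic for a fixed seed.
#'
#' @param layouts list of 1536-format screen [PlateLayout-class] objects
#' @param params list from [truthParams()]
#' @param seed integer seed
#' @return a [SyntheticTruth-class]
#' @export
simulateTruth <- function(layouts, params = truthParams(), seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sort(unique(unlist(lapply(layouts, function(l) {
    e <- layoutEntries(l)
    e$gene_id[!is.na(e$gene_id)]
  }))))
  n <- length(genes)
  if (!n) stop("layouts contain no genes")

  group <- rep("bulk", n)
  pig <- stats::rnorm(n, 0, params$bulkSd)
  if (!is.null(params$plantedYellow) || !is.null(params$plantedWhite)) {
    iy <- match(params$plantedYellow, genes)
    iw <- match(params$plantedWhite, genes)
    if (anyNA(iy) || anyNA(iw)) stop("planted genes absent from layouts")
    pig[iy] <- params$plantedYellowEffect
    pig[iw] <- params$plantedWhiteEffect
    group[iy] <- "yellow"; group[iw] <- "white"
  } else {
    u <- stats::runif(n)
    yellow <- u < params$yellowProp
    white <- !yellow & u < params$yellowProp + params$whiteProp
    pig[yellow] <- stats::rnorm(sum(yellow), params$yellowMean, params$tailSd)
    pig[white] <- stats::rnorm(sum(white), params$whiteMean, params$tailSd)
    group[yellow] <- "yellow"; group[white] <- "white"
  }
  fit <- stats::rnorm(n, 0, params$bulkSd)
  yel <- group == "yellow"
  # yellow tail carries a fitness penalty proportional to its pigment effect
  fit[yel] <- -params$fitnessPenalty * abs(pig[yel]) +
    stats::rnorm(sum(yel), 0, params$bulkSd)

  plateIds <- vapply(layouts, plateId, "")
  plateBias <- exp(stats::rnorm(length(plateIds), 0, params$plateBiasSd))
  names(plateBias) <- plateIds

  pos <- do.call(rbind, lapply(layouts, function(l) {
    e <- layoutEntries(l)
    e <- e[!is.na(e$gene_id), c("row", "col")]
    if (!nrow(e)) return(NULL)
    data.frame(plate_id = plateId(l), e, stringsAsFactors = FALSE)
  }))
  npos <- nrow(pos)
  contam <- pos[stats::runif(npos) < params$contaminationRate, , drop = FALSE]
  contam$white_fraction <- if (nrow(contam))
    stats::rbeta(nrow(contam), params$whiteFractionShape[1],
                 params$whiteFractionShape[2]) else numeric(0)
  miss <- pos[stats::runif(npos) < params$missingRate, , drop = FALSE]
  rownames(contam) <- rownames(miss) <- NULL

  new("SyntheticTruth",
      geneEffects = data.frame(gene_id = genes, pigment_effect = pig,
                               fitness_effect = fit, planted_group = group,
                               stringsAsFactors = FALSE),
      plateBias = plateBias, edgeBias = params$edgeBias,
      contamination = contam, missing = miss,
      params = params, seed = as.integer(seed))
}

#' Simulate a gene-to-term annotation set
#'
#' Builds a synthetic annotation table over the given genes: background terms
#' annotate random gene sets, while `planted` terms annotate the supplied gene
#' lists (e.g. planted screen hits). A shallow parent hierarchy groups terms
#' under a few category roots whose descriptions carry the category keyword,
#' exercising ancestor-based graph coloring.
#'
#' @param geneIds character vector of gene ids
#' @param nTerms number of background terms
#' @param genesPerTerm genes per background term
#' @param planted named list: term description -> gene-id vector
#' @param keywords category keywords used for root descriptions
#' @param seed integer seed
#' @return an [AnnotationSet-class]
#' @export
simulateAnnotations <- function(geneIds, nTerms = 30, genesPerTerm = 15,
                                planted = list(),
                                keywords = c("mitochondria", "translation",
                                             "vacuole"),
                                seed = 1L) {
  set.seed(as.integer(seed))
  roots <- sprintf("ROOT:%04d", seq_along(keywords))
  rootDf <- data.frame(term_id = roots,
                       description = paste(keywords, "process (root)"),
                       stringsAsFactors = FALSE)
  ids <- sprintf("T:%04d", seq_len(nTerms + length(planted)))
  bgIds <- ids[seq_len(nTerms)]
  plIds <- ids[nTerms + seq_along(planted)]
  geneSets <- lapply(bgIds, function(i)
    sample(geneIds, min(genesPerTerm, length(geneIds))))
  names(geneSets) <- bgIds
  desc <- sprintf("background process %02d", seq_len(nTerms))
  if (length(planted)) {
    geneSets[plIds] <- unname(planted)
    desc <- c(desc, names(planted))
  }
  terms <- rbind(rootDf,
                 data.frame(term_id = c(bgIds, plIds), description = desc,
                            stringsAsFactors = FALSE))
  # roots annotate the union of their children so gene sets stay nonempty
  parents <- as.list(sample(roots, nTerms + length(planted), replace = TRUE))
  names(parents) <- c(bgIds, plIds)
  for (r in roots) {
    kids <- names(parents)[vapply(parents, function(p) r %in% p, TRUE)]
    geneSets[[r]] <- unique(unlist(geneSets[kids]))
    if (!length(geneSets[[r]])) geneSets[[r]] <- sample(geneIds, 1L)
  }
  annotationSet(terms, geneSets, parents)
}
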