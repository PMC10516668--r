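#' @include io.R
NULL

#' Simulate complete synthetic screens
#'
#' Convenience front end of the generator: builds the 384-format library,
#' assembles each screen's 1536-format plates with the chosen randomization
#' scheme (an independent seeded Latin-square draw per screen), draws one
#' shared ground truth over all plates (gene effects are common to all
#' screens; plate biases, contamination and missingness are per plate), and
#' optionally renders every plate image.
#'
#' @param nGenes library size
#' @param nScreens number of replicate screens
#' @param scheme `"randomized"` or `"block"` (see [randomizeLayout()])
#' @param geom a 1536-format [GridGeometry-class]
#' @param params generator parameters from [truthParams()]
#' @param seed global integer seed
#' @param render render plate images (set FALSE to work with layouts/truth
#'   only)
#' @param renderPar renderer parameters from [renderParams()]
#' @return list: `library` (384 layouts), `screens` (per screen: screen_id,
#'   layouts, images), `truth` (shared [SyntheticTruth-class])
#' @export
simulateScreens <- function(nGenes = 384, nScreens = 4,
                            scheme = "randomized",
                            geom = gridGeometry(1536, 10),
                            params = truthParams(), seed = 1L,
                            render = TRUE, renderPar = renderParams()) {
  lib <- generateLibrary(nGenes, seed = seed)
  screens <- lapply(seq_len(nScreens), function(s) {
    list(screen_id = sprintf("S%d", s),
         layouts = randomizeLayout(lib, scheme,
                                   seed = .deriveSeed(seed, "simulate") + s,
                                   platePrefix = sprintf("S%dP", s)))
  })
  allLayouts <- unlist(lapply(screens, `[[`, "layouts"), recursive = FALSE)
  truth <- simulateTruth(allLayouts, params,
                         seed = .deriveSeed(seed, "simulate"))
  if (render) {
    for (s in seq_along(screens)) {
      screens[[s]]$images <- lapply(seq_along(screens[[s]]$layouts),
        function(p) renderPlate(screens[[s]]$layouts[[p]], truth, geom,
                                seed = .deriveSeed(seed, "render") +
                                  s * 100L + p,
                                params = renderPar))
    }
  }
  list(library = lib, screens = screens, truth = truth)
}

#' Score all plates of a screen
#'
#' Segments and scores every plate image and assembles the raw
#' [ScreenTable-class].
#'
#' @param images list of [PlateImage-class]
#' @param layouts list of matching [PlateLayout-class]
#' @param screenId screen label
#' @param filterQuantile bright-pixel filter quantile (see [scoreColony()])
#' @return a [ScreenTable-class] in `raw` state
#' @export
scoreScreen <- function(images, layouts, screenId, filterQuantile = 0.5) {
  stopifnot(length(images) == length(layouts))
  recs <- do.call(rbind, lapply(seq_along(images), function(i) {
    masks <- segmentColonies(images[[i]])
    scorePlate(images[[i]], masks, layouts[[i]],
               filterQuantile = filterQuantile)
  }))
  screenTable(screenId, recs)
}

#' Pipeline run configuration
#'
#' One validated configuration object driving [runPipeline()]; round-trips
#' unchanged through YAML ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing
#' @param nGenes,nScreens,scheme,cellPx synthetic-screen shape
#' @param nFrames edge-correction frame count
#' @param grubbsAlpha Grubbs significance level
#' @param minReplicates minimum surviving replicates per gene
#' @param sdThreshold hit-group threshold in screen sd units
#' @param kListSize hit-list size for the overlap test
#' @param qThreshold enrichment significance threshold
#' @param filterQuantile colony bright-pixel filter quantile
#' @param truth generator parameters ([truthParams()])
#' @param outDir output directory
#' @param imageFormat `"png"` or `"tiff"`
#' @param writeImages write rendered plate images to `outDir/images`
#' @param annotationFile optional annotation TSV for the enrichment stage
#' @param colorKeywords keywords for term-graph coloring
#' @return a validated config list (class `crispa_config`)
#' @export
runConfig <- function(seed = 1L, nGenes = 384L, nScreens = 4L,
                      scheme = "randomized", cellPx = 10L, nFrames = 2L,
                      grubbsAlpha = 0.05, minReplicates = 3L,
                      sdThreshold = 1.2, kListSize = 192L,
                      qThreshold = 0.05, filterQuantile = 0.5,
                      truth = truthParams(), outDir = tempfile("crispa_run"),
                      imageFormat = "png", writeImages = FALSE,
                      annotationFile = NULL,
                      colorKeywords = c("mitochondria", "translation",
                                        "vacuole")) {
  cfg <- as.list(environment())
  stopifnot(cfg$nGenes >= 1, cfg$nScreens >= 1,
            cfg$scheme %in% c("randomized", "block"),
            cfg$grubbsAlpha > 0, cfg$grubbsAlpha < 1,
            cfg$minReplicates >= 1, cfg$sdThreshold > 0,
            cfg$kListSize >= 1, cfg$qThreshold > 0, cfg$qThreshold <= 1,
            cfg$filterQuantile >= 0, cfg$filterQuantile < 1,
            cfg$imageFormat %in% c("png", "tiff"))
  class(cfg) <- "crispa_config"
  cfg
}

#' @rdname runConfig
#' @param path YAML file
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  truth <- do.call(truthParams, raw$truth[!vapply(raw$truth, is.null, TRUE)])
  raw$truth <- NULL
  do.call(runConfig, c(raw[!vapply(raw, is.null, TRUE)],
                       list(truth = truth)))
}

.stageGuard <- function(stage, outDir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(outDir, paste0(stage, ".partial"))
    try(writeLines(conditionMessage(e), marker), silent = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full screen pipeline
#'
#' Executes simulate -> score -> correct -> combine -> hits -> overlap ->
#' enrich in fixed order, writing every stage output as TSV (floats at 6
#' significant digits, so reruns with the same config are byte-identical)
#' plus a manifest accounting for every record. The overlap stage compares
#' the first two screens (skipped for a single screen); the enrichment stage
#' runs when `annotationFile` is set.
#'
#' @param cfg a config from [runConfig()]
#' @return list: `manifest`, `summaries`, `hits`, `overlap`, `enrichment`,
#'   `truth`, `outDir`
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "crispa_config"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  geom <- gridGeometry(1536, cfg$cellPx)
  manifest <- list(version = as.character(utils::packageVersion("crispa")),
                   stages = list())

  sim <- .stageGuard("simulate", cfg$outDir, {
    sim <- simulateScreens(cfg$nGenes, cfg$nScreens, cfg$scheme, geom,
                           cfg$truth, cfg$seed, render = TRUE)
    writeLayoutTsv(unlist(lapply(sim$screens, `[[`, "layouts"),
                          recursive = FALSE),
                   file.path(cfg$outDir, "layouts.tsv"))
    writeTruthTsv(sim$truth, file.path(cfg$outDir, "truth.tsv"))
    if (cfg$writeImages) {
      imgDir <- file.path(cfg$outDir, "images")
      dir.create(imgDir, showWarnings = FALSE)
      ext <- if (cfg$imageFormat == "png") "png" else "tif"
      for (s in sim$screens)
        for (img in s$images)
          writePlateImage(img, file.path(imgDir, sprintf("%s_%s.%s",
            s$screen_id, plateId(img), ext)))
    }
    sim
  })
  manifest$stages$simulate <- list(
    genes = cfg$nGenes,
    plates = sum(lengths(lapply(sim$screens, `[[`, "layouts"))),
    contaminated = nrow(sim$truth@contamination),
    missing = nrow(sim$truth@missing))

  tables <- .stageGuard("score", cfg$outDir, {
    lapply(sim$screens, function(s)
      scoreScreen(s$images, s$layouts, s$screen_id,
                  filterQuantile = cfg$filterQuantile))
  })
  nrecs <- sum(vapply(tables, function(t) nrow(screenRecords(t)), 0L))
  manifest$stages$score <- list(
    records_in = nrecs, records_out = nrecs,
    missing = sum(vapply(tables, function(t)
      sum(.isMissingRecord(screenRecords(t))), 0L)))

  tables <- .stageGuard("correct", cfg$outDir, {
    out <- lapply(tables, function(t)
      normalizeScreen(edgeCorrect(t, cfg$nFrames)))
    for (t in out)
      writeMeasurementsTsv(screenRecords(t),
        file.path(cfg$outDir, sprintf("measurements_%s.tsv", screenId(t))))
    out
  })
  manifest$stages$correct <- list(records_in = nrecs, records_out = nrecs,
                                  dropped = 0L)

  allLayouts <- unlist(lapply(sim$screens, `[[`, "layouts"),
                       recursive = FALSE)
  comb <- .stageGuard("combine", cfg$outDir, {
    comb <- combineScreens(tables, allLayouts, alpha = cfg$grubbsAlpha,
                           minReplicates = cfg$minReplicates)
    if (!nrow(comb$summaries))
      warning("every gene dropped: minReplicates exceeds available replicates")
    comb
  })
  present <- nrow(comb$summaries) + nrow(comb$dropped)
  manifest$stages$combine <- list(
    genes_in = cfg$nGenes,
    genes_out = nrow(comb$summaries),
    genes_dropped_low_replicates = nrow(comb$dropped),
    genes_zero_records = cfg$nGenes - present,
    colonies_removed_as_outliers = comb$n_outliers)

  hits <- .stageGuard("hits", cfg$outDir, {
    hits <- callHits(comb$summaries, cfg$sdThreshold)
    writeGeneSummariesTsv(hits, file.path(cfg$outDir, "gene_summaries.tsv"))
    hits
  })
  manifest$stages$hits <- list(
    genes_in = nrow(hits), genes_out = nrow(hits),
    yellow = sum(hits$group == "yellow"), white = sum(hits$group == "white"),
    cyan = sum(hits$cyan))

  overlap <- NULL
  if (cfg$nScreens >= 2) {
    overlap <- .stageGuard("overlap", cfg$outDir, {
      aggOne <- function(i) combineScreens(tables[[i]], allLayouts,
                                           alpha = cfg$grubbsAlpha,
                                           minReplicates = 3L)$summaries
      sA <- aggOne(1L); sB <- aggOne(2L)
      res <- lapply(c("top", "bottom"), function(tl)
        topBottomOverlap(sA, sB, cfg$kListSize, tl))
      df <- do.call(rbind, lapply(res, function(r)
        data.frame(tail = r$tail, M = r$M, n = r$n, N = r$N, k = r$k,
                   p_value = r$p_value)))
      .writeTsv(df, file.path(cfg$outDir, "overlap.tsv"), digits = 10)
      list(top = res[[1]], bottom = res[[2]],
           pearson = genePearson(sA, sB))
    })
    manifest$stages$overlap <- list(M = overlap$top$M,
                                    k_top = overlap$top$k,
                                    k_bottom = overlap$bottom$k)
  }

  enrichment <- NULL
  if (!is.null(cfg$annotationFile)) {
    enrichment <- .stageGuard("enrich", cfg$outDir, {
      ann <- readAnnotationTsv(cfg$annotationFile)
      study <- hits$gene_id[hits$group == "yellow"]
      er <- enrichTerms(study, hits$gene_id, ann, cfg$qThreshold)
      .writeTsv(er, file.path(cfg$outDir, "enrichment.tsv"), digits = 10)
      g <- buildTermGraph(er, ann, cfg$colorKeywords)
      writeTermGraph(g, file.path(cfg$outDir, "term_graph.graphml"))
      list(terms = er, graph = g)
    })
    manifest$stages$enrich <- list(
      terms_tested = nrow(enrichment$terms),
      terms_enriched = sum(enrichment$terms$enriched))
  }

  yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
  list(manifest = manifest, summaries = comb$summaries, hits = hits,
       overlap = overlap, enrichment = enrichment, truth = sim$truth,
       outDir = cfg$outDir)
}
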