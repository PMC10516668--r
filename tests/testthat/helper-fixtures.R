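# Shared fixtures, built in code at test time.

# ground truth with explicitly chosen effects and no nuisance structure
makeTruth <- function(geneIds, pigment, fitness = 0,
                      params = truthParams(noiseSd = 0, plateBiasSd = 0,
                                           edgeBias = c(1, 1),
                                           contaminationRate = 0,
                                           missingRate = 0)) {
  n <- length(geneIds)
  methods::new("SyntheticTruth",
    geneEffects = data.frame(gene_id = geneIds,
                             pigment_effect = rep_len(pigment, n),
                             fitness_effect = rep_len(fitness, n),
                             planted_group = "bulk",
                             stringsAsFactors = FALSE),
    plateBias = stats::setNames(numeric(0), character(0)),
    edgeBias = params$edgeBias, contamination = data.frame(),
    missing = data.frame(), params = params, seed = 0L)
}

# a raw ScreenTable with prescribed per-ring yellowness/size levels on one
# full 1536 plate (values constant within a ring)
ringScreen <- function(ringValuesY, centerY = 100, ringValuesS = NULL,
                       centerS = 400, screenId = "S1", plateId = "P1",
                       jitter = 0) {
  nR <- 32L; nC <- 48L
  df <- expand.grid(row = 0:(nR - 1), col = 0:(nC - 1))
  ring <- pmin(df$row, df$col, nR - 1 - df$row, nC - 1 - df$col)
  nf <- length(ringValuesY)
  y <- ifelse(ring < nf, ringValuesY[pmin(ring + 1, nf)], centerY)
  if (is.null(ringValuesS)) ringValuesS <- ringValuesY * 4
  s <- ifelse(ring < nf, ringValuesS[pmin(ring + 1, nf)], centerS)
  if (jitter > 0) {
    y <- y + stats::runif(length(y), -jitter, jitter)
    s <- s + stats::runif(length(s), -jitter, jitter)
  }
  screenTable(screenId, data.frame(
    plate_id = plateId, row = df$row, col = df$col,
    size_px = as.numeric(s), yellowness_raw = y, flags = "",
    stringsAsFactors = FALSE))
}

# the end-to-end synthetic study: 384 genes, 20 planted yellow (+3) and 20
# planted white (-3), 4 screens x 4 replicates with position randomization,
# 1% contamination, 1% missingness, edge bias 1.25 on the two outer rings.
# Built once and cached for the session; ~15 s of rendering and scoring.
e2eFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(1)
    genes <- sprintf("g%05d", 1:384)
    py <- sample(genes, 20)
    pw <- sample(setdiff(genes, py), 20)
    pars <- truthParams(plantedYellow = py, plantedWhite = pw)
    sim <- simulateScreens(384, 4, "randomized", gridGeometry(1536, 10),
                           pars, seed = 1)
    tabs <- lapply(sim$screens, function(s)
      scoreScreen(s$images, s$layouts, s$screen_id))
    tabs <- lapply(tabs, function(tb)
      suppressWarnings(normalizeScreen(edgeCorrect(tb))))
    allL <- unlist(lapply(sim$screens, `[[`, "layouts"), recursive = FALSE)
    comb <- suppressMessages(combineScreens(tabs, allL))
    hits <- callHits(comb$summaries)
    perScreen <- lapply(seq_along(tabs), function(i)
      suppressMessages(combineScreens(tabs[[i]], allL))$summaries)
    cache <<- list(sim = sim, tables = tabs, layouts = allL, comb = comb,
                   hits = hits, perScreen = perScreen,
                   plantedYellow = py, plantedWhite = pw)
    cache
  }
})
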