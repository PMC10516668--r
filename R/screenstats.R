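#' @include platecorr.R
NULL

#' Grubbs critical value
#'
#' Two-sided single-outlier critical value at level `alpha` for sample size
#' `n`, from the t-quantile formula
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = t_{1 - alpha/(2n), n-2}`.
#'
#' @param n sample size (>= 3)
#' @param alpha significance level
#' @return numeric critical value
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("Grubbs test requires n >= 3")
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier filtering
#'
#' Applies the two-sided single-outlier Grubbs test
#' (`G = max|x - mean| / sd`, sample sd) and, while `G > G_crit`, removes the
#' most deviant value and repeats, stopping when no outlier remains or fewer
#' than 3 values are left. Degenerate inputs (n < 3 or sd = 0) pass through
#' untested.
#'
#' @param values numeric vector
#' @param alpha significance level (default 0.05)
#' @return list with `values` (retained), `removed` (indices into the input,
#'   in removal order) and `trail` (one row per test round: n, G, G_crit,
#'   outlier_index, removed)
#' @examples
#' grubbsFilter(c(1, 1, 1, 10))$removed  # 4
#' @export
grubbsFilter <- function(values, alpha = 0.05) {
  n0 <- length(values)
  idx <- seq_along(values)
  removedIdx <- integer()
  trail <- data.frame(n = integer(), G = numeric(), G_crit = numeric(),
                      outlier_index = integer(), removed = logical())
  repeat {
    n <- length(values)
    if (n < 3) break
    sdv <- stats::sd(values)
    if (is.na(sdv) || sdv == 0) break
    dev <- abs(values - mean(values))
    i <- which.max(dev)
    G <- dev[i] / sdv
    crit <- grubbsCritical(n, alpha)
    hit <- G > crit
    trail <- rbind(trail, data.frame(n = n, G = G, G_crit = crit,
                                     outlier_index = idx[i], removed = hit))
    if (!hit) break
    removedIdx <- c(removedIdx, idx[i])
    values <- values[-i]
    idx <- idx[-i]
  }
  list(values = values, removed = removedIdx, trail = trail, kept_index = idx)
}

#' Aggregate replicate records to gene summaries
#'
#' Means of the yellowness and size z-scores over a gene's surviving
#' replicates; genes with fewer than `minReplicates` survivors are dropped
#' (the screen's two-or-fewer-colonies deletion rule at the default of 3).
#'
#' @param records gene-keyed data.frame with columns gene_id, z_yellow,
#'   z_size (post-normalization, post-outlier-filtering)
#' @param minReplicates minimum surviving replicates to retain a gene
#' @return list with `summaries` (gene_id, mean_yellow, mean_size,
#'   n_replicates) and `dropped` (gene_id, n_replicates)
#' @export
aggregateGenes <- function(records, minReplicates = 3L) {
  spl <- split(records, records$gene_id)
  n <- vapply(spl, nrow, 0L)
  my <- vapply(spl, function(d) mean(d$z_yellow), 0)
  ms <- vapply(spl, function(d) mean(d$z_size), 0)
  df <- data.frame(gene_id = names(spl), mean_yellow = unname(my),
                   mean_size = unname(ms), n_replicates = unname(n),
                   stringsAsFactors = FALSE)
  keep <- df$n_replicates >= minReplicates
  list(summaries = df[keep, , drop = FALSE],
       dropped = df[!keep, c("gene_id", "n_replicates"), drop = FALSE])
}

#' Pool screens and compute final gene scores
#'
#' For each gene, pools the replicate z-scores of all supplied screens (each
#' screen must already be independently edge-corrected and normalized),
#' removes outliers from the pooled set with the iterative Grubbs test on the
#' yellowness z-scores, and aggregates survivors with
#' [aggregateGenes()]. Colonies removed by the filter are excluded from both
#' the yellowness and size means. Works for a single screen as well (the
#' per-quadruplicate flow).
#'
#' @param tables list of normalized [ScreenTable-class] objects
#' @param layouts list of screen [PlateLayout-class] objects covering all
#'   plates
#' @param alpha Grubbs significance level
#' @param minReplicates minimum surviving replicates per gene
#' @return list with `summaries`, `dropped` (from [aggregateGenes()]) and
#'   `n_outliers` (colonies deleted by the Grubbs filter)
#' @export
combineScreens <- function(tables, layouts, alpha = 0.05,
                           minReplicates = 3L) {
  if (methods::is(tables, "ScreenTable")) tables <- list(tables)
  states <- vapply(tables, normState, "")
  if (any(states != "normalized"))
    stop("all screens must be normalized before combining")
  recs <- derandomize(tables, layouts)
  key <- paste(recs$screen_id, recs$plate_id, recs$row, recs$col)
  if (anyDuplicated(key)) stop("duplicate (screen, plate, row, col) records")
  recs <- recs[!.isMissingRecord(recs), , drop = FALSE]
  nOut <- 0L
  parts <- lapply(split(recs, recs$gene_id), function(d) {
    gf <- grubbsFilter(d$z_yellow, alpha)
    nOut <<- nOut + (nrow(d) - length(gf$kept_index))
    d[gf$kept_index, , drop = FALSE]
  })
  filtered <- do.call(rbind, parts)
  agg <- aggregateGenes(filtered, minReplicates)
  c(agg, list(n_outliers = nOut))
}

#' Call yellow / white / cyan hit groups
#'
#' Thresholds the aggregated yellowness z-score at `sdThreshold` screen
#' standard deviations: genes above `+sdThreshold` form the yellow group
#' (raised pigment), genes below `-sdThreshold` the white group (lowered
#' pigment). The cyan group - highly yellow strains with little or no fitness
#' penalty - is reported as a logical sub-label of the yellow group: genes
#' with `mean_yellow > cyanYellowMin` and `mean_size > cyanSizeMin`.
#'
#' @param summaries gene-summary data.frame from [combineScreens()]
#' @param sdThreshold hit threshold in screen sd units (default 1.2)
#' @param cyanYellowMin,cyanSizeMin cyan sub-group thresholds (defaults 1.2
#'   and 0)
#' @return the summaries with `group` (yellow/white/none) and `cyan` columns
#' @export
callHits <- function(summaries, sdThreshold = 1.2, cyanYellowMin = 1.2,
                     cyanSizeMin = 0) {
  s <- summaries
  s$group <- rep("none", nrow(s))
  s$group[s$mean_yellow > sdThreshold] <- "yellow"
  s$group[s$mean_yellow < -sdThreshold] <- "white"
  s$cyan <- s$mean_yellow > cyanYellowMin & s$mean_size > cyanSizeMin
  s
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for the overlap of two hit lists of sizes `n` and `N` drawn
#' from `M` commonly scored genes.
#'
#' @param M genes quantified in both screens
#' @param n,N hit-list sizes
#' @param k observed overlap
#' @return numeric p-value in (0, 1]
#' @export
hypergeomOverlapP <- function(M, n, N, k) {
  if (k > min(n, N) || n > M || N > M || k < 0)
    stop("require k <= min(n, N) and n, N <= M")
  stats::phyper(k - 1, n, M - n, N, lower.tail = FALSE)
}

#' Overlap of top/bottom hit lists between two screens
#'
#' Ranks the genes scored in both screens by their aggregated yellowness
#' (descending for `tail = "top"`, ascending for `"bottom"`; ties broken by
#' gene identifier order), takes each screen's first `kListSize` genes as its
#' hit list, and tests the overlap against the upper-tail hypergeometric null.
#'
#' @param summariesA,summariesB gene-summary data.frames
#' @param kListSize hit-list size (the screen's convention is 192)
#' @param tail `"top"` or `"bottom"`
#' @return list: M, n, N, k, p_value, tail, overlap_genes
#' @export
topBottomOverlap <- function(summariesA, summariesB, kListSize = 192L,
                             tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  common <- intersect(summariesA$gene_id, summariesB$gene_id)
  M <- length(common)
  if (kListSize > M) stop("kListSize exceeds the number of common genes")
  pick <- function(s) {
    s <- s[s$gene_id %in% common, ]
    sgn <- if (tail == "top") -1 else 1
    ties <- s$gene_id[order(sgn * s$mean_yellow, s$gene_id)]
    ties[seq_len(kListSize)]
  }
  hitsA <- pick(summariesA)
  hitsB <- pick(summariesB)
  k <- length(intersect(hitsA, hitsB))
  list(M = M, n = kListSize, N = kListSize, k = k,
       p_value = hypergeomOverlapP(M, kListSize, kListSize, k),
       tail = tail, overlap_genes = sort(intersect(hitsA, hitsB)))
}

#' Pearson correlation of gene scores between two screens
#'
#' Standard product-moment correlation of aggregated yellowness over the
#' genes scored in both screens; the screen-to-screen reproducibility
#' statistic.
#'
#' @param summariesA,summariesB gene-summary data.frames
#' @return numeric correlation coefficient
#' @export
genePearson <- function(summariesA, summariesB) {
  common <- intersect(summariesA$gene_id, summariesB$gene_id)
  if (length(common) < 3) stop("need at least 3 common genes")
  a <- summariesA$mean_yellow[match(common, summariesA$gene_id)]
  b <- summariesB$mean_yellow[match(common, summariesB$gene_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: correlation undefined")
  stats::cor(a, b)
}

#' One-sided two-sample location test
#'
#' Student's pooled-variance t-test or Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom), with the alternative direction
#' supplied by the caller: `"greater"` when testing raised scores (yellow
#' hits), `"less"` for lowered scores (white hits).
#'
#' @param x,y numeric samples (each n >= 2)
#' @param kind `"student"` or `"welch"`
#' @param alternative `"greater"` or `"less"` (x relative to y)
#' @return list: statistic, df, p_value, kind, alternative
#' @export
oneSidedTest <- function(x, y, kind = c("student", "welch"),
                         alternative = c("greater", "less")) {
  kind <- match.arg(kind)
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(x, y, var.equal = (kind == "student"),
                      alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, kind = kind, alternative = alternative)
}
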