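#' @include screenstats.R
NULL

#' Term over-representation analysis
#'
#' For every annotation term with at least one population gene, computes the
#' one-sided (over-representation) hypergeometric p-value of the study-set
#' count, adjusts across all tested terms with Benjamini-Hochberg, and flags
#' terms enriched at `q < qThreshold` (default 0.05). Annotations are used as
#' given; genes are not propagated to ancestor terms (ancestors are consulted
#' only for graph coloring).
#'
#' @param studyGenes character vector, the hit group (must be a subset of the
#'   population)
#' @param populationGenes character vector, the genes the screen scored
#' @param annotations an [AnnotationSet-class]
#' @param qThreshold BH-adjusted significance threshold
#' @return data.frame: term_id, description, study_count, study_n, pop_count,
#'   pop_n, p_value, q_value, enriched; ordered by p_value
#' @export
enrichTerms <- function(studyGenes, populationGenes, annotations,
                        qThreshold = 0.05) {
  studyGenes <- unique(studyGenes)
  populationGenes <- unique(populationGenes)
  if (!length(studyGenes)) stop("empty study set")
  if (!all(studyGenes %in% populationGenes))
    stop("study genes must be a subset of the population")
  sets <- lapply(termGenes(annotations), intersect, populationGenes)
  tested <- names(sets)[lengths(sets) > 0]
  popN <- length(populationGenes)
  studyN <- length(studyGenes)
  rows <- lapply(tested, function(tid) {
    popC <- length(sets[[tid]])
    stuC <- length(intersect(sets[[tid]], studyGenes))
    p <- stats::phyper(stuC - 1, popC, popN - popC, studyN,
                       lower.tail = FALSE)
    data.frame(term_id = tid, study_count = stuC, study_n = studyN,
               pop_count = popC, pop_n = popN, p_value = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ti <- termInfo(annotations)
  df$description <- ti$description[match(df$term_id, ti$term_id)]
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  df$enriched <- df$q_value < qThreshold
  df <- df[order(df$p_value, df$term_id),
           c("term_id", "description", "study_count", "study_n", "pop_count",
             "pop_n", "p_value", "q_value", "enriched")]
  rownames(df) <- NULL
  df
}

# breadth-first keyword match: own description first, then ancestors
.termColor <- function(termId, descriptions, parents, keywords) {
  if (!length(keywords)) return("other")
  frontier <- termId
  seen <- character()
  while (length(frontier)) {
    for (tid in frontier) {
      d <- tolower(descriptions[[tid]])
      if (!is.null(d) && length(d))
        for (kw in keywords) if (grepl(tolower(kw), d, fixed = TRUE))
          return(kw)
    }
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
  }
  "other"
}

#' Build the shared-gene term graph
#'
#' Nodes are enriched terms; an edge connects every pair of terms sharing at
#' least one associated gene. Node size grows linearly in `-log10(q)`
#' (`sMin + sScale * (-log10 q)`), edge opacity is the shared-gene count
#' scaled to (0, 1] by the maximum observed count, and nodes are colored by
#' the first keyword matching their description or, failing that, the
#' description of any ancestor (breadth-first up the is-a parents), else
#' "other".
#'
#' @param enriched data.frame from [enrichTerms()] (rows with
#'   `enriched = TRUE` are used; pass a pre-filtered frame to override)
#' @param annotations the [AnnotationSet-class] supplying gene sets and
#'   parents
#' @param colorKeywords character vector of category keywords, in priority
#'   order
#' @param sMin,sScale node-size mapping (display units)
#' @return an igraph object with vertex attributes name, description,
#'   q_value, size, color and edge attributes shared_genes, opacity
#' @export
buildTermGraph <- function(enriched, annotations, colorKeywords = character(),
                           sMin = 10, sScale = 5) {
  if ("enriched" %in% names(enriched))
    enriched <- enriched[enriched$enriched, , drop = FALSE]
  enriched <- enriched[order(enriched$term_id), , drop = FALSE]
  ids <- enriched$term_id
  q <- pmax(enriched$q_value, .Machine$double.xmin)
  ti <- termInfo(annotations)
  descriptions <- stats::setNames(as.list(ti$description), ti$term_id)
  parents <- termParents(annotations)
  colors <- vapply(ids, .termColor, "", descriptions = descriptions,
                   parents = parents, keywords = colorKeywords)
  edges <- NULL
  if (length(ids) > 1) {
    pairs <- utils::combn(ids, 2)
    shared <- apply(pairs, 2, function(p)
      length(intersect(termGenes(annotations, p[1]),
                       termGenes(annotations, p[2]))))
    keep <- shared >= 1
    if (any(keep))
      edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                          shared_genes = shared[keep],
                          stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character(),
                                   shared_genes = integer()) else edges,
    directed = FALSE,
    vertices = data.frame(name = ids,
                          description = enriched$description,
                          q_value = enriched$q_value,
                          size = sMin + sScale * (-log10(q)),
                          color = unname(colors),
                          stringsAsFactors = FALSE))
  if (!is.null(edges))
    igraph::E(g)$opacity <- igraph::E(g)$shared_genes /
      max(igraph::E(g)$shared_genes)
  g
}

#' Export a term graph
#'
#' @param graph igraph object from [buildTermGraph()]
#' @param path output file
#' @param format `"graphml"` or `"edgelist"` (flat TSV of term pairs with
#'   shared_genes and opacity)
#' @return `path`, invisibly
#' @export
writeTermGraph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
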