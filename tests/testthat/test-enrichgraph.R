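makeAnn <- function() {
  terms <- data.frame(
    term_id = c("T1", "T2", "T3", "R1"),
    description = c("proteasome degradation", "cytosolic translation",
                    "unnamed process", "mitochondria organization"),
    stringsAsFactors = FALSE)
  geneSets <- list(T1 = c("a", "b", "c"), T2 = c("b", "c", "d"),
                   T3 = c("e"), R1 = c("a", "b", "c", "d", "e"))
  annotationSet(terms, geneSets, parents = list(T3 = "R1"))
}

test_that("over-representation p-values match enumeration", {
  pop <- c("a", "b", "c", "d", "e", "f")
  ann <- annotationSet(
    data.frame(term_id = "T", description = "t", stringsAsFactors = FALSE),
    list(T = c("a", "b", "c")))
  er <- enrichTerms(c("a", "b", "c"), pop, ann)
  expect_equal(er$p_value, 1 / 20, tolerance = 1e-12)  # C(3,3)/C(6,3) tail
  expect_equal(er$p_value, enumHyperP(6, 3, 3, 3), tolerance = 1e-12)
  # a term with no study genes is never enriched
  er2 <- enrichTerms(c("d", "e"), pop, ann)
  expect_equal(er2$p_value, 1)
  expect_false(er2$enriched)
  expect_error(enrichTerms(character(0), pop, ann), "empty study")
  expect_error(enrichTerms("zz", pop, ann), "subset")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  ann <- makeAnn()
  er <- enrichTerms(c("a", "b"), c("a", "b", "c", "d", "e", "f"), ann)
  expect_equal(er$q_value, bhOracle(er$p_value), tolerance = 1e-12)
  expect_true(all(er$q_value >= er$p_value))
  set.seed(7)
  for (n in c(5, 50, 1000)) {
    p <- runif(n)^2
    expect_equal(stats::p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("term graph edges, sizes and colors follow the drawing rules", {
  enr <- data.frame(
    term_id = c("T1", "T2", "T3"),
    description = c("proteasome degradation", "cytosolic translation",
                    "unnamed process"),
    q_value = c(1e-4, 1e-2, 1e-3), enriched = TRUE,
    stringsAsFactors = FALSE)
  g <- buildTermGraph(enr, makeAnn(),
                      colorKeywords = c("mitochondria", "translation"))
  expect_identical(sort(igraph::V(g)$name), c("T1", "T2", "T3"))
  # T1-T2 share {b, c}; T3 shares nothing in the annotation (T3 = {e})
  el <- igraph::as_data_frame(g, "edges")
  expect_identical(nrow(el), 1L)
  expect_setequal(unlist(el[c("from", "to")]), c("T1", "T2"))
  expect_identical(el$shared_genes, 2L)
  expect_equal(el$opacity, 1)
  expect_identical(igraph::degree(g)[["T3"]], 0)
  # node size strictly increasing in -log10(q)
  sz <- setNames(igraph::V(g)$size, igraph::V(g)$name)
  expect_gt(sz[["T1"]], sz[["T3"]])
  expect_gt(sz[["T3"]], sz[["T2"]])
  # colors: own description first, then ancestors, else "other"
  cl <- setNames(igraph::V(g)$color, igraph::V(g)$name)
  expect_identical(cl[["T2"]], "translation")
  expect_identical(cl[["T3"]], "mitochondria")  # via parent R1
  expect_identical(cl[["T1"]], "other")
})

test_that("edge set is independent of node insertion order", {
  enr <- data.frame(
    term_id = c("T1", "T2", "T3"),
    description = "d", q_value = c(1e-4, 1e-2, 1e-3), enriched = TRUE,
    stringsAsFactors = FALSE)
  g1 <- buildTermGraph(enr, makeAnn())
  g2 <- buildTermGraph(enr[c(3, 1, 2), ], makeAnn())
  e1 <- igraph::as_data_frame(g1, "edges")
  e2 <- igraph::as_data_frame(g2, "edges")
  expect_setequal(paste(pmin(e1$from, e1$to), pmax(e1$from, e1$to)),
                  paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to)))
  if (nrow(e1)) expect_true(all(e1$opacity > 0 & e1$opacity <= 1))
})

test_that("graph round-trips through GraphML and edge-list export", {
  enr <- data.frame(
    term_id = c("T1", "T2"), description = c("x", "y"),
    q_value = c(1e-4, 1e-2), enriched = TRUE, stringsAsFactors = FALSE)
  g <- buildTermGraph(enr, makeAnn())
  f <- tempfile(fileext = ".graphml")
  writeTermGraph(g, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, c("T1", "T2"))
  expect_equal(sort(igraph::V(g2)$size), sort(igraph::V(g)$size),
               tolerance = 1e-6)
  f2 <- tempfile(fileext = ".tsv")
  writeTermGraph(g, f2, format = "edgelist")
  el <- read.delim(f2)
  expect_identical(el$shared_genes, 2L)
})

test_that("minimal OBO stanzas parse into terms and parents", {
  obo <- c("format-version: 1.2", "", "[Term]", "id: GO:0001",
           "name: mitochondria organization", "", "[Term]", "id: GO:0002",
           "name: respiratory chain assembly", "is_a: GO:0001 ! parent",
           "", "[Typedef]", "id: part_of")
  f <- tempfile(fileext = ".obo")
  writeLines(obo, f)
  parsed <- readOboSubset(f)
  expect_identical(nrow(parsed$terms), 2L)
  expect_identical(parsed$parents[["GO:0002"]], "GO:0001")
  expect_false("part_of" %in% parsed$terms$term_id)
})
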