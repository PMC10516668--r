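test_that("Grubbs filter matches hand-worked and degenerate cases", {
  res <- grubbsFilter(c(1, 1, 1, 10), alpha = 0.05)
  expect_equal(res$trail$G[1], 1.5)   # (10 - 3.25) / 4.5
  expect_identical(res$removed, 4L)
  expect_equal(res$values, c(1, 1, 1))

  expect_identical(grubbsFilter(c(5, 5, 5, 5))$removed, integer(0))
  expect_identical(grubbsFilter(c(1, 2))$removed, integer(0))
  expect_identical(grubbsFilter(numeric(0))$removed, integer(0))
})

test_that("Grubbs decisions agree with the t-quantile oracle", {
  set.seed(42)
  for (rep in 1:1000) {
    n <- sample(3:16, 1)
    x <- rnorm(n)
    if (runif(1) < 0.4) x[sample(n, 1)] <- rnorm(1, 0, 6)  # plant an outlier
    expect_identical(grubbsFilter(x, 0.05)$removed,
                     grubbsOracleRemoved(x, 0.05))
  }
})

test_that("gene aggregation applies the three-replicate rule", {
  recs <- data.frame(
    gene_id = c(rep("a", 3), rep("b", 2), rep("c", 4)),
    z_yellow = c(0.5, 0.6, 0.7, 1, 1, 2, 2, 2, 8),
    z_size = c(0, 0, 0, 1, 1, -1, -1, -1, -1))
  agg <- aggregateGenes(recs, minReplicates = 3)
  expect_setequal(agg$summaries$gene_id, c("a", "c"))
  expect_equal(agg$summaries$mean_yellow[agg$summaries$gene_id == "a"], 0.6)
  expect_identical(agg$dropped$gene_id, "b")
  # composition with Grubbs: one of four removed, mean over remaining 3
  gf <- grubbsFilter(recs$z_yellow[recs$gene_id == "c"])
  expect_identical(gf$removed, 4L)
  expect_equal(mean(gf$values), 2)
})

test_that("hit groups follow the 1.2-sd thresholds with cyan sub-label", {
  s <- data.frame(gene_id = c("a", "b", "c", "d"),
                  mean_yellow = c(1.3, -1.3, 1.3, 0.5),
                  mean_size = c(-2, 0, 0.5, 0.5),
                  n_replicates = 4L)
  h <- callHits(s)
  expect_identical(h$group, c("yellow", "white", "yellow", "none"))
  expect_identical(h$cyan, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  expect_equal(hypergeomOverlapP(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeomOverlapP(6, 3, 3, 2), 0.5, tolerance = 1e-12)
  expect_equal(hypergeomOverlapP(50, 10, 10, 0), 1)
  for (M in 3:20)
    for (n in 1:M) for (N in seq(1, M, by = 3)) for (k in 0:min(n, N)) {
      lo <- max(0, n + N - M)
      if (k < lo) next
      expect_equal(hypergeomOverlapP(M, n, N, k), enumHyperP(M, n, N, k),
                   tolerance = 1e-12)
    }
  expect_error(hypergeomOverlapP(10, 5, 5, 6), "k <= min")
})

test_that("top/bottom overlap ranks by score with stable tie-breaks", {
  sA <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   mean_yellow = c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4),
                   mean_size = 0, n_replicates = 4L)
  sB <- sA
  ov <- topBottomOverlap(sA, sB, kListSize = 5, tail = "top")
  expect_identical(ov$k, 5L)
  expect_equal(ov$p_value, 1 / 252, tolerance = 1e-12)
  # disjoint bottom lists
  sB2 <- sA; sB2$mean_yellow <- rev(sA$mean_yellow)
  ov2 <- topBottomOverlap(sA, sB2, kListSize = 5, tail = "bottom")
  expect_identical(ov2$k, 0L)
  expect_equal(ov2$p_value, 1)
  # ties broken by gene identifier order: all-equal scores give identical
  # lists in both screens
  sT <- sA; sT$mean_yellow <- 0
  ovT <- topBottomOverlap(sT, sT, kListSize = 5, tail = "top")
  expect_identical(ovT$k, 5L)
  expect_error(topBottomOverlap(sA, sB, kListSize = 11), "exceeds")
})

test_that("gene-score correlation matches the direct formula", {
  sA <- data.frame(gene_id = c("a", "b", "c"), mean_yellow = c(1, 2, 3))
  sB <- data.frame(gene_id = c("a", "b", "c"), mean_yellow = c(2, 4, 6))
  expect_equal(genePearson(sA, sB), 1)
  sB$mean_yellow <- c(3, 2, 1)
  expect_equal(genePearson(sA, sB), -1)
  sB$mean_yellow <- c(1, 1, 3)
  a <- c(1, 2, 3); b <- c(1, 1, 3)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(genePearson(sA, sB), direct, tolerance = 1e-12)
  sB$mean_yellow <- c(1, 1, 1)
  expect_error(genePearson(sA, sB), "constant")
})

test_that("one-sided t and Welch tests match the textbook formulas", {
  r <- oneSidedTest(c(1, 2, 3), c(1, 2, 3), "student", "greater")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
  # Welch: [2,4,6] vs [1,2,3]
  w <- oneSidedTest(c(2, 4, 6), c(1, 2, 3), "welch", "greater")
  se <- sqrt(4 / 3 + 1 / 3)
  expect_equal(w$statistic, 2 / se, tolerance = 1e-12)
  df <- (4 / 3 + 1 / 3)^2 / ((4 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(w$df, df, tolerance = 1e-12)
  expect_equal(w$p_value, pt(2 / se, df, lower.tail = FALSE),
               tolerance = 1e-12)
  # antisymmetry under sample swap
  w2 <- oneSidedTest(c(1, 2, 3), c(2, 4, 6), "welch", "greater")
  expect_equal(w2$statistic, -w$statistic)
  expect_error(oneSidedTest(c(1, 1), c(1, 1), "welch"), "zero variance")
})

test_that("combining screens pools replicates and drops sparse genes", {
  fx <- e2eFixture()
  comb <- fx$comb
  # 4 screens x 4 replicates: full genes pool 16 replicates before filtering
  expect_identical(max(comb$summaries$n_replicates), 16L)
  expect_gte(median(comb$summaries$n_replicates), 15)
  # aggregation conservation over the library
  nLib <- 384L
  expect_identical(nrow(comb$summaries) + nrow(comb$dropped) +
                     (nLib - length(unique(c(comb$summaries$gene_id,
                                             comb$dropped$gene_id)))),
                   nLib)
  # duplicate records are rejected
  tb <- fx$tables[[1]]
  expect_error(
    suppressMessages(combineScreens(list(tb, tb), fx$layouts)),
    "duplicate")
  # single screen: pooling identical data equals the single-screen means
  one <- fx$perScreen[[1]]
  expect_true(all(one$n_replicates <= 4))
})
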