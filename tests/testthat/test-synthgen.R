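test_that("library generation fills plates left-to-right, top-to-bottom", {
  lib <- generateLibrary(384)
  expect_length(lib, 1)
  e <- layoutEntries(lib[[1]])
  expect_true(all(!is.na(e$gene_id)))
  # row-major order: first gene at (0,0), 25th at (1,0)
  expect_identical(e$gene_id[e$row == 0 & e$col == 0], "g00001")
  expect_identical(e$gene_id[e$row == 1 & e$col == 0], "g00025")

  lib <- generateLibrary(4788)
  expect_length(lib, 13)
  lastFilled <- sum(!is.na(layoutEntries(lib[[13]])$gene_id))
  expect_identical(lastFilled, 180L)  # 4788 - 12*384

  expect_error(generateLibrary(0), "nGenes")
})

test_that("randomized scheme spreads quadruplicates over 4 distinct plates", {
  lib <- generateLibrary(4 * 384)
  scr <- randomizeLayout(lib, "randomized", seed = 42)
  expect_length(scr, 4)  # 4 library plates -> 4 screen plates
  all_e <- do.call(rbind, lapply(scr, function(l)
    cbind(plate_id = plateId(l), layoutEntries(l))))
  filled <- all_e[!is.na(all_e$gene_id), ]
  cnt <- table(filled$gene_id)
  expect_true(all(cnt == 4))
  plt <- tapply(filled$plate_id, filled$gene_id,
                function(p) length(unique(p)))
  expect_true(all(plt == 4))
  # row/col never altered: screen position interleaves the source position
  expect_true(all(filled$row %/% 2 == filled$source_row))
  expect_true(all(filled$col %/% 2 == filled$source_col))
  # Latin square: on each screen plate all four offsets appear, one per
  # library plate
  for (l in scr) {
    e <- layoutEntries(l)
    e <- e[!is.na(e$gene_id), ]
    off <- tapply(paste(e$row %% 2, e$col %% 2), e$source_plate_id,
                  function(x) unique(x))
    expect_true(all(lengths(off) == 1))
    expect_setequal(unlist(off), c("0 0", "0 1", "1 0", "1 1"))
  }
})

test_that("block scheme keeps quadruplicates as a 2x2 block on one plate", {
  lib <- generateLibrary(30)
  scr <- randomizeLayout(lib, "block", seed = 1)
  all_e <- do.call(rbind, lapply(scr, function(l)
    cbind(plate_id = plateId(l), layoutEntries(l))))
  filled <- all_e[!is.na(all_e$gene_id), ]
  plt <- tapply(filled$plate_id, filled$gene_id,
                function(p) length(unique(p)))
  expect_true(all(plt == 1))
  g <- filled[filled$gene_id == "g00001", ]
  expect_identical(sort(paste(g$row, g$col)), c("0 0", "0 1", "1 0", "1 1"))
})

test_that("unknown scheme and short libraries are handled", {
  lib <- generateLibrary(10)
  expect_error(randomizeLayout(lib, "shuffle"), "arg")
  scr <- randomizeLayout(lib, "randomized", seed = 3)  # padded to 4 plates
  expect_length(scr, 4)
  filled <- do.call(rbind, lapply(scr, layoutEntries))
  expect_identical(sum(!is.na(filled$gene_id)), 40L)
})

test_that("layout randomization is deterministic and seed-sensitive", {
  lib <- generateLibrary(200)
  a <- randomizeLayout(lib, "randomized", seed = 9)
  b <- randomizeLayout(lib, "randomized", seed = 9)
  c <- randomizeLayout(lib, "randomized", seed = 10)
  expect_identical(lapply(a, layoutEntries), lapply(b, layoutEntries))
  expect_false(identical(lapply(a, layoutEntries),
                         lapply(c, layoutEntries)))
})

test_that("simulated truth echoes planted parameters and is seeded", {
  lib <- generateLibrary(384)
  scr <- randomizeLayout(lib, "randomized", seed = 1)
  genes <- sprintf("g%05d", 1:384)
  py <- genes[1:20]
  pars <- truthParams(plantedYellow = py, plantedYellowEffect = 3)
  tr <- simulateTruth(scr, pars, seed = 5)
  ge <- geneEffects(tr)
  expect_identical(sum(ge$pigment_effect == 3), 20L)
  expect_setequal(ge$gene_id[ge$planted_group == "yellow"], py)
  # yellow tail carries a negative fitness effect by default
  expect_true(mean(ge$fitness_effect[ge$planted_group == "yellow"]) < -1)

  tr2 <- simulateTruth(scr, pars, seed = 5)
  expect_identical(geneEffects(tr), geneEffects(tr2))

  zero <- simulateTruth(scr, truthParams(contaminationRate = 0,
                                         missingRate = 0), seed = 1)
  expect_identical(nrow(zero@contamination), 0L)
  expect_identical(nrow(zero@missing), 0L)

  expect_error(truthParams(missingRate = -0.1), "non-negative|\\[0,1\\]")
})

test_that("mixture defaults produce bulk plus yellow and white tails", {
  lib <- generateLibrary(4 * 384)
  scr <- randomizeLayout(lib, "randomized", seed = 2)
  tr <- simulateTruth(scr, truthParams(), seed = 7)
  ge <- geneEffects(tr)
  tab <- table(ge$planted_group)
  n <- nrow(ge)
  expect_gt(tab[["bulk"]] / n, 0.8)
  expect_gt(tab[["yellow"]], 0)
  expect_gt(tab[["white"]], 0)
  expect_gt(min(ge$pigment_effect[ge$planted_group == "yellow"]), 0)
  expect_lt(max(ge$pigment_effect[ge$planted_group == "white"]), 0)
})
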