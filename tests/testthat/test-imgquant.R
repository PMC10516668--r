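test_that("per-pixel yellowness reproduces closed-form HSV values", {
  expect_equal(yellownessPixel(255, 255, 0), 1)
  expect_equal(yellownessPixel(128, 128, 128), 0)
  o <- hsvOracle(200, 180, 40)
  expect_equal(yellownessPixel(200, 180, 40), sqrt(o["S"] * o["V"]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(yellownessPixel(200, 180, 40), 0.7921, tolerance = 1e-3)
  expect_equal(yellownessPixel(0, 0, 0), 0)  # S defined 0 when V = 0
  expect_error(yellownessPixel(300, 0, 0), "0..255")
})

test_that("yellowness is monotone in saturation and hue-invariant", {
  # raising S at fixed V never lowers the score
  v <- 200
  scores <- vapply(seq(0, 1, by = 0.05), function(S)
    yellownessPixel(v, v, round(v * (1 - S))), 0)
  expect_true(all(diff(scores) >= 0))
  # hue rotation at fixed S, V leaves the score unchanged
  expect_equal(yellownessPixel(200, 200, 40),   # yellow hue
               yellownessPixel(40, 200, 200),   # cyan hue
               tolerance = 1e-12)
})

test_that("segmentation recovers a known disc exactly", {
  geom <- gridGeometry(384, cellPx = 24)
  H <- 16 * 24; W <- 24 * 24
  px <- array(30, c(H, W, 3))
  cy <- geom@originPx[1] + 2 * 24; cx <- geom@originPx[2] + 3 * 24
  for (i in 1:H) for (j in 1:W)
    if ((i - 1 - cy)^2 + (j - 1 - cx)^2 <= 100) px[i, j, ] <- c(230, 230, 40)
  img <- methods::new("PlateImage", pixels = px, geometry = geom,
                      plateId = "T", meta = data.frame())
  masks <- segmentColonies(img, geom)
  rec <- scoreColony(img, masks, 2, 3)
  expect_identical(rec$size_px, discPixelCount(cy, cx, 10, H, W))
  # all other cells empty and flagged missing
  all_rec <- scorePlate(img, masks)
  expect_identical(sum(all_rec$size_px > 0), 1L)
  expect_true(all(all_rec$flags[all_rec$size_px == 0] == "missing"))
})

test_that("adjacent discs stay in their own cells; sizes conserve foreground", {
  geom <- gridGeometry(384, cellPx = 16)
  lib <- generateLibrary(8)
  tr <- makeTruth(sprintf("g%05d", 1:8), pigment = seq(-2, 2, length.out = 8))
  img <- renderPlate(lib[[1]], tr, geom, seed = 3)
  masks <- segmentColonies(img)
  labs <- maskLabels(masks)
  recs <- scorePlate(img, masks, lib[[1]])
  # conservation: per-colony sizes sum to the plate's foreground pixel count
  expect_identical(sum(recs$size_px), sum(labs > 0))
  # disjointness by construction + each drawn colony found in its own cell
  drawn <- img@meta[!is.na(img@meta$radius), ]
  for (i in seq_len(nrow(drawn))) {
    r <- recs[recs$row == drawn$row[i] & recs$col == drawn$col[i], ]
    expect_gt(r$size_px, 0)
  }
})

test_that("uniform image yields empty masks everywhere", {
  geom <- gridGeometry(384, cellPx = 12)
  px <- array(38, c(16 * 12, 24 * 12, 3))
  img <- methods::new("PlateImage", pixels = px, geometry = geom,
                      plateId = "U", meta = data.frame())
  masks <- segmentColonies(img)
  recs <- scorePlate(img, masks)
  expect_true(all(recs$size_px == 0))
  expect_true(all(recs$flags == "missing"))
})

test_that("pixel filter averages the retained bright pixels", {
  geom <- gridGeometry(384, cellPx = 12)
  px <- array(0, c(16 * 12, 24 * 12, 3))
  # half pure yellow (255,255,0), half gray (128,128,128) in cell (0,0)
  px[3:6, 3:6, 1] <- 255; px[3:6, 3:6, 2] <- 255; px[3:6, 3:6, 3] <- 0
  px[7:10, 3:6, ] <- 128
  img <- methods::new("PlateImage", pixels = px, geometry = geom,
                      plateId = "F", meta = data.frame())
  masks <- segmentColonies(img, method = "fixed", threshold = 0.1)
  # filter disabled: arithmetic mean over all 32 pixels = 0.5
  rec0 <- scoreColony(img, masks, 0, 0, filterQuantile = 0)
  expect_equal(rec0$yellowness_raw, 0.5, tolerance = 1e-12)
  expect_identical(rec0$size_px, 32L)
  # uniform pure yellow mask scores 1 regardless of filtering
  px2 <- array(0, c(16 * 12, 24 * 12, 3))
  px2[3:8, 3:8, 1] <- 255; px2[3:8, 3:8, 2] <- 255
  img2 <- methods::new("PlateImage", pixels = px2, geometry = geom,
                       plateId = "F2", meta = data.frame())
  m2 <- segmentColonies(img2, method = "fixed", threshold = 0.1)
  expect_equal(scoreColony(img2, m2, 0, 0)$yellowness_raw, 1)
  expect_equal(scoreColony(img2, m2, 0, 0, filterQuantile = 0)$yellowness_raw, 1)
})

test_that("noise-free rendered colonies recover the planted sqrt(S*V)", {
  geom <- gridGeometry(384, cellPx = 14)
  pig <- seq(-2, 4, by = 0.5)
  ids <- sprintf("g%05d", seq_along(pig))
  lib <- generateLibrary(length(pig))
  tr <- makeTruth(ids, pigment = pig)
  img <- renderPlate(lib[[1]], tr, geom, seed = 1)
  masks <- segmentColonies(img)
  recs <- scorePlate(img, masks, lib[[1]])
  recs <- recs[!is.na(recs$gene_id), ]
  recs <- recs[order(match(recs$gene_id, ids)), ]
  measured <- recs$yellowness_raw
  expect_equal(measured, plantedYellowness(pig), tolerance = 1e-3)
  # monotone in planted pigment
  expect_true(all(diff(measured) >= 0))
  expect_gt(measured[length(pig)], measured[1])
  # worked value: planted saturation 0.6, value 0.9 -> ~ sqrt(0.54)
  pig06 <- log(0.6 / 0.4) / 0.9   # logistic inverse at default slope
  tr2 <- makeTruth("g00001", pigment = pig06)
  img2 <- renderPlate(generateLibrary(1)[[1]], tr2, geom, seed = 1)
  r2 <- scoreColony(img2, segmentColonies(img2), 0, 0)
  expect_lt(abs(r2$yellowness_raw - sqrt(0.6 * 0.9)), 1e-3)
})
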