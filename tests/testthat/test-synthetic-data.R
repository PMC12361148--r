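# Scene and field-dataset generators: determinism, separability,
# distributional recovery.

test_that("lncToChannelMeans is the clipped linear map", {
  flat <- colorMapping(intercepts = c(100, 120, 60), slopes = c(0, 0, 0))
  expect_equal(unname(lncToChannelMeans(2.0, flat)), c(100, 120, 60))
  # clipping invariant at the ends of the observed LNC range
  for (lnc in c(0.93, 3.95)) {
    v <- lncToChannelMeans(lnc, colorMapping())
    expect_true(all(v >= 0 & v <= 255))
  }
  expect_error(lncToChannelMeans(0), "positive")
  expect_error(lncToChannelMeans(-1.2), "positive")
})

test_that("default mapping gives monotone NBI and decreasing NRI in LNC", {
  grid <- seq(1.0, 3.9, by = 0.1)
  idx <- t(vapply(grid, function(l) {
    v <- lncToChannelMeans(l, colorMapping())
    computeColorIndices(v["R"], v["G"], v["B"])[c("NRI", "NBI")]
  }, numeric(2)))
  expect_true(all(diff(idx[, "NBI"]) > 0))
  expect_true(all(diff(idx[, "NRI"]) < 0))
})

test_that("leaf scans are deterministic and exact at zero noise", {
  cfg <- sceneConfig("leaf", 48, 48, noiseSd = 0, seed = 5)
  sc <- generateLeafScan(2.3, cfg)
  col <- round(lncToChannelMeans(2.3, colorMapping()))
  fg <- maskMatrix(sc$truth)
  for (ch in c("R", "G", "B"))
    expect_true(all(channel(sc$image, ch)[fg] == col[ch]))
  # same config and seed twice: bit-identical output
  cfgN <- sceneConfig("leaf", 48, 48, noiseSd = 8, seed = 5)
  a <- generateLeafScan(2.3, cfgN); b <- generateLeafScan(2.3, cfgN)
  expect_identical(a$image@data, b$image@data)
  expect_identical(maskMatrix(a$truth), maskMatrix(b$truth))
  # leaf area beyond what fits the frame is rejected
  expect_error(
    generateLeafScan(2.3, sceneConfig("leaf", 32, 32, vegFraction = 0.9)),
    "exceed")
  expect_error(generateLeafScan(2.3, sceneConfig("canopy", 32, 32)),
               "leaf")
})

test_that("canopy scenes separate vegetation from background by GMR", {
  # veg_fraction 1 gives an all-foreground truth mask
  cfg1 <- sceneConfig("canopy", 24, 24, vegFraction = 1, noiseSd = 0)
  expect_true(all(maskMatrix(generateCanopyScene(2, cfg1)$truth)))
  # noiseless margin-25 scene: exact recovery at all swept thresholds
  cfg <- sceneConfig("canopy", 64, 64, noiseSd = 0, gmrMargin = 25,
                     seed = 9)
  scn <- generateCanopyScene(2.1, cfg)
  for (t in c(0, 5, 10, 15, 20))
    expect_identical(maskMatrix(segmentByGMR(scn$image, t)),
                     maskMatrix(scn$truth))
  # realized foreground fraction close to the target at 512 x 512
  big <- generateCanopyScene(
    2.1, sceneConfig("canopy", 512, 512, vegFraction = 0.65, seed = 1))
  expect_lt(abs(mean(maskMatrix(big$truth)) - 0.65), 0.02)
  expect_error(
    generateCanopyScene(2, sceneConfig("canopy", 24, 24, gmrMargin = 0)),
    "gmrMargin")
})

test_that("plot mosaics tile canopy scenes with enclosing polygons", {
  cfg <- sceneConfig("plot", 96, 96, vegFraction = 0.7, noiseSd = 0,
                     seed = 3)
  lncs <- c(1.8, 2.4, 3.1, 2.0)
  mos <- generatePlotMosaic(lncs, cfg)
  # polygons pairwise disjoint and inside the image bounds
  masks <- lapply(mos$polygons,
                  function(p) maskMatrix(clipToPolygon(mos$image,
                                                       p$vertices)))
  for (i in seq_along(masks)) {
    for (j in seq_along(masks)) {
      if (i < j) expect_equal(sum(masks[[i]] & masks[[j]]), 0)
    }
    expect_true(all(mos$polygons[[i]]$vertices >= 0) &&
                  all(mos$polygons[[i]]$vertices[, 1] <= 96) &&
                  all(mos$polygons[[i]]$vertices[, 2] <= 96))
  }
  # per-plot truth-masked means reproduce the LNC-mapped color (noiseless:
  # exact up to DN rounding)
  for (i in seq_along(lncs)) {
    inPlot <- masks[[i]] & maskMatrix(mos$truth)
    col <- lncToChannelMeans(lncs[i], colorMapping())
    col["G"] <- max(col["G"], col["R"] + cfg@gmrMargin)
    got <- c(mean(channel(mos$image, "R")[inPlot]),
             mean(channel(mos$image, "G")[inPlot]),
             mean(channel(mos$image, "B")[inPlot]))
    expect_equal(got, unname(round(col)), tolerance = 1e-12)
  }
  expect_error(generatePlotMosaic(numeric(0), cfg), "at least one")
  expect_error(
    generatePlotMosaic(rep(2, 100), sceneConfig("plot", 32, 32)),
    "do not fit")
})

test_that("single-plot mosaic is a canopy scene plus border", {
  cfg <- sceneConfig("plot", 40, 40, vegFraction = 1, noiseSd = 0, seed = 2)
  mos <- generatePlotMosaic(2.5, cfg, bund = 4L)
  inner <- mos$image@data[5:36, 5:36, ]
  sub <- generateCanopyScene(
    2.5, sceneConfig("canopy", 32, 32, vegFraction = 1, noiseSd = 0,
                     seed = 1))  # veg_fraction 1, noiseless: seed-free color
  expect_identical(inner, sub$image@data)
  expect_true(all(maskMatrix(mos$truth)[5:36, 5:36]))
  expect_false(any(maskMatrix(mos$truth)[1:4, ]))
})

test_that("field dataset recovers design moments and respects truncation", {
  # large-n recovery of the booting-stage mean/SD used as parameters
  fd <- fieldDesign(data.frame(site = "Pukou", year = 2019L,
                               stage = "booting", mean = 2.31, sd = 0.41,
                               nPlots = 2000L), seed = 42)
  tab <- generateFieldDataset(fd)$table
  expect_equal(nrow(tab), 2000L)
  expect_lt(abs(mean(tab$lnc_percent) - 2.31), 0.03)
  expect_lt(abs(sd(tab$lnc_percent) - 0.41), 0.03)
  expect_true(all(tab$lnc_percent >= 0.5 & tab$lnc_percent <= 4.5))
  # degenerate SD: all draws equal the mean
  fd0 <- fieldDesign(data.frame(site = "Pukou", year = 2019L,
                                stage = "filling", mean = 1.71, sd = 0,
                                nPlots = 20L), seed = 1)
  expect_true(all(generateFieldDataset(fd0)$table$lnc_percent == 1.71))
  # identical seed, identical table; plot insertion leaves others unchanged
  t1 <- generateFieldDataset(fieldDesign(seed = 7))$table
  t2 <- generateFieldDataset(fieldDesign(seed = 7))$table
  expect_identical(t1, t2)
  fdBig <- fieldDesign(data.frame(site = "Pukou", year = 2019L,
                                  stage = "booting", mean = 2.31,
                                  sd = 0.41, nPlots = 12L), seed = 7)
  fdSmall <- fieldDesign(data.frame(site = "Pukou", year = 2019L,
                                    stage = "booting", mean = 2.31,
                                    sd = 0.41, nPlots = 10L), seed = 7)
  big <- generateFieldDataset(fdBig)$table
  small <- generateFieldDataset(fdSmall)$table
  expect_identical(small$lnc_percent, big$lnc_percent[1:10])
})

test_that("field dataset round-trips through files", {
  dir <- tempfile("fielddata")
  fd <- fieldDesign(data.frame(site = "Pukou", year = 2019L,
                               stage = "booting", mean = 2.31, sd = 0.41,
                               nPlots = 2L), seed = 3)
  cfgs <- list(canopy = sceneConfig("canopy", 24, 24, seed = 3),
               plot = sceneConfig("plot", 48, 48, seed = 3))
  out <- generateFieldDataset(fd, scales = c("canopy", "plot"),
                              sceneConfigs = cfgs, dir = dir)
  rt <- readSampleTable(file.path(dir, "samples.csv"))
  expect_identical(rt[, 1:4], out$table[, 1:4])
  expect_equal(rt$lnc_percent, out$table$lnc_percent, tolerance = 1e-12)
  key <- "Pukou/booting/1"
  img <- readRGBImage(file.path(dir, "canopy_Pukou_booting_1.png"))
  expect_identical(img@data, out$images$canopy[[key]]@data)
  msk <- readMask(file.path(dir, "canopy_Pukou_booting_1_truth.png"))
  expect_identical(maskMatrix(msk),
                   maskMatrix(out$truths$canopy[[key]]))
  poly <- readPlotPolygons(
    file.path(dir, "plot_Pukou_booting_polygons.json"))
  expect_equal(poly[[1]]$vertices,
               out$polygons[["Pukou/booting"]][[1]]$vertices,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
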