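# Field-level dataset generation: LNC draws per site x stage x plot,
# optional imagery at the requested scales, CSV-compatible sample table.

# Truncated-normal draws by rejection; acceptance is ~1 for the study's
# mean/SD values so this never loops meaningfully.
.rtruncnorm <- function(n, mean, sd, lower = 0.5, upper = 4.5) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- stats::rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic field dataset
#'
#' Draws one LNC value per site x stage x plot from a normal distribution
#' with the design's stage-specific mean and SD, truncated to
#' \[0.5, 4.5\] % to exclude non-physical concentrations, and optionally
#' renders imagery at the requested scales. Each scene (and each plot's
#' LNC draw) uses its own RNG stream derived from the master seed and the
#' (site, stage, plot) key, so adding or removing plots does not perturb
#' other scenes. Identical seed gives an identical table.
#'
#' @param design a [FieldDesign-class].
#' @param scales character subset of `c("leaf", "canopy", "plot")`; for
#'   each requested scale one image per plot is generated (`"plot"` gives
#'   one mosaic per site x stage covering all its plots).
#' @param sceneConfigs named list of [SceneConfig-class] templates by
#'   scale; defaults are built with [sceneConfig()].
#' @param mapping a [ColorMapping-class] used for all scenes.
#' @param vegFractionRange optional length-2 numeric; when given, each
#'   canopy/plot scene draws its vegetation fraction uniformly from this
#'   range (canopy cover varies across real plots; without variation,
#'   background contamination would be a fixed offset).
#' @param dir optional directory; when given, images, truth masks and the
#'   sample table are written there (PNG / CSV / JSON).
#' @return list with `table` (data.frame: site, year, stage, plot_id,
#'   lnc_percent), `images` and `truths` (nested lists by scale, or empty
#'   when no scales requested), and `polygons` (plot scale only).
#' @examples
#' fd <- fieldDesign(seed = 7)
#' tab <- generateFieldDataset(fd)$table
#' head(tab)
#' @export
generateFieldDataset <- function(design, scales = character(0),
                                 sceneConfigs = NULL,
                                 mapping = colorMapping(),
                                 vegFractionRange = NULL, dir = NULL) {
  stopifnot(is(design, "FieldDesign"))
  bad <- setdiff(scales, .SCALES)
  if (length(bad)) stop("unknown scale(s): ", paste(bad, collapse = ", "))
  if (is.null(sceneConfigs)) sceneConfigs <- list()
  for (sc in scales) {
    if (is.null(sceneConfigs[[sc]]))
      sceneConfigs[[sc]] <- sceneConfig(sc, 64L, 64L)
  }

  d <- design@design
  rows <- vector("list", nrow(d))
  images <- truths <- polygons <- list()
  for (g in seq_len(nrow(d))) {
    site <- d$site[g]; stage <- d$stage[g]; nP <- d$nPlots[g]
    lncs <- numeric(nP)
    for (p in seq_len(nP)) {
      key <- paste(site, stage, p, sep = "/")
      lncs[p] <- withSceneSeed(sceneSeed(design@seed, paste0("lnc/", key)),
                               .rtruncnorm(1, d$mean[g], d$sd[g]))
    }
    rows[[g]] <- data.frame(site = site, year = d$year[g], stage = stage,
                            plot_id = seq_len(nP), lnc_percent = lncs,
                            stringsAsFactors = FALSE)
    for (sc in setdiff(scales, "plot")) {
      cfgT <- sceneConfigs[[sc]]
      for (p in seq_len(nP)) {
        key <- paste(site, stage, p, sep = "/")
        cfgP <- .sceneVariant(cfgT, design@seed, paste0(sc, "/", key),
                              vegFractionRange)
        scn <- if (sc == "leaf") generateLeafScan(lncs[p], cfgP, mapping)
               else generateCanopyScene(lncs[p], cfgP, mapping)
        images[[sc]][[key]] <- scn$image
        truths[[sc]][[key]] <- scn$truth
      }
    }
    if ("plot" %in% scales) {
      key <- paste(site, stage, sep = "/")
      cfgP <- .sceneVariant(sceneConfigs[["plot"]], design@seed,
                            paste0("plot/", key), vegFractionRange)
      mos <- generatePlotMosaic(lncs, cfgP, mapping)
      images[["plot"]][[key]] <- mos$image
      truths[["plot"]][[key]] <- mos$truth
      polygons[[key]] <- mos$polygons
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeSampleTable(table, file.path(dir, "samples.csv"))
    for (sc in names(images)) {
      for (key in names(images[[sc]])) {
        stem <- file.path(dir, paste0(sc, "_", gsub("/", "_", key)))
        writeRGBImage(images[[sc]][[key]], paste0(stem, ".png"))
        writeMask(truths[[sc]][[key]], paste0(stem, "_truth.png"))
      }
    }
    for (key in names(polygons)) {
      writePlotPolygons(polygons[[key]],
                        file.path(dir, paste0("plot_", gsub("/", "_", key),
                                              "_polygons.json")))
    }
  }
  list(table = table, images = images, truths = truths, polygons = polygons)
}

# Per-scene config: derived seed, optional vegetation-fraction draw.
.sceneVariant <- function(cfgT, masterSeed, key, vegFractionRange) {
  sd_ <- sceneSeed(masterSeed, key)
  vf <- cfgT@vegFraction
  if (!is.null(vegFractionRange)) {
    vf <- withSceneSeed(sceneSeed(masterSeed, paste0("vf/", key)),
                        stats::runif(1, vegFractionRange[1],
                                     vegFractionRange[2]))
  }
  sceneConfig(cfgT@scale, cfgT@height, cfgT@width, vegFraction = vf,
              backgroundPalette = cfgT@backgroundPalette,
              noiseSd = cfgT@noiseSd, gmrMargin = cfgT@gmrMargin,
              seed = sd_)
}

#' Simulate a color-index design table
#'
#' Draws independent random channel means and computes the 13 color
#' indices for each sample. This is the regression test-bed: unlike
#' image-derived tables (where all indices are functions of a single
#' underlying LNC and hence perfectly confounded), independent channel
#' variation makes the generating index set of a simulated response
#' identifiable.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with the 13 index columns in the fixed order of
#'   [computeColorIndices()].
#' @examples
#' head(simulateIndexTable(5, seed = 1))
#' @export
simulateIndexTable <- function(n, seed = 1L) {
  withSceneSeed(seed, {
    R <- stats::runif(n, 20, 230)
    G <- stats::runif(n, 20, 230)
    B <- stats::runif(n, 10, 220)
    out <- t(vapply(seq_len(n),
                    function(i) computeColorIndices(R[i], G[i], B[i]),
                    numeric(13)))
    as.data.frame(out)
  })
}
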