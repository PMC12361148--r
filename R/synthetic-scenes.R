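# Synthetic scene generators: leaf scans, canopy scenes, plot mosaics.
# Every scene is a pure function of (lnc, config, mapping); RNG streams are
# local to the scene and derived from the config seed.

# Gaussian DN noise, then 8-bit quantization: round and clip to [0, 255].
.quantize8 <- function(x, noiseSd) {
  if (noiseSd > 0) x <- x + stats::rnorm(length(x), 0, noiseSd)
  arr <- pmin(pmax(round(x), 0), 255)
  storage.mode(arr) <- "integer"
  dim(arr) <- dim(x)
  arr
}

# Fill an h x w x 3 double array with palette rows sampled per pixel.
.paletteField <- function(h, w, palette) {
  idx <- if (nrow(palette) == 1L) rep(1L, h * w) else
    sample.int(nrow(palette), h * w, replace = TRUE)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(palette[idx, ch], h, w)
  arr
}

#' Map LNC to mean channel DN
#'
#' Applies the linear per-channel map `intercept + slope * lnc` and clips
#' the result to \[0, 255\]. Deterministic.
#'
#' @param lnc leaf nitrogen concentration (%), must be > 0.
#' @param mapping a [ColorMapping-class].
#' @return named numeric length 3 (R, G, B), DN.
#' @examples
#' lncToChannelMeans(2.0, colorMapping())
#' @export
lncToChannelMeans <- function(lnc, mapping = colorMapping()) {
  if (!is.numeric(lnc) || length(lnc) != 1L || is.na(lnc) || lnc <= 0)
    stop("lnc must be a single positive number")
  v <- mapping@intercepts + mapping@slopes * lnc
  v <- pmin(pmax(v, 0), 255)
  names(v) <- c("R", "G", "B")
  v
}

#' Generate a synthetic leaf scan with ground truth
#'
#' Emulates a flatbed scan of a single leaf on a near-white background:
#' an elliptical leaf-shaped region whose channel means follow
#' [lncToChannelMeans()], plus i.i.d. Gaussian pixel noise quantized to
#' 8 bits. Identical config and seed give bit-identical output.
#'
#' @param lnc leaf nitrogen concentration (%).
#' @param cfg a [SceneConfig-class] with `scale = "leaf"`; `vegFraction`
#'   sets the leaf area as a fraction of the image.
#' @param mapping a [ColorMapping-class].
#' @return list with elements `image` ([RGBImage-class]) and `truth`
#'   ([SegmentationMask-class], method `"truth"`).
#' @examples
#' sc <- generateLeafScan(2.3, sceneConfig("leaf", 64, 64, noiseSd = 0))
#' foregroundCount(sc$truth)
#' @export
generateLeafScan <- function(lnc, cfg, mapping = colorMapping()) {
  if (cfg@scale != "leaf") stop("cfg$scale must be 'leaf'")
  h <- cfg@height; w <- cfg@width
  # ellipse with area vegFraction * h * w and axes proportional to the
  # image sides; s > 1 means the leaf cannot fit inside the frame
  s <- sqrt(4 * cfg@vegFraction / pi)
  if (s > 1) stop("invalid config: leaf region would exceed image bounds")
  a <- s * h / 2; b <- s * w / 2
  rc <- (row(matrix(0, h, w)) - 0.5 - h / 2)
  cc <- (col(matrix(0, h, w)) - 0.5 - w / 2)
  truth <- if (cfg@vegFraction == 0) matrix(FALSE, h, w) else
    (rc / a)^2 + (cc / b)^2 <= 1
  leafCol <- lncToChannelMeans(lnc, mapping)
  img <- withSceneSeed(cfg@seed, {
    arr <- .paletteField(h, w, cfg@backgroundPalette)
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[truth] <- leafCol[ch]
      arr[, , ch] <- plane
    }
    .quantize8(arr, cfg@noiseSd)
  })
  list(image = rgbImage(img, "leaf"),
       truth = segmentationMask(truth, "truth"))
}

#' Generate a synthetic canopy scene with ground truth
#'
#' Emulates a nadir photograph of a rice canopy over a heterogeneous
#' soil/water background. Vegetation pixels (a Bernoulli field with
#' probability `vegFraction`) take the LNC-mapped color, with the green
#' channel floored at `R + gmrMargin` so vegetation has pre-noise
#' G - R >= `gmrMargin`; background pixels are drawn from the palette
#' (all with R >= G, hence pre-noise G - R <= 0).
#'
#' @inheritParams generateLeafScan
#' @param cfg a [SceneConfig-class] with `scale = "canopy"` and
#'   `gmrMargin > 0`.
#' @return list with elements `image` and `truth` as in
#'   [generateLeafScan()].
#' @export
generateCanopyScene <- function(lnc, cfg, mapping = colorMapping()) {
  if (cfg@scale != "canopy") stop("cfg$scale must be 'canopy'")
  if (cfg@gmrMargin <= 0)
    stop("invalid config: gmrMargin must be > 0 (classes inseparable)")
  if (any(cfg@backgroundPalette[, 1] < cfg@backgroundPalette[, 2]))
    stop("invalid config: background palette must satisfy R >= G")
  h <- cfg@height; w <- cfg@width
  vegCol <- lncToChannelMeans(lnc, mapping)
  vegCol["G"] <- min(max(vegCol["G"], vegCol["R"] + cfg@gmrMargin), 255)
  res <- withSceneSeed(cfg@seed, {
    truth <- matrix(stats::runif(h * w) < cfg@vegFraction, h, w)
    arr <- .paletteField(h, w, cfg@backgroundPalette)
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[truth] <- vegCol[ch]
      arr[, , ch] <- plane
    }
    list(img = .quantize8(arr, cfg@noiseSd), truth = truth)
  })
  list(image = rgbImage(res$img, "canopy"),
       truth = segmentationMask(res$truth, "truth"))
}

#' Generate a synthetic plot mosaic with polygons and ground truth
#'
#' Emulates an orthomosaic of a gridded field trial: rectangular treatment
#' plots separated by background-colored bunds, each plot rendered as a
#' canopy scene driven by its own LNC. Returned polygons (0-based
#' row/col vertex coordinates) exactly enclose each plot's pixels under
#' the pixel-center point-in-polygon convention of [clipToPolygon()].
#'
#' @param plotLncs numeric vector of per-plot LNC values (%), >= 1 plot.
#' @param cfg a [SceneConfig-class] with `scale = "plot"`.
#' @param mapping a [ColorMapping-class].
#' @param bund bund (border) width in pixels between and around plots.
#' @return list with `image`, `polygons` (list of
#'   `list(plot_id, vertices)`), and `truth`.
#' @export
generatePlotMosaic <- function(plotLncs, cfg, mapping = colorMapping(),
                               bund = 4L) {
  if (cfg@scale != "plot") stop("cfg$scale must be 'plot'")
  k <- length(plotLncs)
  if (k < 1L) stop("at least one plot is required")
  h <- cfg@height; w <- cfg@width
  gcols <- ceiling(sqrt(k)); grows <- ceiling(k / gcols)
  ph <- floor((h - (grows + 1L) * bund) / grows)
  pw <- floor((w - (gcols + 1L) * bund) / gcols)
  if (ph < 4L || pw < 4L)
    stop("invalid config: plots do not fit the image dimensions")
  arr <- withSceneSeed(sceneSeed(cfg@seed, "mosaic-background"), {
    .quantize8(.paletteField(h, w, cfg@backgroundPalette), cfg@noiseSd)
  })
  truth <- matrix(FALSE, h, w)
  polygons <- vector("list", k)
  for (i in seq_len(k)) {
    gr <- ceiling(i / gcols); gc <- i - (gr - 1L) * gcols
    r0 <- bund + (gr - 1L) * (ph + bund)   # 0-based offsets
    c0 <- bund + (gc - 1L) * (pw + bund)
    sub <- sceneConfig("canopy", ph, pw,
                       vegFraction = cfg@vegFraction,
                       backgroundPalette = cfg@backgroundPalette,
                       noiseSd = cfg@noiseSd, gmrMargin = cfg@gmrMargin,
                       seed = sceneSeed(cfg@seed, paste0("plot-", i)))
    scn <- generateCanopyScene(plotLncs[i], sub, mapping)
    rows <- (r0 + 1L):(r0 + ph); cols <- (c0 + 1L):(c0 + pw)
    arr[rows, cols, ] <- scn$image@data
    truth[rows, cols] <- maskMatrix(scn$truth)
    polygons[[i]] <- list(
      plot_id = i,
      vertices = matrix(c(r0,      c0,
                          r0,      c0 + pw,
                          r0 + ph, c0 + pw,
                          r0 + ph, c0),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("row", "col"))))
  }
  list(image = rgbImage(arr, "plot"), polygons = polygons,
       truth = segmentationMask(truth, "truth"))
}
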