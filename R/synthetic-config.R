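# Scene/mapping/design constructors with the study defaults.

# Run `expr` with its own RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. Every generator goes through this, so
# scenes are pure functions of (config, seed).
withSceneSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-scene RNG seed
#'
#' Splits a master seed into an independent stream seed via a polynomial
#' rolling hash of a scene key (e.g. `"Pukou/booting/7"`), modulo a prime
#' below 2^31. Each scene getting its own stream means inserting or
#' removing plots never perturbs the draws of other scenes.
#'
#' @param masterSeed integer master seed.
#' @param key character scene key.
#' @return an integer seed.
#' @export
sceneSeed <- function(masterSeed, key) {
  h <- as.double(masterSeed) %% 2147483629
  for (code in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h)
}

#' Default background palettes
#'
#' Leaf scans have a near-white scanner background; canopy and plot scenes
#' have soil / water / residue backgrounds, all with R >= G so that the
#' green-minus-red index of background pixels is <= 0 by construction.
#'
#' @param scale `"leaf"`, `"canopy"`, or `"plot"`.
#' @return numeric matrix (n x 3) of RGB triples.
#' @export
defaultBackgroundPalette <- function(scale = c("canopy", "leaf", "plot")) {
  scale <- match.arg(scale)
  if (scale == "leaf") {
    matrix(c(250, 250, 250), ncol = 3,
           dimnames = list(NULL, c("R", "G", "B")))
  } else {
    # wet soil, dry residue, grey water -- all with G - R <= -12 so the
    # classes stay separable through 8-DN channel noise
    matrix(c(120, 100,  80,
             150, 135, 118,
             100,  88, 105),
           ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("R", "G", "B")))
  }
}

#' Create a SceneConfig
#'
#' @param scale acquisition scale of the scene.
#' @param height,width image dimensions in pixels.
#' @param vegFraction target fraction of vegetation/leaf pixels in \[0, 1\].
#' @param backgroundPalette n x 3 matrix of background RGB triples; defaults
#'   to [defaultBackgroundPalette()] for the scale.
#' @param noiseSd per-pixel, per-channel Gaussian noise SD (DN).
#' @param gmrMargin minimum pre-noise G - R of vegetation pixels (DN).
#' @param seed integer master seed for the scene.
#' @return a [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig("canopy", 64, 64, vegFraction = 0.65, noiseSd = 0)
#' @export
sceneConfig <- function(scale = c("canopy", "leaf", "plot"),
                        height = 256L, width = 256L,
                        vegFraction = if (scale == "leaf") 0.35 else 0.65,
                        backgroundPalette = defaultBackgroundPalette(scale),
                        noiseSd = 8, gmrMargin = 25, seed = 1L) {
  scale <- match.arg(scale)
  force(vegFraction)
  new("SceneConfig", scale = scale,
      height = as.integer(height), width = as.integer(width),
      vegFraction = vegFraction, backgroundPalette = backgroundPalette,
      noiseSd = noiseSd, gmrMargin = gmrMargin, seed = as.integer(seed))
}

#' Create a ColorMapping
#'
#' Linear per-channel map from LNC (%) to mean channel DN, clipped to
#' \[0, 255\]. The default makes leaves darker (R and G fall) and bluer
#' (B rises) as nitrogen increases, so NBI rises and NRI falls with LNC,
#' and gives vegetation a G - R of 10 + 18 LNC, comfortably above the
#' default segmentation margin over the observed LNC range.
#'
#' @param intercepts numeric length-3 (R, G, B) intercepts, DN.
#' @param slopes numeric length-3 (R, G, B) slopes, DN per LNC %.
#' @return a [ColorMapping-class] object.
#' @export
colorMapping <- function(intercepts = c(140, 150, 45),
                         slopes = c(-28, -10, 10)) {
  new("ColorMapping", intercepts = as.numeric(intercepts),
      slopes = as.numeric(slopes))
}

#' Create a FieldDesign
#'
#' Default design mirrors the two-site rice experiment summary: per-stage
#' LNC mean and SD at Pukou (n = 40 per stage) and Liuhe (n = 30 per
#' stage) across booting, flowering, and grain-filling.
#'
#' @param design data.frame with columns site, year, stage, mean, sd,
#'   nPlots.
#' @param seed integer master seed for LNC draws.
#' @return a [FieldDesign-class] object.
#' @examples
#' fd <- fieldDesign()
#' fd@design
#' @export
fieldDesign <- function(design = NULL, seed = 1L) {
  if (is.null(design)) {
    design <- data.frame(
      site   = rep(c("Pukou", "Liuhe"), each = 3),
      year   = 2019L,
      stage  = rep(c("booting", "flowering", "filling"), 2),
      mean   = c(2.31, 2.01, 1.71, 3.00, 2.55, 1.98),
      sd     = c(0.41, 0.35, 0.42, 0.49, 0.39, 0.50),
      nPlots = rep(c(40L, 30L), each = 3),
      stringsAsFactors = FALSE)
  }
  new("FieldDesign", design = design, seed = as.integer(seed))
}
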