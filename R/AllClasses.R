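#' @import methods
NULL

.SCALES <- c("leaf", "canopy", "plot")
.MASK_METHODS <- c("otsu", "gmr", "truth", "clip", "all")
.STAGES <- c("booting", "flowering", "filling")

#' RGBImage: an 8-bit three-channel raster
#'
#' Container for an RGB image as acquired by a flatbed scanner, a digital
#' camera, or a UAV-mounted camera. Pixel values are digital numbers (DN)
#' in \[0, 255\]; the `scale` tag records the acquisition level.
#'
#' @slot data integer array of dimension height x width x 3 (R, G, B planes),
#'   values in \[0, 255\].
#' @slot scale one of `"leaf"`, `"canopy"`, `"plot"`.
#' @exportClass RGBImage
setClass("RGBImage",
  representation(data = "array", scale = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      return("data must be a height x width x 3 array")
    if (anyNA(d)) return("data must not contain NA")
    if (min(d) < 0 || max(d) > 255)
      return("all DN values must lie in [0, 255]")
    if (any(d != round(d)))
      return("DN values must be whole numbers")
    if (length(object@scale) != 1L || !object@scale %in% .SCALES)
      return(sprintf("scale must be one of %s",
                     paste(.SCALES, collapse = ", ")))
    TRUE
  })

#' SegmentationMask: a boolean foreground mask aligned to an image
#'
#' @slot mask logical matrix; `TRUE` marks vegetation/leaf foreground.
#' @slot method one of `"otsu"`, `"gmr"`, `"truth"`, `"clip"`, `"all"`.
#' @slot threshold numeric threshold used by the method (`NA` if none).
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(mask = "matrix", method = "character",
                 threshold = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    if (anyNA(object@mask)) return("mask must not contain NA")
    if (length(object@method) != 1L || !object@method %in% .MASK_METHODS)
      return(sprintf("method must be one of %s",
                     paste(.MASK_METHODS, collapse = ", ")))
    if (length(object@threshold) != 1L) return("threshold must be length 1")
    TRUE
  })

#' ColorMapping: linear LNC-to-channel-mean map
#'
#' Defines the synthetic relation between leaf nitrogen concentration and
#' mean channel DN: `channel = intercept + slope * lnc`, clipped to
#' \[0, 255\]. The default map makes leaves darker and bluer at high LNC,
#' so that NBI correlates positively and NRI negatively with LNC.
#'
#' @slot intercepts numeric length-3 (R, G, B) intercepts in DN.
#' @slot slopes numeric length-3 (R, G, B) slopes in DN per LNC %.
#' @exportClass ColorMapping
setClass("ColorMapping",
  representation(intercepts = "numeric", slopes = "numeric"),
  validity = function(object) {
    if (length(object@intercepts) != 3L || length(object@slopes) != 3L)
      return("intercepts and slopes must each have length 3 (R, G, B)")
    if (anyNA(object@intercepts) || anyNA(object@slopes))
      return("intercepts and slopes must not contain NA")
    TRUE
  })

#' SceneConfig: parameters of a synthetic scene
#'
#' @slot scale one of `"leaf"`, `"canopy"`, `"plot"`.
#' @slot height,width image dimensions in pixels.
#' @slot vegFraction target foreground fraction in \[0, 1\].
#' @slot backgroundPalette numeric matrix (n x 3) of background RGB triples.
#' @slot noiseSd per-pixel, per-channel Gaussian noise SD in DN (>= 0).
#' @slot gmrMargin minimum pre-noise G - R of vegetation pixels, DN.
#' @slot seed integer master seed for the scene.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(scale = "character", height = "integer", width = "integer",
                 vegFraction = "numeric", backgroundPalette = "matrix",
                 noiseSd = "numeric", gmrMargin = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@scale %in% .SCALES)
      return(sprintf("scale must be one of %s",
                     paste(.SCALES, collapse = ", ")))
    if (object@height < 1L || object@width < 1L)
      return("height and width must be positive")
    if (is.na(object@vegFraction) ||
        object@vegFraction < 0 || object@vegFraction > 1)
      return("vegFraction must lie in [0, 1]")
    if (is.na(object@noiseSd) || object@noiseSd < 0)
      return("noiseSd must be >= 0")
    p <- object@backgroundPalette
    if (ncol(p) != 3L || nrow(p) < 1L)
      return("backgroundPalette must be an n x 3 matrix of RGB triples")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("all palette DNs must lie in [0, 255]")
    TRUE
  })

#' FieldDesign: site-by-stage LNC distribution and plot counts
#'
#' Describes the sampling design of a two-site field experiment: for each
#' site and growth stage, the mean and SD of the LNC distribution and the
#' number of plots sampled. Defaults reproduce the observed summary
#' statistics of the Pukou and Liuhe rice experiments.
#'
#' @slot design data.frame with columns site, year, stage, mean, sd, nPlots.
#' @slot seed integer master seed.
#' @exportClass FieldDesign
setClass("FieldDesign",
  representation(design = "data.frame", seed = "integer"),
  validity = function(object) {
    d <- object@design
    need <- c("site", "year", "stage", "mean", "sd", "nPlots")
    if (!all(need %in% names(d)))
      return(sprintf("design must have columns %s",
                     paste(need, collapse = ", ")))
    if (nrow(d) < 1L) return("design must have at least one row")
    if (any(d$sd < 0)) return("all SDs must be >= 0")
    if (any(d$nPlots < 1)) return("all plot counts must be >= 1")
    if (!all(d$stage %in% .STAGES))
      return(sprintf("stage must be one of %s",
                     paste(.STAGES, collapse = ", ")))
    TRUE
  })

#' SMLRModel: a fitted stepwise multiple linear regression model
#'
#' @slot terms character vector of selected index names, in entry order.
#' @slot coefficients named numeric: `(Intercept)` plus one per term,
#'   in LNC % per index unit.
#' @slot pValues named numeric, two-sided t-test p-value per retained term.
#' @slot n number of observations used in the fit.
#' @slot trace data.frame of selection steps (step, action, term, p).
#' @slot candidates character vector of the candidate pool, in the fixed
#'   index-table order used for tie-breaking.
#' @exportClass SMLRModel
setClass("SMLRModel",
  representation(terms = "character", coefficients = "numeric",
                 pValues = "numeric", n = "integer", trace = "data.frame",
                 candidates = "character"),
  validity = function(object) {
    if (length(object@coefficients) != length(object@terms) + 1L)
      return("coefficients must be intercept plus one per term")
    if (length(object@pValues) != length(object@terms))
      return("pValues must have one entry per term")
    TRUE
  })

#' FitMetrics: goodness-of-fit summary for LNC predictions
#'
#' @slot r2 coefficient of determination (dimensionless).
#' @slot rmse root mean square error, LNC percentage points.
#' @slot nrmse RMSE normalized by mean observed LNC, percent.
#' @slot band quality band: excellent / good / fair / poor.
#' @slot n number of prediction-observation pairs.
#' @slot meanObserved mean observed LNC (%).
#' @exportClass FitMetrics
setClass("FitMetrics",
  representation(r2 = "numeric", rmse = "numeric", nrmse = "numeric",
                 band = "character", n = "integer", meanObserved = "numeric"),
  validity = function(object) {
    if (object@rmse < 0) return("rmse must be >= 0")
    if (object@nrmse < 0) return("nrmse must be >= 0")
    if (!object@band %in% c("excellent", "good", "fair", "poor"))
      return("band must be excellent, good, fair, or poor")
    TRUE
  })
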