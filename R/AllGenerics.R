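#' @rdname RGBImage-class
#' @param x an `RGBImage` or `SegmentationMask`.
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))

#' @rdname RGBImage-class
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))

#' @rdname RGBImage-class
#' @export
setGeneric("imageScale", function(x) standardGeneric("imageScale"))

#' @rdname RGBImage-class
#' @param which channel name, one of `"R"`, `"G"`, `"B"`.
#' @export
setGeneric("channel", function(x, which) standardGeneric("channel"))

#' @rdname SegmentationMask-class
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname SegmentationMask-class
#' @export
setGeneric("maskMethod", function(x) standardGeneric("maskMethod"))

#' @rdname SegmentationMask-class
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))

#' @rdname SegmentationMask-class
#' @export
setGeneric("foregroundCount", function(x) standardGeneric("foregroundCount"))

#' @rdname SMLRModel-class
#' @export
setGeneric("selectedTerms", function(x) standardGeneric("selectedTerms"))

#' @rdname SMLRModel-class
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @rdname FitMetrics-class
#' @export
setGeneric("qualityBand", function(x) standardGeneric("qualityBand"))
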