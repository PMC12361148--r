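# Constructors, accessors and show methods for the core classes.

#' Create an RGBImage
#'
#' @param data height x width x 3 array of DN values in \[0, 255\]; whole
#'   numbers (stored as integer).
#' @param scale acquisition scale: `"leaf"`, `"canopy"`, or `"plot"`.
#' @return an [RGBImage-class] object.
#' @examples
#' img <- rgbImage(array(100L, dim = c(4, 4, 3)), scale = "leaf")
#' imgHeight(img)
#' @export
rgbImage <- function(data, scale = "canopy") {
  storage.mode(data) <- "integer"
  new("RGBImage", data = data, scale = scale)
}

#' Create a SegmentationMask
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param method segmentation method tag.
#' @param threshold threshold used, if any.
#' @return a [SegmentationMask-class] object.
#' @export
segmentationMask <- function(mask, method, threshold = NA_real_) {
  new("SegmentationMask", mask = mask, method = method,
      threshold = as.numeric(threshold))
}

#' @rdname RGBImage-class
#' @export
setMethod("imgHeight", "RGBImage", function(x) dim(x@data)[1])
#' @rdname RGBImage-class
#' @export
setMethod("imgWidth", "RGBImage", function(x) dim(x@data)[2])
#' @rdname RGBImage-class
#' @export
setMethod("imageScale", "RGBImage", function(x) x@scale)
#' @rdname RGBImage-class
#' @export
setMethod("channel", "RGBImage", function(x, which) {
  i <- match(which, c("R", "G", "B"))
  if (is.na(i)) stop("channel must be one of 'R', 'G', 'B'")
  m <- x@data[, , i, drop = FALSE]
  dim(m) <- dim(x@data)[1:2]
  m
})

#' @rdname SegmentationMask-class
#' @export
setMethod("maskMatrix", "SegmentationMask", function(x) x@mask)
#' @rdname SegmentationMask-class
#' @export
setMethod("maskMethod", "SegmentationMask", function(x) x@method)
#' @rdname SegmentationMask-class
#' @export
setMethod("maskThreshold", "SegmentationMask", function(x) x@threshold)
#' @rdname SegmentationMask-class
#' @export
setMethod("foregroundCount", "SegmentationMask", function(x) sum(x@mask))
#' @rdname SegmentationMask-class
#' @export
setMethod("imgHeight", "SegmentationMask", function(x) nrow(x@mask))
#' @rdname SegmentationMask-class
#' @export
setMethod("imgWidth", "SegmentationMask", function(x) ncol(x@mask))

#' @rdname SMLRModel-class
#' @export
setMethod("selectedTerms", "SMLRModel", function(x) x@terms)
#' @rdname SMLRModel-class
#' @export
setMethod("selectionTrace", "SMLRModel", function(x) x@trace)
#' @rdname SMLRModel-class
#' @param object an `SMLRModel`.
#' @export
setMethod("coef", "SMLRModel", function(object) object@coefficients)

#' @rdname FitMetrics-class
#' @export
setMethod("qualityBand", "FitMetrics", function(x) x@band)

setMethod("show", "RGBImage", function(object) {
  cat(sprintf("RGBImage: %d x %d, scale = %s, DN range [%d, %d]\n",
              imgHeight(object), imgWidth(object), object@scale,
              min(object@data), max(object@data)))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf(
    "SegmentationMask: %d x %d, method = %s%s, foreground = %d px (%.1f%%)\n",
    nrow(object@mask), ncol(object@mask), object@method,
    if (is.na(object@threshold)) "" else
      sprintf(" (threshold %g)", object@threshold),
    sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "SMLRModel", function(object) {
  cat(sprintf("SMLRModel: %d term(s) selected from %d candidates (n = %d)\n",
              length(object@terms), length(object@candidates), object@n))
  if (length(object@terms)) {
    for (tm in object@terms)
      cat(sprintf("  %-5s coef = %10.5f  p = %.3g\n",
                  tm, object@coefficients[tm], object@pValues[tm]))
    cat(sprintf("  intercept = %.5f\n", object@coefficients["(Intercept)"]))
  } else {
    cat("  (intercept-only model)\n")
  }
})

setMethod("show", "FitMetrics", function(object) {
  cat(sprintf(
    "FitMetrics (n = %d): R2 = %.4f, RMSE = %.4f %%LNC, NRMSE = %.2f%% [%s]\n",
    object@n, object@r2, object@rmse, object@nrmse, object@band))
})

#' @rdname FitMetrics-class
#' @param x a `FitMetrics` object.
#' @param ... unused.
#' @return `as.list` returns the metric fields as a plain list.
#' @export
setMethod("as.list", "FitMetrics", function(x, ...) {
  list(r2 = x@r2, rmse = x@rmse, nrmse = x@nrmse, band = x@band,
       n = x@n, meanObserved = x@meanObserved)
})
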