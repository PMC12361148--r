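# File interfaces: 8-bit RGB PNG images, 0/255 single-channel mask PNGs,
# CSV sample tables, JSON plot polygons, JSON model serialization.

#' Read and write RGB images as 8-bit PNG
#'
#' @param path file path.
#' @param scale acquisition scale tag to attach on read.
#' @return `readRGBImage` returns an [RGBImage-class].
#' @export
readRGBImage <- function(path, scale = "canopy") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  rgbImage(array(as.integer(round(a * 255)), dim = dim(a)), scale)
}

#' @rdname readRGBImage
#' @param image an [RGBImage-class].
#' @export
writeRGBImage <- function(image, path) {
  stopifnot(is(image, "RGBImage"))
  png::writePNG(image@data / 255, path)
  invisible(path)
}

#' Read and write segmentation masks as 0/255 single-channel PNG
#'
#' @param path file path.
#' @param method,threshold mask metadata to attach on read.
#' @return `readMask` returns a [SegmentationMask-class].
#' @export
readMask <- function(path, method = "truth", threshold = NA_real_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  segmentationMask(a >= 0.5, method, threshold)
}

#' @rdname readMask
#' @param mask a [SegmentationMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  png::writePNG(maskMatrix(mask) * 1.0, path)
  invisible(path)
}

#' Read and write the sample table CSV
#'
#' Canonical header: `site,year,stage,plot_id,lnc_percent`.
#'
#' @param path file path.
#' @return `readSampleTable` returns a data.frame.
#' @export
readSampleTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readSampleTable
#' @param table the sample table data.frame.
#' @export
writeSampleTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read and write plot-boundary polygons as JSON
#'
#' JSON form: a list of `{plot_id, vertices: [[row, col], ...]}` objects
#' in 0-based pixel coordinates; polygons are implicitly closed.
#'
#' @param path file path.
#' @return `readPlotPolygons` returns a list of
#'   `list(plot_id, vertices)` entries with a k x 2 vertex matrix each.
#' @export
readPlotPolygons <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    v <- do.call(rbind, lapply(p$vertices, unlist))
    colnames(v) <- c("row", "col")
    list(plot_id = p$plot_id, vertices = v)
  })
}

#' @rdname readPlotPolygons
#' @param polygons list of `list(plot_id, vertices)` entries.
#' @export
writePlotPolygons <- function(polygons, path) {
  out <- lapply(polygons, function(p) {
    list(plot_id = p$plot_id,
         vertices = lapply(seq_len(nrow(p$vertices)),
                           function(i) as.numeric(p$vertices[i, ])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize an SMLR model and its metrics to JSON
#'
#' @param model an [SMLRModel-class].
#' @param metrics optional [FitMetrics-class].
#' @param path file path.
#' @param extra optional named list of extra fields (e.g. mode flags).
#' @return the path, invisibly.
#' @export
writeModelJSON <- function(model, path, metrics = NULL, extra = list()) {
  stopifnot(is(model, "SMLRModel"))
  payload <- c(list(
    terms = model@terms,
    coefficients = as.list(model@coefficients),
    pValues = as.list(model@pValues),
    n = model@n,
    trace = model@trace,
    indexConvention = "indices computed from foreground channel means"),
    if (!is.null(metrics)) list(metrics = as.list(metrics)),
    extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
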