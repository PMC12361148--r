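# Foreground/background separation: Otsu binarization for white-background
# leaf scans, green-minus-red (GMR) thresholding for field scenes, polygon
# clipping for plot extraction, and foreground channel statistics.

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the threshold t* maximizing the between-class variance
#' `w0(t) w1(t) (mu0(t) - mu1(t))^2`, where class 0 holds intensities <= t.
#' Ties are broken by the smallest maximizing t. Cumulative sums are exact
#' integer arithmetic on the counts; the final variance ratio is floating
#' point.
#'
#' @param histogram numeric vector of 256 non-negative counts for
#'   intensities 0..255.
#' @return integer threshold in 0..255.
#' @examples
#' h <- numeric(256); h[51] <- 100; h[201] <- 100  # spikes at 50 and 200
#' otsuThreshold(h)  # 50: variance is flat on [50, 199], smallest t wins
#' @export
otsuThreshold <- function(histogram) {
  if (length(histogram) != 256L || anyNA(histogram) || any(histogram < 0))
    stop("histogram must be 256 non-negative counts")
  if (sum(histogram > 0) < 2L)
    stop("degenerate histogram: fewer than two distinct non-zero bins")
  counts <- as.double(histogram)
  lev <- 0:255
  W <- sum(counts)
  S <- sum(lev * counts)
  w0 <- cumsum(counts)          # class 0: intensities <= t
  s0 <- cumsum(lev * counts)
  w1 <- W - w0
  # between-class variance: (s0*W - S*w0)^2 / (w0*w1*W^2); the W^2 factor
  # is constant in t and dropped
  bcv <- ifelse(w0 > 0 & w1 > 0, (s0 * W - S * w0)^2 / (w0 * w1), -Inf)
  as.integer(which.max(bcv) - 1L)   # which.max takes the first (smallest t)
}

# 256-bin histogram of an integer matrix with values 0..255
.hist256 <- function(gray) {
  tabulate(as.integer(gray) + 1L, nbins = 256L)
}

#' Segment a leaf scan by Otsu binarization
#'
#' Grayscale is the rounded per-pixel mean of the three channels; the Otsu
#' threshold is applied and the darker class (the leaf, against the white
#' scanner background) is taken as foreground.
#'
#' @param image an [RGBImage-class], leaf scale.
#' @return a [SegmentationMask-class] with method `"otsu"` and the
#'   threshold used.
#' @export
segmentLeaf <- function(image) {
  stopifnot(is(image, "RGBImage"))
  gray <- round((channel(image, "R") + channel(image, "G") +
                 channel(image, "B")) / 3)
  t_ <- otsuThreshold(.hist256(gray))
  fg <- gray <= t_   # class 0 has the lower mean: the dark leaf
  if (!any(fg))
    stop("empty foreground after Otsu segmentation (threshold ", t_, ")")
  segmentationMask(fg, "otsu", t_)
}

#' Per-pixel green-minus-red map
#'
#' Signed elementwise difference G - R, unclipped, in \[-255, 255\].
#'
#' @param image an [RGBImage-class].
#' @return integer matrix of G - R values.
#' @export
gmrMap <- function(image) {
  stopifnot(is(image, "RGBImage"))
  channel(image, "G") - channel(image, "R")
}

#' Segment vegetation by GMR thresholding
#'
#' Foreground is the set of pixels with G - R strictly greater than the
#' threshold; at threshold 0 achromatic pixels (G = R) are background. An
#' empty foreground is allowed here and only raises an error when channel
#' statistics are requested.
#'
#' @param image an [RGBImage-class].
#' @param threshold integer DN threshold; the study sweeps 0, 5, 10, 15, 20.
#' @return a [SegmentationMask-class] with method `"gmr"`.
#' @examples
#' cfg <- sceneConfig("canopy", 32, 32, noiseSd = 0, seed = 2)
#' scn <- generateCanopyScene(2.5, cfg)
#' identical(maskMatrix(segmentByGMR(scn$image, 5)), maskMatrix(scn$truth))
#' @export
segmentByGMR <- function(image, threshold) {
  stopifnot(is(image, "RGBImage"), is.numeric(threshold),
            length(threshold) == 1L)
  segmentationMask(gmrMap(image) > threshold, "gmr", threshold)
}

#' All-foreground mask (unsegmented statistics)
#'
#' The "before segmentation" convention: every pixel counts.
#'
#' @param image an [RGBImage-class].
#' @return a [SegmentationMask-class] with method `"all"`.
#' @export
fullMask <- function(image) {
  stopifnot(is(image, "RGBImage"))
  segmentationMask(matrix(TRUE, imgHeight(image), imgWidth(image)), "all")
}

#' Mean channel DN over the foreground
#'
#' @param image an [RGBImage-class].
#' @param mask a [SegmentationMask-class] aligned to the image.
#' @return named numeric: `R`, `G`, `B` (floating-point means) and
#'   `n_foreground` (pixel count).
#' @export
foregroundChannelMeans <- function(image, mask) {
  stopifnot(is(image, "RGBImage"), is(mask, "SegmentationMask"))
  m <- maskMatrix(mask)
  if (!identical(dim(m), dim(image@data)[1:2]))
    stop("mask is not aligned to the image")
  n <- sum(m)
  if (n == 0L)
    stop(sprintf("empty foreground (method %s%s)", maskMethod(mask),
                 if (is.na(maskThreshold(mask))) "" else
                   sprintf(", threshold %g", maskThreshold(mask))))
  c(R = mean(channel(image, "R")[m]),
    G = mean(channel(image, "G")[m]),
    B = mean(channel(image, "B")[m]),
    n_foreground = n)
}

#' Combine two masks by intersection
#'
#' Used for plot-scale statistics: clip-to-polygon composed with GMR
#' segmentation. Intersection commutes, so clip-then-gmr equals
#' gmr-then-clip.
#'
#' @param a,b [SegmentationMask-class] objects of equal shape.
#' @return a [SegmentationMask-class]; method/threshold are taken from `a`
#'   unless `a` is a clip/all mask, in which case from `b`.
#' @export
intersectMasks <- function(a, b) {
  stopifnot(identical(dim(maskMatrix(a)), dim(maskMatrix(b))))
  src <- if (maskMethod(a) %in% c("clip", "all")) b else a
  segmentationMask(maskMatrix(a) & maskMatrix(b), maskMethod(src),
                   maskThreshold(src))
}

#' Clip an image to a plot-boundary polygon
#'
#' Marks as foreground every pixel whose center lies inside (or on the
#' boundary of) the polygon under the even-odd rule. Coordinates are
#' 0-based (row, col); the center of pixel (i, j) (0-based) is at
#' (i + 0.5, j + 0.5), so an axis-aligned rectangle with integer vertices
#' (r0, c0)..(r1, c1) selects exactly the pixel block rows r0..r1-1,
#' cols c0..c1-1 and no center ever falls on an integer-coordinate edge.
#'
#' @param image an [RGBImage-class] (only its shape is used).
#' @param polygon numeric matrix (k x 2) of (row, col) vertices, k >= 3,
#'   implicitly closed, all inside the image bounds.
#' @return a [SegmentationMask-class] with method `"clip"`.
#' @examples
#' img <- rgbImage(array(0L, dim = c(32, 32, 3)), "plot")
#' rect <- matrix(c(10, 10, 10, 20, 20, 20, 20, 10), ncol = 2, byrow = TRUE)
#' foregroundCount(clipToPolygon(img, rect))  # 100 pixels
#' @export
clipToPolygon <- function(image, polygon) {
  stopifnot(is(image, "RGBImage"))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop("invalid polygon: fewer than 3 vertices")
  h <- imgHeight(image); w <- imgWidth(image)
  if (min(polygon) < 0 || max(polygon[, 1]) > h || max(polygon[, 2]) > w)
    stop("invalid polygon: vertices outside image bounds")
  # zero-area check via the shoelace formula
  ry <- polygon[, 1]; cx <- polygon[, 2]
  k <- nrow(polygon); nx <- c(2:k, 1)
  if (abs(sum(cx * ry[nx] - cx[nx] * ry)) / 2 == 0)
    stop("invalid polygon: zero area")
  pr <- rep(seq_len(h) - 0.5, times = w)   # pixel-center rows, 0-based
  pc <- rep(seq_len(w) - 0.5, each = h)    # pixel-center cols
  inside <- rep(FALSE, h * w)
  # even-odd ray cast: horizontal ray in +col direction per pixel center
  for (e in seq_len(k)) {
    r1 <- ry[e]; c1 <- cx[e]; r2 <- ry[nx[e]]; c2 <- cx[nx[e]]
    if (r1 == r2) next
    crosses <- (r1 > pr) != (r2 > pr)
    xint <- c1 + (pr - r1) / (r2 - r1) * (c2 - c1)
    inside <- xor(inside, crosses & pc < xint)
  }
  segmentationMask(matrix(inside, h, w), "clip")
}
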