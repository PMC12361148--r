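# The 13 RGB color indices, computed from foreground channel means
# (index-of-means convention: the ratio of means, not the mean of ratios).

.INDEX_ORDER <- c("R", "G", "B", "NRI", "NGI", "NBI", "ExR", "ExG",
                  "G_R", "G_B", "R_B", "GMR", "INT")

#' Compute the 13 color indices from channel means
#'
#' Given foreground mean digital numbers, returns (in fixed order): the
#' raw bands R, G, B; the normalized indices NRI = R/(R+G+B),
#' NGI = G/(R+G+B), NBI = B/(R+G+B); the excess-red and excess-green
#' indices ExR = (1.4R - G)/(R+G+B), ExG = (2G - R - B)/(R+G+B); the
#' ratios G/R, G/B, R/B (named `G_R`, `G_B`, `R_B`); the green-minus-red
#' difference GMR = G - R; and the intensity INT = (R+G+B)/3.
#'
#' Indices are computed from channel means, not averaged per-pixel — the
#' two differ for ratio indices.
#'
#' @param R,G,B channel mean DN values, each in \[0, 255\].
#' @return named numeric vector of length 13 in the fixed order
#'   `R, G, B, NRI, NGI, NBI, ExR, ExG, G_R, G_B, R_B, GMR, INT`.
#' @examples
#' computeColorIndices(120, 150, 60)
#' @export
computeColorIndices <- function(R, G, B) {
  for (v in list(R = R, G = G, B = B)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 255)
      stop("channel means must be single values in [0, 255]")
  }
  R <- unname(R); G <- unname(G); B <- unname(B)
  s <- R + G + B
  if (s == 0)
    stop("undefined indices NRI, NGI, NBI, ExR, ExG: R + G + B is zero")
  if (R == 0) stop("undefined index G_R: R is zero")
  if (B == 0) stop("undefined indices G_B, R_B: B is zero")
  c(R = R, G = G, B = B,
    NRI = R / s, NGI = G / s, NBI = B / s,
    ExR = (1.4 * R - G) / s, ExG = (2 * G - R - B) / s,
    G_R = G / R, G_B = G / B, R_B = R / B,
    GMR = G - R, INT = s / 3)
}

#' Build an index table from images and masks
#'
#' Convenience wrapper: foreground channel means per image, then the 13
#' indices, one row per image, columns in the fixed index order.
#'
#' @param images list of [RGBImage-class] objects.
#' @param masks list of [SegmentationMask-class] objects, parallel to
#'   `images`.
#' @return data.frame with the 13 index columns plus `n_foreground`.
#' @export
indexTable <- function(images, masks) {
  stopifnot(length(images) == length(masks))
  rows <- lapply(seq_along(images), function(i) {
    m <- foregroundChannelMeans(images[[i]], masks[[i]])
    c(computeColorIndices(m[["R"]], m[["G"]], m[["B"]]),
      n_foreground = m[["n_foreground"]])
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(images)
  out
}
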