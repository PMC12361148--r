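# Study-level experiments: stage-stratified correlation screens, summary
# tables, GMR threshold sweeps, cross-site transfer, and the
# segmentation-improvement accounting.

#' Pearson correlation with significance stars
#'
#' Two-sided p-value from the t-transform with n - 2 degrees of freedom;
#' `"**"` marks p < 0.01 and `"*"` marks 0.01 <= p < 0.05.
#'
#' @param x numeric index values.
#' @param y numeric LNC values.
#' @return list with `r`, `p`, and `star`.
#' @examples
#' pearsonWithStars(1:10, (1:10) + rnorm(10, 0, 0.1))
#' @export
pearsonWithStars <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  list(r = unname(ct$estimate), p = p,
       star = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' Stage-stratified correlation screen
#'
#' Pearson r, p, and star for every index column against LNC, within each
#' stage and in the pooled `"All"` partition.
#'
#' @param table data.frame with a `stage` column, an LNC column, and the
#'   index columns.
#' @param indices character vector of index column names.
#' @param lncColumn name of the LNC column.
#' @return data.frame with columns stage, index, r, p, star.
#' @export
correlationScreen <- function(table, indices = .INDEX_ORDER,
                              lncColumn = "lnc_percent") {
  parts <- c(split(table, table$stage), list(All = table))
  out <- list()
  for (st in names(parts)) {
    d <- parts[[st]]
    for (ix in indices) {
      res <- tryCatch(pearsonWithStars(d[[ix]], d[[lncColumn]]),
                      error = function(e) list(r = NA_real_, p = NA_real_,
                                               star = ""))
      out[[length(out) + 1L]] <- data.frame(
        stage = st, index = ix, r = res$r, p = res$p, star = res$star,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Site-by-stage LNC summary
#'
#' Groupwise n, min, max, mean, and SD (n - 1 denominator; `NA` for
#' single-sample groups).
#'
#' @param table sample table with columns site, stage, lnc_percent.
#' @return data.frame with one row per site x stage group.
#' @export
lncSummary <- function(table) {
  if (!nrow(table)) stop("empty sample table")
  groups <- split(table, list(table$site, table$stage), drop = TRUE)
  out <- lapply(groups, function(g) {
    v <- g$lnc_percent
    data.frame(site = g$site[1], stage = g$stage[1], n = length(v),
               min = min(v), max = max(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, match(res$stage, .STAGES)), , drop = FALSE]
}

#' Percent change between two quantities
#'
#' `100 (after - before) / before`, sign preserved: declines are negative.
#' When quoting a "decline", report the magnitude of the negative value.
#'
#' @param before,after the two quantities; `before` must be non-zero.
#' @return signed percent change.
#' @examples
#' percentChange(3.00, 2.55)   # -15: booting-to-flowering decline
#' percentChange(22.3, 26.6)   # +19.3: site difference in organic matter
#' @export
percentChange <- function(before, after) {
  if (!is.numeric(before) || length(before) != 1L || is.na(before) ||
      before == 0)
    stop("undefined percent change: 'before' must be a non-zero number")
  100 * (after - before) / before
}

#' Relative improvement in R2 after segmentation
#'
#' `100 (r2After - r2Before) / r2Before` by default (relative change,
#' which reproduces the published pre/post pair 0.54 -> 0.59 = +9.26%);
#' `method = "absolute"` gives the difference in R2 units times 100.
#'
#' @param r2Before pre-segmentation R2, must be > 0.
#' @param r2After post-segmentation R2.
#' @param method `"relative"` (default) or `"absolute"`.
#' @return percent improvement (negative when accuracy drops).
#' @examples
#' r2Improvement(0.54, 0.59)
#' @export
r2Improvement <- function(r2Before, r2After,
                          method = c("relative", "absolute")) {
  method <- match.arg(method)
  if (!is.numeric(r2Before) || length(r2Before) != 1L || is.na(r2Before) ||
      r2Before <= 0)
    stop("undefined improvement: r2Before must be > 0")
  if (method == "relative") 100 * (r2After - r2Before) / r2Before
  else 100 * (r2After - r2Before)
}

#' GMR threshold sweep
#'
#' For each threshold in the sweep: segment every image, compute the 13
#' indices from foreground channel means, select an SMLR model, and score
#' it by LOOCV — within each growth stage and in the pooled `"All"`
#' partition. Optionally includes the unsegmented (all-pixel, or
#' clip-only at plot scale) baseline as threshold `NA`. Cells whose
#' foreground is empty at some threshold are marked failed and the sweep
#' continues. The coefficient of variation (SD/mean, %) of each metric
#' across thresholds is reported per partition.
#'
#' @param images list of [RGBImage-class] objects, one per sample.
#' @param table data.frame parallel to `images` with columns
#'   `lnc_percent` and `stage`.
#' @param thresholds integer GMR thresholds (default 0, 5, 10, 15, 20).
#' @param includeUnsegmented also evaluate the before-segmentation
#'   baseline (all-true mask).
#' @param clipMasks optional list of [SegmentationMask-class] clip masks
#'   (plot scale); they are intersected with every segmentation mask and
#'   used alone for the baseline.
#' @param selection LOOCV selection mode, see [loocvEvaluate()].
#' @return list with `results` (data.frame: partition, threshold, failed,
#'   r2, rmse, nrmse, band, nTerms, terms) and `cv` (data.frame:
#'   partition, metric, cv_percent, across the non-failed threshold
#'   cells).
#' @export
runThresholdSweep <- function(images, table,
                              thresholds = c(0, 5, 10, 15, 20),
                              includeUnsegmented = TRUE, clipMasks = NULL,
                              selection = "fixed") {
  stopifnot(length(images) == nrow(table))
  thrList <- as.list(thresholds)
  if (includeUnsegmented) thrList <- c(list(NA_real_), thrList)
  rows <- list()
  for (thr in thrList) {
    tab <- tryCatch({
      masks <- lapply(seq_along(images), function(i) {
        m <- if (is.na(thr)) fullMask(images[[i]]) else
          segmentByGMR(images[[i]], thr)
        if (!is.null(clipMasks)) m <- intersectMasks(clipMasks[[i]], m)
        m
      })
      indexTable(images, masks)
    }, error = function(e) NULL)
    parts <- c(split(seq_len(nrow(table)), table$stage),
               list(All = seq_len(nrow(table))))
    for (pt in names(parts)) {
      idx <- parts[[pt]]
      cell <- if (is.null(tab)) NULL else tryCatch(
        loocvEvaluate(tab[idx, .INDEX_ORDER, drop = FALSE],
                      table$lnc_percent[idx], selection = selection),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(cell)) {
        data.frame(partition = pt, threshold = thr, failed = TRUE,
                   r2 = NA_real_, rmse = NA_real_, nrmse = NA_real_,
                   band = NA_character_, nTerms = NA_integer_,
                   terms = NA_character_, stringsAsFactors = FALSE)
      } else {
        m <- cell$metrics
        data.frame(partition = pt, threshold = thr, failed = FALSE,
                   r2 = m@r2, rmse = m@rmse, nrmse = m@nrmse,
                   band = m@band, nTerms = length(cell$model@terms),
                   terms = paste(cell$model@terms, collapse = "+"),
                   stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  # CV of each metric across the swept thresholds (baseline excluded)
  swept <- results[!is.na(results$threshold) & !results$failed, ]
  cvRows <- list()
  for (pt in unique(swept$partition)) {
    d <- swept[swept$partition == pt, ]
    for (met in c("r2", "rmse", "nrmse")) {
      v <- d[[met]]
      cvRows[[length(cvRows) + 1L]] <- data.frame(
        partition = pt, metric = met,
        cv_percent = if (length(v) > 1L && mean(v) != 0)
          100 * stats::sd(v) / mean(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(results = results,
       cv = if (length(cvRows)) do.call(rbind, cvRows) else
         data.frame(partition = character(0), metric = character(0),
                    cv_percent = numeric(0)))
}

#' Cross-site model transfer
#'
#' Selects and fits an SMLR model on the training site only, then applies
#' the frozen model to the test site. No test-site information enters
#' selection or fitting. Training metrics are resubstitution metrics on
#' the training site.
#'
#' @param table data.frame with a `site` column, an LNC column, and the
#'   candidate index columns.
#' @param trainSite,testSite site labels present in `table` (disjoint row
#'   sets by construction).
#' @param candidates character vector of index column names.
#' @param lncColumn name of the LNC column.
#' @param pEnter,pRemove stepwise criteria.
#' @return list with `model` ([SMLRModel-class]), `train` and `test`
#'   ([FitMetrics-class]), and the site labels.
#' @export
crossSiteValidate <- function(table, trainSite, testSite,
                              candidates = .INDEX_ORDER,
                              lncColumn = "lnc_percent",
                              pEnter = 0.05, pRemove = 0.10) {
  for (s in c(trainSite, testSite)) {
    if (!any(table$site == s))
      stop("configuration error: site '", s, "' not present in table")
  }
  tr <- table[table$site == trainSite, , drop = FALSE]
  te <- table[table$site == testSite, , drop = FALSE]
  model <- suppressWarnings(
    stepwiseSelect(tr[, candidates, drop = FALSE], tr[[lncColumn]],
                   pEnter, pRemove))
  trainMetrics <- computeFitMetrics(predict(model, tr), tr[[lncColumn]])
  testMetrics <- computeFitMetrics(predict(model, te), te[[lncColumn]])
  list(model = model, train = trainMetrics, test = testMetrics,
       trainSite = trainSite, testSite = testSite)
}
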