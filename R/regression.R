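# Stepwise multiple linear regression (forward entry at 5%, backward
# removal at 10%), leave-one-out cross-validation, and the R2/RMSE/NRMSE
# evaluation metrics with quality banding.

# Rank of the design matrix [1 | X].
.designRank <- function(X) {
  qr(cbind(`(Intercept)` = 1, as.matrix(X)))$rank
}

#' Ordinary least squares with per-term p-values
#'
#' Least-squares fit of `y` on the columns of `X` plus an intercept, with
#' two-sided t-test p-values per coefficient. Refuses rank-deficient
#' designs and undersized samples rather than silently dropping columns.
#'
#' @param X data.frame or matrix of predictor columns.
#' @param y numeric response (LNC, %).
#' @return list with `coefficients` (named, including `(Intercept)`),
#'   `pValues` (named, including the intercept), `residualDf`, `fitted`,
#'   `residuals`, and `sigma`.
#' @examples
#' x <- 1:10
#' fitOLS(data.frame(x = x), 3 + 2 * x)$coefficients
#' @export
fitOLS <- function(X, y) {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y must have the same number of rows")
  p <- ncol(X)
  if (n < p + 2L)
    stop(sprintf("insufficient sample size: n = %d for %d predictor(s)",
                 n, p))
  if (.designRank(X) < p + 1L)
    stop("singular design: predictor columns are linearly dependent")
  fit <- stats::lm(.y ~ ., data = cbind(.y = y, X))
  # numerically exact fits are routine for noiseless synthetic responses;
  # the NaN p-values they produce are handled by the callers
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  list(coefficients = stats::coef(fit),
       pValues = stats::setNames(co[, "Pr(>|t|)"], rownames(co)),
       residualDf = fit$df.residual,
       fitted = as.numeric(stats::fitted(fit)),
       residuals = as.numeric(stats::residuals(fit)),
       sigma = sm$sigma)
}

# p-values of the non-intercept terms of a fit on `terms`; NaN (zero
# residual variance) is mapped to 1 so degenerate terms are never kept.
.termPValues <- function(data, y, terms) {
  if (!length(terms)) return(stats::setNames(numeric(0), character(0)))
  pv <- fitOLS(data[, terms, drop = FALSE], y)$pValues[terms]
  pv[is.na(pv) | is.nan(pv)] <- 1
  pv
}

#' Stepwise multiple linear regression
#'
#' Iterates forward selection and backward elimination: each forward step
#' adds the candidate with the smallest p-value among those significant
#' at `pEnter` (the p-value a term has when added to the current model);
#' each backward step removes retained terms with p >= `pRemove`, largest
#' first, until all survive. Candidates whose addition would make the
#' design rank-deficient are skipped; once the fit is numerically exact
#' (residual sum of squares below machine precision relative to the
#' response variance) forward selection stops. Ties are broken by the
#' fixed index-table column order, making the procedure deterministic.
#'
#' @param data data.frame of candidate predictor columns (typically the
#'   13 color indices in their fixed order).
#' @param y numeric response (LNC, %).
#' @param pEnter forward entry significance level (default 0.05).
#' @param pRemove backward removal significance level (default 0.10);
#'   must be >= `pEnter` to avoid oscillation.
#' @param candidates character vector of column names to consider, in
#'   tie-break order; defaults to all columns of `data`.
#' @return an [SMLRModel-class].
#' @examples
#' tab <- simulateIndexTable(40, seed = 1)
#' m <- stepwiseSelect(tab, 1.5 + 4 * tab$NRI)
#' selectedTerms(m)
#' @export
stepwiseSelect <- function(data, y, pEnter = 0.05, pRemove = 0.10,
                           candidates = colnames(data)) {
  data <- as.data.frame(data)
  if (pEnter > pRemove)
    stop("invalid criteria: pEnter must be <= pRemove (oscillation risk)")
  if (!all(candidates %in% colnames(data)))
    stop("candidates must name columns of data")
  n <- length(y)
  if (n < 10L)
    warning("fewer than 10 observations; stepwise selection is unstable")

  current <- character(0)
  trace <- list()
  step_ <- 0L
  maxIter <- 2L * length(candidates)
  tss <- sum((y - mean(y))^2)
  for (iter in seq_len(max(maxIter, 1L))) {
    changed <- FALSE
    # forward: skip when the current fit is already numerically exact
    rss <- if (length(current))
      sum(fitOLS(data[, current, drop = FALSE], y)$residuals^2)
    else tss
    if (rss > 1e-10 * max(tss, 1)) {
      pool <- setdiff(candidates, current)
      entryP <- rep(NA_real_, length(pool))
      for (j in seq_along(pool)) {
        trial <- c(current, pool[j])
        if (n < length(trial) + 2L) next
        if (.designRank(data[, trial, drop = FALSE]) < length(trial) + 1L)
          next
        entryP[j] <- .termPValues(data, y, trial)[pool[j]]
      }
      if (any(!is.na(entryP)) && min(entryP, na.rm = TRUE) < pEnter) {
        j <- which.min(entryP)   # first minimum: fixed-order tie-break
        current <- c(current, pool[j])
        step_ <- step_ + 1L
        trace[[length(trace) + 1L]] <-
          data.frame(step = step_, action = "add", term = pool[j],
                     p = entryP[j], stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # backward: remove worst term at or above pRemove, repeat to stability
    repeat {
      pv <- .termPValues(data, y, current)
      if (!length(pv) || max(pv) < pRemove) break
      worst <- names(pv)[which.max(pv)]
      current <- setdiff(current, worst)
      step_ <- step_ + 1L
      trace[[length(trace) + 1L]] <-
        data.frame(step = step_, action = "remove", term = worst,
                   p = max(pv), stringsAsFactors = FALSE)
      changed <- TRUE
    }
    if (!changed) break
  }

  traceDf <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               term = character(0), p = numeric(0))
  if (length(current)) {
    fit <- fitOLS(data[, current, drop = FALSE], y)
    coefs <- fit$coefficients
    pv <- .termPValues(data, y, current)
  } else {
    coefs <- c(`(Intercept)` = mean(y))
    pv <- stats::setNames(numeric(0), character(0))
  }
  new("SMLRModel", terms = current, coefficients = coefs, pValues = pv,
      n = as.integer(n), trace = traceDf, candidates = candidates)
}

#' Predict LNC from an SMLRModel
#'
#' @param object an [SMLRModel-class].
#' @param newdata data.frame containing the model's term columns.
#' @param ... unused.
#' @return numeric vector of predicted LNC (%).
#' @export
setMethod("predict", "SMLRModel", function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object@terms, colnames(newdata))
  if (length(miss))
    stop("newdata lacks model term(s): ", paste(miss, collapse = ", "))
  out <- rep(object@coefficients[["(Intercept)"]], nrow(newdata))
  for (tm in object@terms)
    out <- out + object@coefficients[[tm]] * newdata[[tm]]
  out
})

#' Leave-one-out cross-validation of an SMLR model
#'
#' Each sample is predicted by a model trained on all other samples;
#' metrics are computed once on the pooled held-out predictions. In the
#' default `"fixed"` mode the variable set is selected once on the full
#' data and only the coefficients are refit per fold; `"per-fold"`
#' reselects the variables inside every fold. The mode is recorded in the
#' result.
#'
#' @param data data.frame of candidate predictor columns.
#' @param y numeric response (LNC, %).
#' @param selection `"fixed"` or `"per-fold"`.
#' @param pEnter,pRemove stepwise significance criteria.
#' @return list with `metrics` ([FitMetrics-class]), `predictions`
#'   (pooled held-out predictions, in input order), `selection`, and
#'   `model` (the full-data [SMLRModel-class]).
#' @export
loocvEvaluate <- function(data, y, selection = c("fixed", "per-fold"),
                          pEnter = 0.05, pRemove = 0.10) {
  selection <- match.arg(selection)
  data <- as.data.frame(data)
  n <- length(y)
  if (n < 3L) stop("sample-size error: LOOCV requires n >= 3")
  fullModel <- suppressWarnings(
    stepwiseSelect(data, y, pEnter, pRemove))
  preds <- numeric(n)
  for (i in seq_len(n)) {
    di <- data[-i, , drop = FALSE]; yi <- y[-i]
    terms <- if (selection == "fixed") fullModel@terms else
      suppressWarnings(stepwiseSelect(di, yi, pEnter, pRemove))@terms
    if (length(terms)) {
      fit <- tryCatch(fitOLS(di[, terms, drop = FALSE], yi),
                      error = function(e)
                        stop("fold ", i, " failed: ", conditionMessage(e)))
      preds[i] <- fit$coefficients[["(Intercept)"]] +
        sum(fit$coefficients[terms] *
              as.numeric(data[i, terms, drop = FALSE]))
    } else {
      preds[i] <- mean(yi)
    }
  }
  list(metrics = computeFitMetrics(preds, y), predictions = preds,
       selection = selection, model = fullModel)
}

#' Fit metrics: R2, RMSE, NRMSE, and quality band
#'
#' `R2 = 1 - sum((P - O)^2) / sum((O - mean(O))^2)`;
#' `RMSE = sqrt(mean((P - O)^2))` in LNC percentage points;
#' `NRMSE = 100 RMSE / mean(O)` in percent, banded by [classifyNRMSE()].
#'
#' @param predicted numeric predicted LNC (%).
#' @param observed numeric observed LNC (%), same length, mean > 0.
#' @return a [FitMetrics-class].
#' @examples
#' computeFitMetrics(c(1.1, 1.9, 3.2), c(1, 2, 3))
#' @export
computeFitMetrics <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("shape error: predicted and observed differ in length")
  n <- length(observed)
  if (n < 2L) stop("at least two prediction-observation pairs required")
  if (anyNA(predicted) || anyNA(observed))
    stop("predicted and observed must not contain NA")
  obar <- mean(observed)
  if (obar == 0) stop("NRMSE undefined: mean observed value is zero")
  sse <- sum((predicted - observed)^2)
  sst <- sum((observed - obar)^2)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / n)
  nrmse <- 100 / obar * rmse
  new("FitMetrics", r2 = r2, rmse = rmse, nrmse = nrmse,
      band = classifyNRMSE(nrmse), n = as.integer(n), meanObserved = obar)
}

#' Quality band of an NRMSE value
#'
#' Excellent below 10%, good in \[10, 20)%, fair in \[20, 30)%, poor at
#' 30% and above (half-open bands, lower-inclusive from 10 upward).
#'
#' @param nrmse NRMSE in percent, >= 0.
#' @return one of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @examples
#' classifyNRMSE(9.24)   # excellent
#' classifyNRMSE(17.74)  # good
#' @export
classifyNRMSE <- function(nrmse) {
  if (!is.numeric(nrmse) || length(nrmse) != 1L || is.na(nrmse) ||
      nrmse < 0)
    stop("nrmse must be a single non-negative number")
  if (nrmse < 10) "excellent"
  else if (nrmse < 20) "good"
  else if (nrmse < 30) "fair"
  else "poor"
}
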