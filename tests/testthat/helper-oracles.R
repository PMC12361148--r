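# Independent brute-force oracles used to check the implementation paths.

# Exhaustive Otsu: per-threshold loop computing class weights and means
# directly from the histogram; smallest maximizing t.
oracleOtsu <- function(histogram) {
  lev <- 0:255
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:255) {
    in0 <- lev <= t
    w0 <- sum(histogram[in0]); w1 <- sum(histogram[!in0])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lev[in0] * histogram[in0]) / w0
    mu1 <- sum(lev[!in0] * histogram[!in0]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  bestT
}

# Scalar even-odd ray cast for a single point (r, c), 0-based coordinates.
oraclePointInPolygon <- function(r, c, poly) {
  k <- nrow(poly); inside <- FALSE
  j <- k
  for (i in seq_len(k)) {
    ri <- poly[i, 1]; ci <- poly[i, 2]
    rj <- poly[j, 1]; cj <- poly[j, 2]
    if ((ri > r) != (rj > r)) {
      xint <- ci + (r - ri) / (rj - ri) * (cj - ci)
      if (c < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Normal-equations OLS: beta = (X'X)^-1 X'y with explicit solve().
oracleOLS <- function(X, y) {
  Xm <- cbind(1, as.matrix(X))
  as.numeric(solve(t(Xm) %*% Xm, t(Xm) %*% y))
}

# Naive leave-one-out loop for a fixed term set: refit with lm per fold.
oracleLOOCV <- function(data, terms, y) {
  n <- length(y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    d <- cbind(.y = y[-i], data[-i, terms, drop = FALSE])
    fit <- lm(.y ~ ., data = d)
    preds[i] <- predict(fit, newdata = data[i, terms, drop = FALSE])
  }
  preds
}

# Stable subsets of the stepwise criteria, sizes <= maxSize: full rank,
# every retained term p < pRemove, no outside candidate enters at p < pEnter.
# Degenerate (NaN) p-values count as 1, matching the selection procedure's
# treatment of exact fits.
oracleStableSubsets <- function(data, y, candidates, maxSize = 4,
                                pEnter = 0.05, pRemove = 0.10) {
  termP <- function(terms) {
    d <- cbind(.y = y, data[, terms, drop = FALSE])
    sm <- suppressWarnings(summary(lm(.y ~ ., data = d)))
    pv <- sm$coefficients[, "Pr(>|t|)"]
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    pv[is.na(pv) | is.nan(pv)] <- 1
    pv
  }
  fullRank <- function(terms) {
    qr(cbind(1, as.matrix(data[, terms, drop = FALSE])))$rank ==
      length(terms) + 1
  }
  stable <- list()
  for (size in seq_len(maxSize)) {
    for (sel in utils::combn(candidates, size, simplify = FALSE)) {
      if (!fullRank(sel)) next
      if (any(termP(sel) >= pRemove)) next
      entryOK <- TRUE
      for (cand in setdiff(candidates, sel)) {
        trial <- c(sel, cand)
        if (!fullRank(trial)) next
        if (termP(trial)[cand] < pEnter) { entryOK <- FALSE; break }
      }
      if (entryOK) stable[[length(stable) + 1L]] <- sort(sel)
    }
  }
  stable
}

iou <- function(a, b) {
  ma <- maskMatrix(a); mb <- maskMatrix(b)
  sum(ma & mb) / sum(ma | mb)
}
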