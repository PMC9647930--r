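#' Pairwise t-test feature selection
#'
#' For every feature, a Welch two-sample t-test between each pair of genetic
#' classes; a feature is included when its smallest pairwise p-value falls
#' below the threshold (default 0.02). Features constant within both groups
#' of a pair score p = 1 for that pair when the group means agree (and 0 when
#' they differ, a perfectly separating feature).
#'
#' @param features numeric matrix, subjects x features
#' @param labels class labels, one per subject
#' @param threshold inclusion p-value threshold
#' @return list with `pvalues` (features x class pairs), `minP`, and the
#'   logical `included` mask
#' @export
selectFeatures <- function(features, labels, threshold = 0.02) {
  classes <- sort(unique(labels))
  stopifnot(length(classes) >= 2, all(table(labels) >= 2))
  pairs <- utils::combn(classes, 2)
  pv <- matrix(NA_real_, ncol(features), ncol(pairs),
               dimnames = list(colnames(features),
                               apply(pairs, 2, paste, collapse = "_vs_")))
  for (j in seq_len(ncol(pairs))) {
    a <- features[labels == pairs[1, j], , drop = FALSE]
    b <- features[labels == pairs[2, j], , drop = FALSE]
    pv[, j] <- vapply(seq_len(ncol(features)), function(k) {
      x <- a[, k]; y <- b[, k]
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    }, numeric(1))
  }
  minP <- apply(pv, 1, min)
  list(pvalues = pv, minP = minP, included = minP < threshold,
       threshold = threshold)
}

#' z-score standardization with stored statistics
#'
#' Fits per-feature mean and standard deviation on the training matrix and
#' applies the transform to any matrix with the same columns. Features with
#' zero training-set variance are dropped with a warning.
#'
#' @param train training feature matrix (subjects x features)
#' @return object of class `zscaler` with `$transform(newdata)`
#' @export
fitZscore <- function(train) {
  mu <- colMeans(train)
  sigma <- apply(train, 2, stats::sd)
  drop <- sigma == 0
  if (any(drop))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(train)[drop], collapse = ", "))
  sc <- structure(list(mean = mu[!drop], sd = sigma[!drop],
                       keep = which(!drop)), class = "zscaler")
  sc
}

#' @rdname fitZscore
#' @param scaler a `zscaler`
#' @param newdata matrix to transform (same columns as the training matrix)
#' @export
applyZscore <- function(scaler, newdata) {
  stopifnot(inherits(scaler, "zscaler"))
  x <- newdata[, scaler$keep, drop = FALSE]
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}
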