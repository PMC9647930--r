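#' Per-class and overall classification metrics
#'
#' Per class: accuracy (the true positive rate — the fraction of that class's
#' test subjects classified correctly), false positive rate (false positives
#' over non-class subjects), and F1. Overall accuracy is the fraction of all
#' test subjects correct.
#'
#' @param truth,pred factors (or characters) of true and predicted classes
#' @param classes class order for the output
#' @return list with `overall` and a data.frame `perClass`
#' @export
classMetrics <- function(truth, pred, classes = diseaseClasses()) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
    data.frame(class = cl, tpr = tpr, fpr = fpr, f1 = f1)
  }))
  list(overall = mean(truth == pred), perClass = perClass)
}

#' Class-balanced train/test split
#'
#' Draws `trainPerClass` subjects per class for training; the remainder is
#' the test set.
#'
#' @param labels class labels
#' @param trainPerClass training subjects per class
#' @param seed RNG seed
#' @return list with integer index vectors `train`, `test`
#' @export
splitCohort <- function(labels, trainPerClass = 50, seed = 1) {
  set.seed(seed)
  train <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) <= trainPerClass)
      stop("class ", cl, " has ", length(idx),
           " subjects; need more than trainPerClass = ", trainPerClass)
    sample(idx, trainPerClass)
  }))
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Train and evaluate one classifier on one split
#'
#' Standardizes the (already selected) features with training-set statistics,
#' fits the classifier, predicts the test subjects, and reports the metrics
#' of [classMetrics()].
#'
#' @param method one of [classifierMethods()]
#' @param features numeric matrix of selected features (subjects x features)
#' @param labels class labels
#' @param split list from [splitCohort()]
#' @param seed seed for the fitter
#' @param ... passed to [fitClassifier()]
#' @return list with `overall`, `perClass`, `pred`, `truth`
#' @export
trainEval <- function(method, features, labels, split, seed = 1, ...) {
  scaler <- fitZscore(features[split$train, , drop = FALSE])
  xtr <- applyZscore(scaler, features[split$train, , drop = FALSE])
  xte <- applyZscore(scaler, features[split$test, , drop = FALSE])
  fit <- fitClassifier(method, xtr, labels[split$train], seed = seed, ...)
  pred <- predict(fit, xte)
  met <- classMetrics(labels[split$test], pred)
  c(met, list(pred = as.character(pred), truth = labels[split$test],
              method = method))
}

#' Repeated (serialized) evaluation of one classifier
#'
#' Repeats [trainEval()] over independent split and initialization seeds,
#' keeps the runs whose overall accuracy meets `floor`, and aggregates each
#' metric as mean, standard deviation (sample, n - 1) and max. Per-run ROC
#' points (per-class FPR, TPR) are collected for curve fitting.
#'
#' @param method one of [classifierMethods()]
#' @param features selected feature matrix
#' @param labels class labels
#' @param nRuns number of serializations
#' @param trainPerClass training subjects per class
#' @param floor overall-accuracy retention floor in `[0, 1]`
#' @param seed master seed; run seeds derive from it
#' @param ... passed to [fitClassifier()]
#' @return list of class `serializedRuns` with `aggregate` (data.frame),
#'   `rocPoints`, `runs`, and `meanClassAccuracy` (named per-class TPR means,
#'   used by the ensemble rule)
#' @export
serializeRuns <- function(method, features, labels, nRuns = 30,
                          trainPerClass = 50, floor = 0, seed = 1, ...) {
  stopifnot(nRuns >= 1)
  runSeeds <- deriveSeeds(seed, 2 * nRuns)
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    split <- splitCohort(labels, trainPerClass, seed = runSeeds[2 * r - 1])
    runs[[r]] <- trainEval(method, features, labels, split,
                           seed = runSeeds[2 * r], ...)
  }
  keep <- vapply(runs, `[[`, numeric(1), "overall") >= floor
  if (!any(keep))
    stop("no run met the performance floor ", floor,
         "; lower the floor or inspect the runs")
  runs <- runs[keep]
  classes <- diseaseClasses()
  agg <- function(v) c(mean = mean(v),
                       sd = if (length(v) > 1) stats::sd(v) else 0,
                       max = max(v))
  overall <- vapply(runs, `[[`, numeric(1), "overall")
  rows <- list(data.frame(class = "overall", metric = "accuracy",
                          t(agg(overall))))
  rocPoints <- list()
  for (cl in classes) {
    tpr <- vapply(runs, function(r) r$perClass$tpr[r$perClass$class == cl],
                  numeric(1))
    fpr <- vapply(runs, function(r) r$perClass$fpr[r$perClass$class == cl],
                  numeric(1))
    f1 <- vapply(runs, function(r) r$perClass$f1[r$perClass$class == cl],
                 numeric(1))
    rows <- c(rows, list(
      data.frame(class = cl, metric = "accuracy", t(agg(tpr))),
      data.frame(class = cl, metric = "tpr", t(agg(tpr))),
      data.frame(class = cl, metric = "fpr", t(agg(fpr))),
      data.frame(class = cl, metric = "f1", t(agg(f1)))))
    rocPoints[[cl]] <- data.frame(fpr = fpr, tpr = tpr)
  }
  meanClassAcc <- vapply(classes, function(cl) {
    mean(vapply(runs, function(r) r$perClass$tpr[r$perClass$class == cl],
                numeric(1)))
  }, numeric(1))
  structure(list(method = method, aggregate = do.call(rbind, rows),
                 rocPoints = rocPoints, runs = runs,
                 meanClassAccuracy = meanClassAcc,
                 nRetained = sum(keep)),
            class = "serializedRuns")
}

#' Table of aggregated metrics across classifiers
#'
#' Binds the `aggregate` tables of several [serializeRuns()] results into one
#' data.frame mirroring the mean (sd) - max reporting layout.
#'
#' @param runsList named list of `serializedRuns`
#' @return data.frame with columns `method`, `class`, `metric`, `mean`,
#'   `sd`, `max`
#' @export
metricsTable <- function(runsList) {
  do.call(rbind, lapply(names(runsList), function(nm) {
    data.frame(method = nm, runsList[[nm]]$aggregate, row.names = NULL)
  }))
}
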