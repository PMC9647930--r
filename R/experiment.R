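#' Run the classification experiment on a cohort
#'
#' Feature selection by pairwise t-tests, then repeated train/evaluate runs
#' of the requested classifiers, and the product-of-error-probability
#' ensemble evaluated on a held-out split shared by all models.
#'
#' @param cohort an [EpCohort-class]
#' @param methods classifiers to run (default all five)
#' @param nRuns serializations per classifier
#' @param trainPerClass training subjects per class; defaults to 50, or to
#'   about two thirds of the smallest class when the cohort is smaller than
#'   the full-scale design
#' @param alpha feature-selection p-value threshold
#' @param floor serialization retention floor (overall accuracy)
#' @param seed master seed
#' @param ... passed to [serializeRuns()]
#' @return list with `selection`, `runs` (named list of
#'   [serializeRuns()] results), `metrics` (the bound table), `ensemble`,
#'   and `roc` (per method, per class)
#' @export
runExperiment <- function(cohort, methods = classifierMethods(), nRuns = 30,
                          trainPerClass = NULL, alpha = 0.02, floor = 0,
                          seed = 1, ...) {
  stopifnot(is(cohort, "EpCohort"))
  features <- featureMatrix(cohort)
  labels <- classLabels(cohort)
  minClass <- min(table(labels))
  if (is.null(trainPerClass))
    trainPerClass <- if (minClass > 50) 50 else
      max(2, as.integer(minClass * 2 / 3))
  sel <- selectFeatures(features, labels, threshold = alpha)
  if (!any(sel$included)) stop("no feature passed selection at alpha = ", alpha)
  selected <- features[, sel$included, drop = FALSE]

  seeds <- deriveSeeds(seed, length(methods) + 1)
  runs <- list()
  for (i in seq_along(methods)) {
    runs[[methods[i]]] <- serializeRuns(
      methods[i], selected, labels, nRuns = nRuns,
      trainPerClass = trainPerClass, floor = floor, seed = seeds[i], ...)
  }

  # ensemble on one shared split: each model refit on the same training set
  split <- splitCohort(labels, trainPerClass,
                       seed = seeds[length(methods) + 1])
  predMat <- vapply(methods, function(m) {
    as.character(trainEval(m, selected, labels, split,
                           seed = seeds[length(methods) + 1])$pred)
  }, character(length(split$test)))
  classAcc <- lapply(runs[methods], `[[`, "meanClassAccuracy")
  ens <- ensembleEval(predMat, labels[split$test], classAcc)

  roc <- lapply(runs, function(r) lapply(r$rocPoints, rocAuc))
  list(selection = sel, runs = runs, metrics = metricsTable(runs),
       ensemble = ens, roc = roc,
       trainPerClass = trainPerClass, seed = seed)
}

#' Aggregate per-class mean firing rates of a cohort specification
#'
#' Simulates `nSeeds` subjects per class at the given scale and returns the
#' mean network firing rate per class; used for excitability comparisons.
#'
#' @param nSeeds seeds (subjects) per class
#' @param durationMs duration (ms)
#' @param nExc,nInh,gridShape geometry
#' @param masterSeed master seed
#' @return named numeric vector of mean rates (Hz) per class
#' @export
classFiringRates <- function(nSeeds = 10, durationMs = 500, nExc = 33,
                             nInh = 17, gridShape = c(10, 5),
                             masterSeed = 1) {
  seeds <- deriveSeeds(masterSeed, nSeeds)
  vapply(diseaseClasses(), function(cl) {
    mean(vapply(seeds, function(s) {
      res <- simulateSubject(s, cl, durationMs = durationMs, nExc = nExc,
                             nInh = nInh, gridShape = gridShape,
                             keepTraces = FALSE)
      mean(firingRates(res))
    }, numeric(1)))
  }, numeric(1))
}
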