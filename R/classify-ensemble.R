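#' Product-of-error-probability ensemble rule
#'
#' Combines predictions from several models using their per-class accuracies:
#' for each class, the probabilities of being wrong (1 - accuracy on that
#' class) of every model that predicted the class are multiplied, giving the
#' probability that all those predictions are wrong; a class predicted by no
#' model scores 1. The class with the smallest score wins; ties break by the
#' fixed class order (healthy, gof, lof).
#'
#' @param predictions character vector, one predicted class per model
#' @param classAccuracies list (one element per model) of named per-class
#'   accuracy vectors, or a matrix models x classes
#' @param classes class order for tie-breaking
#' @return the ensemble prediction (character scalar)
#' @examples
#' ensemblePredict(c("healthy", "healthy"),
#'                 list(c(healthy = 0.83), c(healthy = 0.72)))
#' @export
ensemblePredict <- function(predictions, classAccuracies,
                            classes = diseaseClasses()) {
  stopifnot(length(predictions) >= 1,
            length(predictions) == length(classAccuracies))
  if (is.matrix(classAccuracies))
    classAccuracies <- asplit(classAccuracies, 1)
  score <- vapply(classes, function(cl) {
    who <- which(predictions == cl)
    if (length(who) == 0) return(1)
    prod(vapply(who, function(m) {
      acc <- classAccuracies[[m]][[cl]]
      stopifnot(acc >= 0, acc <= 1)
      1 - acc
    }, numeric(1)))
  }, numeric(1))
  classes[which.min(score)]
}

#' Evaluate the ensemble over a test set
#'
#' Applies [ensemblePredict()] subject-wise to the prediction columns of
#' several models and returns the metrics of [classMetrics()].
#'
#' @param predMatrix character matrix, subjects x models, of per-model
#'   predictions
#' @param truth true classes
#' @param classAccuracies list of named per-class accuracy vectors, one per
#'   model (e.g. `meanClassAccuracy` from [serializeRuns()])
#' @return list with `overall`, `perClass`, `pred`
#' @export
ensembleEval <- function(predMatrix, truth, classAccuracies) {
  pred <- apply(predMatrix, 1, ensemblePredict,
                classAccuracies = classAccuracies)
  c(classMetrics(truth, pred), list(pred = pred))
}
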