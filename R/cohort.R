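#' Cohort specification
#'
#' Study conditions for a simulated cohort. The defaults are the full-scale
#' experiment: 76 subjects per class, 1 s of activity at a 0.1 ms step on the
#' 20 x 10 lattice with 132 excitatory and 68 inhibitory neurons. Reduced
#' specifications (fewer subjects, neurons or milliseconds) are used for
#' fixtures and fast runs.
#'
#' @param subjectsPerClass subjects per genetic class
#' @param durationMs simulated duration per subject (ms)
#' @param masterSeed master seed; all subject seeds derive from it
#' @param nExc,nInh,gridShape,pitch geometry configuration
#' @param mseScales,medDelay,teThreshold,teBins feature-extraction settings
#' @return list of class `CohortSpec`
#' @export
cohortSpec <- function(subjectsPerClass = 76, durationMs = 1000,
                       masterSeed = 1, nExc = 132, nInh = 68,
                       gridShape = c(20, 10), pitch = 10,
                       mseScales = 1:20, medDelay = 500,
                       teThreshold = 5e-5, teBins = 3) {
  stopifnot(subjectsPerClass >= 2)
  structure(list(subjectsPerClass = subjectsPerClass,
                 durationMs = durationMs, masterSeed = masterSeed,
                 nExc = nExc, nInh = nInh, gridShape = gridShape,
                 pitch = pitch, mseScales = mseScales, medDelay = medDelay,
                 teThreshold = teThreshold, teBins = teBins),
            class = "CohortSpec")
}

#' Reduced-scale cohort specification
#'
#' Convenience wrapper: 10 subjects per class, 50 neurons (10 x 5 lattice,
#' 33 excitatory / 17 inhibitory, preserving the full-scale E:I ratio) and
#' 500 ms of activity.
#'
#' @param subjectsPerClass subjects per class
#' @param durationMs duration (ms)
#' @param masterSeed master seed
#' @param ... further arguments to [cohortSpec()]
#' @return a `CohortSpec`
#' @export
reducedCohortSpec <- function(subjectsPerClass = 10, durationMs = 500,
                              masterSeed = 1, ...) {
  cohortSpec(subjectsPerClass = subjectsPerClass, durationMs = durationMs,
             masterSeed = masterSeed, nExc = 33, nInh = 17,
             gridShape = c(10, 5), ...)
}

#' Construct an EpCohort from a feature table
#'
#' @param features numeric matrix, subjects x features
#' @param labels character vector of genetic classes, one per subject
#' @param seeds integer vector of subject seeds
#' @param subjectIds optional subject identifiers
#' @return an [EpCohort-class]
#' @export
EpCohort <- function(features, labels, seeds = seq_len(nrow(features)),
                     subjectIds = NULL) {
  if (is.null(subjectIds))
    subjectIds <- sprintf("subject_%03d", seq_len(nrow(features)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    colData = S4Vectors::DataFrame(subject_id = subjectIds,
                                   label = labels,
                                   seed = as.integer(seeds),
                                   row.names = subjectIds))
  new("EpCohort", se)
}

#' Feature matrix of a cohort (subjects x features)
#' @param cohort an [EpCohort-class]
#' @return numeric matrix
#' @export
featureMatrix <- function(cohort) {
  t(SummarizedExperiment::assay(cohort, "features"))
}

#' Genetic class labels of a cohort
#' @param cohort an [EpCohort-class]
#' @return character vector
#' @export
classLabels <- function(cohort) as.character(cohort$label)

setMethod("show", "EpCohort", function(object) {
  tab <- table(classLabels(object))
  cat(sprintf("EpCohort: %d subjects x %d features (%s)\n",
              ncol(object), nrow(object),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
})

#' Run a full simulated cohort
#'
#' Simulates every subject (classes interleaved, each with a seed derived
#' deterministically from the master seed), extracts the 92-feature panel,
#' and returns the assembled cohort. Subjects whose simulation or feature
#' extraction fails are skipped with a warning; more than 5% failures aborts.
#' Traces are discarded after extraction unless `keepTraces` is set.
#'
#' @param spec a [cohortSpec()]
#' @param keepTraces logical; also return the per-subject simulation results
#' @param verbose logical; log one line per subject
#' @return an [EpCohort-class]; when `keepTraces` is set, the simulation
#'   results are attached as the `"results"` attribute
#' @export
runCohort <- function(spec = cohortSpec(), keepTraces = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  classes <- rep(diseaseClasses(), each = spec$subjectsPerClass)
  nSub <- length(classes)
  seeds <- deriveSeeds(spec$masterSeed, nSub)
  feats <- matrix(NA_real_, nSub, 92,
                  dimnames = list(NULL, featureNames()))
  results <- if (keepTraces) vector("list", nSub) else NULL
  failed <- logical(nSub)
  for (i in seq_len(nSub)) {
    t0 <- proc.time()[3]
    ok <- tryCatch({
      res <- simulateSubject(seeds[i], classes[i],
                             durationMs = spec$durationMs,
                             nExc = spec$nExc, nInh = spec$nInh,
                             gridShape = spec$gridShape, pitch = spec$pitch)
      feats[i, ] <- extractFeatures(res, mseScales = spec$mseScales,
                                    medDelay = spec$medDelay,
                                    teThreshold = spec$teThreshold,
                                    teBins = spec$teBins)
      if (keepTraces) results[[i]] <- res
      TRUE
    }, error = function(e) {
      warning("subject ", i, " (", classes[i], ", seed ", seeds[i],
              ") failed: ", conditionMessage(e))
      FALSE
    })
    failed[i] <- !ok
    if (verbose)
      message(sprintf("subject %d/%d class=%s seed=%d %.1fs", i, nSub,
                      classes[i], seeds[i], proc.time()[3] - t0))
  }
  if (mean(failed) > 0.05)
    stop("more than 5% of subjects failed (", sum(failed), "/", nSub, ")")
  keep <- !failed
  cohort <- EpCohort(feats[keep, , drop = FALSE], classes[keep],
                     seeds[keep])
  if (keepTraces) attr(cohort, "results") <- results[keep]
  cohort
}

#' Write a cohort feature table to CSV
#'
#' One row per subject: `subject_id`, `label`, `seed`, then the 92 named
#' feature columns.
#'
#' @param cohort an [EpCohort-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFeatureCsv <- function(cohort, path) {
  df <- data.frame(subject_id = cohort$subject_id,
                   label = classLabels(cohort), seed = cohort$seed,
                   featureMatrix(cohort), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort feature table from CSV
#'
#' @param path CSV written by [writeFeatureCsv()]
#' @return an [EpCohort-class]
#' @export
readFeatureCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "label", "seed")
  stopifnot(all(meta %in% names(df)))
  EpCohort(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]),
           df$label, df$seed, subjectIds = df$subject_id)
}

#' Export spike trains as a two-column table
#'
#' @param result a [SimulationResult-class]
#' @param path optional CSV output path
#' @return data.frame with columns `neuron_id`, `time_ms`
#' @export
spikesToTable <- function(result, path = NULL) {
  spk <- spikeTimes(result)
  df <- data.frame(
    neuron_id = rep(seq_along(spk), lengths(spk)),
    time_ms = unlist(spk, use.names = FALSE))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
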