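#' Default configuration
#'
#' Flat key-value list of every model constant: membrane and synapse
#' parameters, geometry, disease model, feature-extraction settings, and
#' classifier hyperparameters. All values can be overridden through a YAML
#' file; unknown keys are rejected.
#'
#' @return named list
#' @export
defaultConfig <- function() {
  list(
    # membrane
    Cm = 1, gl = 0.05, El = -65, ENa = 50, EK = -90,
    gNa0 = 100, gK0 = 30, tauNa = 6, tauK = 6, VT = -63, vSpike = -63,
    dt = 0.1,
    # synapses / connectivity
    omegaF = 3.33, omegaD = 2, U0 = 0.6, wE = 70, wI = 20,
    RE = 15.1, RI = 9, ampE = 0.83, ampI = 0.41, sdE = 15.5, sdI = 12,
    areaNorm = 5000,
    # geometry
    nExc = 132, nInh = 68, gridCols = 20, gridRows = 10, pitch = 10,
    areaMin = 10000, areaMax = 30000,
    # disease model
    mutantFraction = 0.2, gofFold = 80,
    # cohort
    subjectsPerClass = 76, durationMs = 1000,
    # features
    mseScaleMax = 20, mseM = 2, mseRFactor = 0.2,
    medDelay = 500, medMaxDim = 10, medRtol = 10, medAtol = 2,
    medMinFrac = 0.01, iisIsolationMs = 50,
    teThreshold = 5e-5, teBins = 3,
    # classification
    selectionAlpha = 0.02, trainPerClass = 50, nRuns = 30,
    svmCost = 0.2, nnHidden = 3, nnEpochs = 800, nnBatch = 80)
}

#' Read a configuration file
#'
#' YAML flat key-value file; values present override the defaults of
#' [defaultConfig()].
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return named list
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Write a configuration file
#'
#' @param cfg named list (e.g. [defaultConfig()])
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run manifest for a cohort or experiment
#'
#' Snapshot of configuration, seeds and package version; written as JSON next
#' to experiment outputs so a run can be reproduced exactly.
#'
#' @param cfg configuration list
#' @param seeds integer vector of seeds used
#' @param extra optional named list of additional entries
#' @param path optional JSON output path
#' @return the manifest list
#' @export
runManifest <- function(cfg, seeds, extra = list(), path = NULL) {
  man <- c(list(package = "epinetml",
                version = as.character(utils::packageVersion("epinetml")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seeds = seeds, config = cfg), extra)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  man
}
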