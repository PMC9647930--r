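#' Names of the 92-feature electrophysiology panel
#'
#' Fixed order: firing-rate block (4), embedding-dimension block (6),
#' multiscale-entropy block (18), waveform-shape block (36), transfer-entropy
#' connectivity block (28).
#'
#' @return character vector of length 92
#' @export
featureNames <- function() {
  summ <- c("_mean", "_max", "_sd", "_grad_mean", "_grad_max", "_grad_sd")
  te7 <- c("_mean", "_max", "_total", "_sd",
           "_grad_mean", "_grad_max", "_grad_sd")
  c("freq_max", "freq_grad_max", "freq_mean", "freq_grad_mean",
    paste0("med", summ),
    paste0(rep(c("mse_integral", "mse_mean", "mse_sd"), each = 6), summ),
    paste0(rep(c("pds_rate", "pds_dur", "iis_rate", "iis_dur",
                 "line_length", "auc"), each = 6), summ),
    paste0(rep(c("te_alpha", "te_beta", "te_gamma", "te_all"), each = 7),
           te7))
}

#' Sizes of the feature blocks
#' @return named integer vector summing to 92
#' @export
featureBlockSizes <- function() {
  c(frequency = 4L, med = 6L, mse = 18L, waveform = 36L, te = 28L)
}

#' Extract the 92-feature electrophysiology panel for one subject
#'
#' Concatenates the five feature blocks in fixed order. The embedding delay
#' defaults to 50 ms worth of samples; when the trace is too short for the
#' full 10-dimension search range, the dimension cap is lowered to the largest
#' value the trace supports (never below 2).
#'
#' @param result a [SimulationResult-class] with traces kept
#' @param mseScales scales for the multiscale-entropy block
#' @param medDelay embedding delay in samples
#' @param medMaxDim embedding dimension cap
#' @param teThreshold functional-connection threshold (nats)
#' @param teBins TE discretization levels
#' @return named numeric vector of length 92
#' @export
extractFeatures <- function(result, mseScales = 1:20, medDelay = 500,
                            medMaxDim = 10, teThreshold = 5e-5, teBins = 3) {
  stopifnot(is(result, "SimulationResult"))
  traces <- voltageTraces(result)
  if (nrow(traces) == 0)
    stop("feature extraction needs voltage traces (keepTraces = TRUE)")
  nt <- ncol(traces)
  effMaxDim <- max(2L, min(medMaxDim, floor((nt - 100) / medDelay)))
  out <- c(
    frequencyFeatures(result),
    medFeatures(result, delay = medDelay, maxDim = effMaxDim),
    mseFeatures(result, scales = mseScales),
    waveformFeatures(result),
    teConnectivityFeatures(result, threshold = teThreshold,
                           nBins = teBins)$features)
  names(out) <- featureNames()
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature(s): ", paste(names(out)[bad], collapse = ", "))
  out
}
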