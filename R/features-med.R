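#' Minimum embedding dimension by false nearest neighbors
#'
#' Kennel's false-nearest-neighbor criterion on delay embeddings of a voltage
#' trace: the minimum embedding dimension (MED) is the smallest dimension at
#' which the fraction of false nearest neighbors falls below `minFrac`. A
#' neighbor is false if adding the next delay coordinate inflates its distance
#' by more than `rtol`-fold, or beyond `atol` standard deviations of the
#' signal. Defaults: 10-fold distance threshold, 2 SD threshold, delay 500
#' steps (50 ms at a 0.1 ms step). A constant (zero-variance) trace has MED 1
#' by convention; if the criterion is never met the cap `maxDim` is returned.
#'
#' For long traces at most `maxVectors` embedding vectors (a uniform stride
#' subsample) are used for the neighbor search, which bounds the quadratic
#' search cost without biasing the fraction.
#'
#' @param trace numeric voltage series
#' @param delay embedding delay in samples
#' @param maxDim dimension cap
#' @param rtol fold-distance false-neighbor threshold
#' @param atol absolute threshold in signal standard deviations
#' @param minFrac acceptance fraction of false neighbors
#' @param maxVectors cap on embedding vectors used in the neighbor search
#' @return integer embedding dimension in `1:maxDim`
#' @export
minEmbeddingDim <- function(trace, delay = 500, maxDim = 10, rtol = 10,
                            atol = 2, minFrac = 0.01, maxVectors = 500) {
  if (stats::sd(trace) == 0) return(1L)
  if (length(trace) <= maxDim * delay)
    stop("trace too short (", length(trace), ") for maxDim * delay = ",
         maxDim * delay)
  frac <- cpp_fnn_fractions(trace, delay, maxDim, rtol, atol, maxVectors)
  ok <- which(!is.na(frac) & frac < minFrac)
  if (length(ok)) as.integer(ok[1]) else as.integer(maxDim)
}

#' Embedding-dimension features
#'
#' MED per neuron, summarized by [fieldSummary()] (mean, max, SD of the MED
#' field and of its spatial gradient).
#'
#' @param result a [SimulationResult-class]
#' @param ... passed to [minEmbeddingDim()]
#' @return named numeric vector of length 6
#' @export
medFeatures <- function(result, ...) {
  traces <- voltageTraces(result)
  med <- apply(traces, 1, minEmbeddingDim, ...)
  fieldSummary(as.numeric(med), geometry(result), "med")
}
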