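#' Discretize a series into equal-width bins
#'
#' Equal-width binning over the series' own range; a constant series maps to
#' bin 0.
#'
#' @param x numeric series
#' @param nBins number of bins
#' @return integer vector of symbols in `0:(nBins - 1)`
#' @export
binSeries <- function(x, nBins = 3) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(integer(length(x)))
  b <- findInterval(x, seq(rng[1], rng[2], length.out = nBins + 1),
                    rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b - 1L)
}

#' Transfer entropy between two series
#'
#' Plug-in estimate of the transfer entropy TE(source -> target) in nats with
#' history length 1 and one-step horizon,
#' `sum p(y+, y, x) log[p(y+ | y, x) / p(y+ | y)]`, over states obtained by
#' equal-width binning of each series into `nBins` levels. Non-negative by
#' construction (clipped at 0 against floating error).
#'
#' @param source,target equal-length numeric series
#' @param nBins number of discretization levels per series
#' @return transfer entropy in nats
#' @export
transferEntropy <- function(source, target, nBins = 3) {
  if (length(source) != length(target)) stop("series lengths differ")
  if (length(source) < 3) stop("series too short for transfer entropy")
  cpp_transfer_entropy(binSeries(source, nBins), binSeries(target, nBins),
                       as.integer(nBins))
}

#' Frequency band of a firing rate
#'
#' Alpha 0-12.5 Hz, Beta 12.5-30 Hz, Gamma 30-80 Hz (left-closed intervals);
#' rates above 80 Hz fall in no named band but still count toward "all".
#'
#' @param rate firing rate (Hz)
#' @return factor with levels `alpha`, `beta`, `gamma`, `none`
#' @export
frequencyBand <- function(rate) {
  cut(rate, breaks = c(-Inf, 12.5, 30, 80, Inf), right = FALSE,
      labels = c("alpha", "beta", "gamma", "none"))
}

#' Transfer-entropy functional-connectivity features
#'
#' Computes TE for every ordered neuron pair from the voltage traces; a
#' directed functional connection exists where TE exceeds `threshold`
#' (default 5e-5). Each edge is assigned the frequency band of its origin
#' (source) neuron's firing rate; per band (alpha, beta, gamma, all) the
#' per-neuron outgoing-connection counts are summarized by mean, max, total,
#' SD, and the mean, max and SD of their spatial gradient, for 4 x 7 = 28
#' features.
#'
#' @param result a [SimulationResult-class]
#' @param threshold TE connection threshold (nats)
#' @param nBins discretization levels for the TE estimator
#' @return list with `te` (the TE matrix), `adjacency` (logical matrix), and
#'   `features` (named numeric vector of length 28)
#' @export
teConnectivityFeatures <- function(result, threshold = 5e-5, nBins = 3) {
  traces <- voltageTraces(result)
  n <- nrow(traces)
  bins <- t(apply(traces, 1, binSeries, nBins = nBins))
  te <- cpp_te_matrix(bins, as.integer(nBins))
  adj <- te > threshold
  diag(adj) <- FALSE
  rates <- firingRates(result)
  band <- frequencyBand(rates)
  geom <- geometry(result)
  outDeg <- rowSums(adj)

  bandCounts <- function(which) {
    cnt <- outDeg
    cnt[!which] <- 0
    cnt
  }
  summarize <- function(cnt, prefix) {
    grad <- spatialGradient(cnt, geom)
    out <- c(mean(cnt), max(cnt), sum(cnt), stats::sd(cnt),
             mean(grad), max(grad), stats::sd(grad))
    names(out) <- paste0(prefix, c("_mean", "_max", "_total", "_sd",
                                   "_grad_mean", "_grad_max", "_grad_sd"))
    out
  }
  feats <- c(
    summarize(bandCounts(band == "alpha"), "te_alpha"),
    summarize(bandCounts(band == "beta"), "te_beta"),
    summarize(bandCounts(band == "gamma"), "te_gamma"),
    summarize(outDeg, "te_all"))
  list(te = te, adjacency = adj, features = feats)
}
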