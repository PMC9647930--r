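#' Sample entropy of a series
#'
#' SampEn(m, r): the negative log conditional probability that template pairs
#' matching for `m` points (Chebyshev distance within `r`, self-matches
#' excluded) also match for `m + 1`. A zero-variance series has entropy 0 (all
#' templates match). When no length-`m + 1` match exists the estimate is
#' undefined; the Richman-Moorman upper bound
#' `-log(2 / ((N - m - 1) * (N - m)))` is returned instead so downstream
#' summaries stay finite. When even no length-`m` match exists, 0 is returned.
#'
#' @param x numeric series
#' @param m template length
#' @param r tolerance (same units as `x`)
#' @return sample entropy in nats
#' @export
sampleEntropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2) stop("series too short for SampEn with m = ", m)
  if (stats::sd(x) == 0) return(0)
  cnt <- cpp_sampen_counts(x, m, r)
  if (cnt[["B"]] == 0) return(0)
  if (cnt[["A"]] == 0) return(-log(2 / ((n - m - 1) * (n - m))))
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Multiscale entropy curve
#'
#' Coarse-grains the series by non-overlapping window averaging at each scale
#' and computes the sample entropy of each coarse-grained series, holding the
#' tolerance fixed at `r` computed from the original series (the usual
#' multiscale convention). Returns the curve and its three scalar summaries:
#' trapezoid integral over scale, mean, and standard deviation.
#'
#' @param x numeric series
#' @param m template length
#' @param r tolerance; default `0.2 * sd(x)`
#' @param scales integer vector of scales (in samples)
#' @return list with `scales`, `sampen` (the curve), and scalars `integral`,
#'   `mean`, `sd`
#' @export
multiscaleEntropy <- function(x, m = 2, r = 0.2 * stats::sd(x),
                              scales = 1:20) {
  stopifnot(all(scales >= 1), !is.unsorted(scales, strictly = TRUE))
  if (length(x) < max(scales) * (m + 2))
    stop("series too short for the coarsest scale")
  se <- vapply(scales, function(s) {
    cg <- if (s == 1) x else cpp_coarse_grain(x, as.integer(s))
    sampleEntropy(cg, m = m, r = r)
  }, numeric(1))
  integral <- if (length(scales) > 1)
    sum(diff(scales) * (se[-1] + se[-length(se)]) / 2) else 0
  list(scales = as.integer(scales), sampen = se,
       integral = integral, mean = mean(se), sd = stats::sd(se))
}

#' Multiscale-entropy features
#'
#' Per neuron, the three scalars of the multiscale entropy curve (integral,
#' mean, SD over scales); each scalar field is then summarized by
#' [fieldSummary()] for 3 x 6 = 18 features.
#'
#' @param result a [SimulationResult-class]
#' @param scales scales passed to [multiscaleEntropy()]
#' @param m template length
#' @return named numeric vector of length 18
#' @export
mseFeatures <- function(result, scales = 1:20, m = 2) {
  traces <- voltageTraces(result)
  per <- apply(traces, 1, function(tr) {
    mse <- multiscaleEntropy(tr, m = m, scales = scales)
    c(mse$integral, mse$mean, mse$sd)
  })
  geom <- geometry(result)
  c(fieldSummary(per[1, ], geom, "mse_integral"),
    fieldSummary(per[2, ], geom, "mse_mean"),
    fieldSummary(per[3, ], geom, "mse_sd"))
}
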