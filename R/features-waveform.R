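#' Detect action-potential events in a voltage trace
#'
#' An event is a maximal contiguous run of samples at or above the threshold;
#' its duration is the run length times the sampling step.
#'
#' @param trace numeric voltage series (mV)
#' @param dt sampling step (ms)
#' @param threshold detection threshold (mV)
#' @return data.frame with columns `onset`, `offset` (ms, inclusive sample
#'   times) and `duration` (ms); zero rows if the trace never crosses
#' @examples
#' tr <- rep(-70, 100); tr[21:45] <- -50
#' detectAps(tr, dt = 0.1)  # one event of 2.5 ms
#' @export
detectAps <- function(trace, dt = 0.1, threshold = -63) {
  above <- trace >= threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset = (starts[keep] - 1) * dt,
             offset = (ends[keep] - 1) * dt,
             duration = r$lengths[keep] * dt)
}

#' Per-neuron waveform-shape scalars
#'
#' For each neuron: frequency and mean duration of paroxysmal depolarization
#' shifts (PDS: events at least 50% longer than the subject-wide mean event
#' duration), frequency and mean duration of interictal spikes (IIS: isolated
#' events shorter than 50% of the mean duration, "isolated" meaning no other
#' event in the same neuron within `isolationMs`), total line length of the
#' trace, and rectified area under the curve `sum(|V|) * dt`. Neurons without
#' qualifying events report zero durations.
#'
#' @param result a [SimulationResult-class]
#' @param threshold event-detection threshold (mV)
#' @param isolationMs isolation window for IIS (ms)
#' @return matrix 6 x neurons with rows `pds_rate`, `pds_dur`, `iis_rate`,
#'   `iis_dur`, `line_length`, `auc`
#' @export
waveformScalars <- function(result, threshold = -63, isolationMs = 50) {
  traces <- voltageTraces(result)
  dt <- result@dt
  durS <- result@durationMs / 1000
  events <- apply(traces, 1, detectAps, dt = dt, threshold = threshold,
                  simplify = FALSE)
  refDur <- mean(unlist(lapply(events, `[[`, "duration")))
  out <- vapply(seq_along(events), function(i) {
    ev <- events[[i]]
    tr <- traces[i, ]
    ll <- cpp_line_length(tr)
    auc <- sum(abs(tr)) * dt
    if (nrow(ev) == 0 || is.na(refDur)) {
      return(c(0, 0, 0, 0, ll, auc))
    }
    pds <- ev$duration >= 1.5 * refDur
    mid <- (ev$onset + ev$offset) / 2
    isolated <- vapply(seq_along(mid), function(k) {
      others <- mid[-k]
      length(others) == 0 || min(abs(others - mid[k])) > isolationMs
    }, logical(1))
    iis <- isolated & ev$duration < 0.5 * refDur
    c(sum(pds) / durS, if (any(pds)) mean(ev$duration[pds]) else 0,
      sum(iis) / durS, if (any(iis)) mean(ev$duration[iis]) else 0,
      ll, auc)
  }, numeric(6))
  rownames(out) <- c("pds_rate", "pds_dur", "iis_rate", "iis_dur",
                     "line_length", "auc")
  out
}

#' Waveform-shape features
#'
#' The six per-neuron scalars of [waveformScalars()], each summarized by
#' [fieldSummary()], for 6 x 6 = 36 features.
#'
#' @inheritParams waveformScalars
#' @return named numeric vector of length 36
#' @export
waveformFeatures <- function(result, threshold = -63, isolationMs = 50) {
  sc <- waveformScalars(result, threshold = threshold,
                        isolationMs = isolationMs)
  geom <- geometry(result)
  out <- lapply(rownames(sc), function(nm) fieldSummary(sc[nm, ], geom, nm))
  unlist(out)
}
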