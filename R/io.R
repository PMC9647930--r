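#' Build a simulation result from external trace files
#'
#' Entry point for non-simulated data: a numeric trace matrix (rows = time,
#' columns = neurons/channels, in mV) and a channel-coordinate table
#' (`neuron_id`, `x_um`, `y_um`) on a rectangular lattice. Spike trains are
#' reconstructed from upward threshold crossings so the whole feature panel
#' can be computed. Excitatory/inhibitory identity and membrane area are not
#' observable from recordings and are filled with placeholders (all
#' excitatory, mid-range area); no feature depends on them.
#'
#' @param tracesPath CSV of the time x channels voltage matrix (no header
#'   needed; a header row is auto-detected)
#' @param positionsPath CSV with columns `neuron_id`, `x_um`, `y_um`
#' @param dt sampling step (ms)
#' @param threshold spike threshold (mV)
#' @param label class label to record
#' @return a [SimulationResult-class]
#' @export
readTracesCsv <- function(tracesPath, positionsPath, dt = 0.1,
                          threshold = -63, label = "healthy") {
  first <- utils::read.csv(tracesPath, header = FALSE, nrows = 1)
  hasHeader <- !all(vapply(first, is.numeric, logical(1)))
  traces <- t(as.matrix(utils::read.csv(tracesPath, header = hasHeader)))
  pos <- utils::read.csv(positionsPath)
  stopifnot(all(c("neuron_id", "x_um", "y_um") %in% names(pos)))
  pos <- pos[order(pos$neuron_id), ]
  if (nrow(pos) != nrow(traces))
    stop("positions table has ", nrow(pos), " channels but traces have ",
         nrow(traces))
  ux <- sort(unique(pos$x_um))
  uy <- sort(unique(pos$y_um))
  pitch <- if (length(ux) > 1) min(diff(ux)) else
    if (length(uy) > 1) min(diff(uy)) else 10
  geom <- new("NetworkGeometry",
              positions = cbind(x = pos$x_um - min(pos$x_um),
                                y = pos$y_um - min(pos$y_um)),
              areas = rep(20000, nrow(pos)),
              isExcitatory = rep(TRUE, nrow(pos)),
              gridShape = c(length(ux), length(uy)), pitch = pitch)
  spikes <- apply(traces, 1, function(tr) {
    ev <- detectAps(tr, dt = dt, threshold = threshold)
    ev$onset
  }, simplify = FALSE)
  new("SimulationResult", traces = traces, spikes = spikes,
      geometry = geom, label = label, seed = 0L, dt = dt,
      durationMs = ncol(traces) * dt)
}
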