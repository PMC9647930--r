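#' @describeIn NetworkGeometry-class neuron (x, y) coordinates in um
#' @export
setMethod("positions", "NetworkGeometry", function(x) x@positions)

#' @describeIn NetworkGeometry-class per-neuron membrane area (um^2)
#' @export
setMethod("areas", "NetworkGeometry", function(x) x@areas)

#' @describeIn NetworkGeometry-class per-neuron excitatory flag
#' @export
setMethod("isExcitatory", "NetworkGeometry", function(x) x@isExcitatory)

#' @describeIn SimulationResult-class voltage matrix (neurons x time, mV)
#' @export
setMethod("voltageTraces", "SimulationResult", function(x) x@traces)

#' @describeIn SimulationResult-class list of per-neuron spike times (ms)
#' @export
setMethod("spikeTimes", "SimulationResult", function(x) x@spikes)

#' @describeIn SimulationResult-class genetic class label of the subject
#' @export
setMethod("diseaseClass", "SimulationResult", function(x) x@label)

#' @describeIn SimulationResult-class the network geometry
#' @export
setMethod("geometry", "SimulationResult", function(x) x@geometry)

#' @describeIn SimulationResult-class per-neuron firing rate (Hz)
#' @param ... unused
#' @export
setMethod("firingRates", "SimulationResult", function(x, ...) {
  vapply(x@spikes, length, numeric(1)) / (x@durationMs / 1000)
})

setMethod("show", "NetworkGeometry", function(object) {
  cat(sprintf("NetworkGeometry: %d neurons on a %d x %d lattice (pitch %g um)\n",
              nrow(object@positions), object@gridShape[1], object@gridShape[2],
              object@pitch))
  cat(sprintf("  excitatory: %d, inhibitory: %d\n",
              sum(object@isExcitatory), sum(!object@isExcitatory)))
})

setMethod("show", "SynapseTable", function(object) {
  cat(sprintf("SynapseTable: %d directed edges (%d excitatory, %d inhibitory)\n",
              length(object@pre), sum(object@excitatory),
              sum(!object@excitatory)))
})

setMethod("show", "SimulationResult", function(object) {
  nSpk <- sum(lengths(object@spikes))
  cat(sprintf("SimulationResult: class '%s', %d neurons, %g ms at dt %g ms\n",
              object@label, length(object@spikes), object@durationMs,
              object@dt))
  cat(sprintf("  %d spikes (network mean rate %.2f Hz), seed %d\n", nSpk,
              mean(firingRates(object)), object@seed))
})

setMethod("show", "HHParams", function(object) {
  cat("HHParams (densities per cm^2, voltages mV, times ms):\n")
  cat(sprintf("  Cm %g uF, gl %g mS, gNa0 %g mS, gK0 %g mS\n",
              object@Cm, object@gl, object@gNa0, object@gK0))
  cat(sprintf("  El %g, ENa %g, EK %g, VT %g, vSpike %g; tauNa %g, tauK %g, dt %g\n",
              object@El, object@ENa, object@EK, object@VT, object@vSpike,
              object@tauNa, object@tauK, object@dt))
})
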