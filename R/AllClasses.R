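#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib epinetml, .registration = TRUE
NULL

#' Membrane (Hodgkin-Huxley type) parameter set
#'
#' Parameters of the conductance-based membrane model: leak plus
#' transient sodium and delayed-rectifier potassium channels whose maximal
#' conductances are themselves dynamic, relaxing toward resting values
#' `gNa0`/`gK0` and bumped by synaptic input. Densities are per membrane
#' area; voltages in mV, times in ms.
#'
#' @slot Cm membrane capacitance density (uF cm^-2)
#' @slot gl leak conductance density (mS cm^-2)
#' @slot El,ENa,EK leak, sodium and potassium Nernst potentials (mV)
#' @slot gNa0,gK0 resting ligand-channel conductance densities (mS cm^-2)
#' @slot tauNa,tauK conductance relaxation time constants (ms)
#' @slot VT gating-kinetics threshold parameter (mV)
#' @slot vSpike spike-detection threshold (mV)
#' @slot dt integration step (ms)
#' @exportClass HHParams
setClass("HHParams", representation(
  Cm = "numeric", gl = "numeric", El = "numeric", ENa = "numeric",
  EK = "numeric", gNa0 = "numeric", gK0 = "numeric", tauNa = "numeric",
  tauK = "numeric", VT = "numeric", vSpike = "numeric", dt = "numeric"))

setValidity("HHParams", function(object) {
  msg <- character()
  if (any(c(object@gl, object@gNa0, object@gK0) < 0))
    msg <- c(msg, "conductances must be non-negative")
  if (!(object@EK < object@El && object@El < object@vSpike &&
        object@vSpike < object@ENa))
    msg <- c(msg, "require EK < El < vSpike < ENa")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@tauNa <= 0 || object@tauK <= 0)
    msg <- c(msg, "time constants must be positive")
  if (length(msg)) msg else TRUE
})

#' Synapse and connectivity parameter set
#'
#' Short-term plasticity (facilitation/depression) constants and the
#' distance-dependent Gaussian connection-probability profile, separately for
#' excitatory and inhibitory presynaptic neurons.
#'
#' @slot omegaF facilitation decay rate (s^-1)
#' @slot omegaD depression recovery rate (s^-1)
#' @slot U0 neurotransmitter release fraction on a spike (dimensionless)
#' @slot wE,wI excitatory/inhibitory synaptic weights (mS)
#' @slot RE,RI synaptic-to-initialization weight ratios (dimensionless)
#' @slot ampE,ampI connection-probability amplitudes at zero distance
#' @slot sdE,sdI connection-probability Gaussian SDs (um)
#' @exportClass SynapseParams
setClass("SynapseParams", representation(
  omegaF = "numeric", omegaD = "numeric", U0 = "numeric",
  wE = "numeric", wI = "numeric", RE = "numeric", RI = "numeric",
  ampE = "numeric", ampI = "numeric", sdE = "numeric", sdI = "numeric"))

setValidity("SynapseParams", function(object) {
  msg <- character()
  if (object@U0 <= 0 || object@U0 > 1) msg <- c(msg, "U0 must be in (0, 1]")
  if (any(c(object@ampE, object@ampI) <= 0) ||
      any(c(object@ampE, object@ampI) > 1))
    msg <- c(msg, "connection amplitudes must be in (0, 1]")
  if (object@sdE <= 0 || object@sdI <= 0)
    msg <- c(msg, "connection SDs must be positive")
  if (length(msg)) msg else TRUE
})

#' Network geometry on a rectangular electrode lattice
#'
#' One neuron per electrode site on a rectangular lattice with fixed pitch;
#' per-neuron excitatory/inhibitory identity and membrane area.
#'
#' @slot positions numeric matrix (neurons x 2) of (x, y) coordinates in um
#' @slot areas per-neuron membrane area (um^2)
#' @slot isExcitatory per-neuron logical flag
#' @slot gridShape integer c(ncol, nrow) of the lattice
#' @slot pitch electrode spacing (um)
#' @exportClass NetworkGeometry
setClass("NetworkGeometry", representation(
  positions = "matrix", areas = "numeric", isExcitatory = "logical",
  gridShape = "integer", pitch = "numeric"))

setValidity("NetworkGeometry", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (n != prod(object@gridShape))
    msg <- c(msg, "number of neurons must equal number of lattice sites")
  if (length(object@areas) != n || length(object@isExcitatory) != n)
    msg <- c(msg, "areas and isExcitatory must have one entry per neuron")
  xmax <- (object@gridShape[1] - 1) * object@pitch
  ymax <- (object@gridShape[2] - 1) * object@pitch
  if (n > 0 && (any(object@positions[, 1] < 0) ||
                any(object@positions[, 1] > xmax) ||
                any(object@positions[, 2] < 0) ||
                any(object@positions[, 2] > ymax)))
    msg <- c(msg, "positions must lie on the lattice bounding box")
  if (length(msg)) msg else TRUE
})

#' Directed synapse table with short-term plasticity state
#'
#' @slot pre,post 1-based presynaptic/postsynaptic neuron indices
#' @slot excitatory per-edge sign, from the presynaptic label
#' @slot uS,xS per-edge release/resource state in `[0, 1]`
#' @exportClass SynapseTable
setClass("SynapseTable", representation(
  pre = "integer", post = "integer", excitatory = "logical",
  uS = "numeric", xS = "numeric"))

setValidity("SynapseTable", function(object) {
  msg <- character()
  if (any(object@pre == object@post))
    msg <- c(msg, "self-edges are not allowed")
  if (length(object@uS) && (any(object@uS < 0) || any(object@uS > 1)))
    msg <- c(msg, "uS must be in [0, 1]")
  if (length(object@xS) && (any(object@xS < 0) || any(object@xS > 1)))
    msg <- c(msg, "xS must be in [0, 1]")
  lens <- lengths(list(object@pre, object@post, object@excitatory,
                       object@uS, object@xS))
  if (length(unique(lens)) != 1)
    msg <- c(msg, "all edge vectors must have equal length")
  if (length(msg)) msg else TRUE
})

#' Result of one subject simulation
#'
#' Voltage traces (one row per neuron, mV, sampled every `dt` ms), per-neuron
#' spike times, the geometry, the subject's genetic class, and the seed.
#'
#' @slot traces numeric matrix, neurons x time steps (mV)
#' @slot spikes list of numeric vectors of spike times (ms), one per neuron
#' @slot geometry a [NetworkGeometry-class]
#' @slot label one of `"healthy"`, `"gof"`, `"lof"`
#' @slot seed integer master seed for the subject
#' @slot dt sampling/integration step (ms)
#' @slot durationMs simulated duration (ms)
#' @exportClass SimulationResult
setClass("SimulationResult", representation(
  traces = "matrix", spikes = "list", geometry = "NetworkGeometry",
  label = "character", seed = "integer", dt = "numeric",
  durationMs = "numeric"))

setValidity("SimulationResult", function(object) {
  msg <- character()
  n <- nrow(object@geometry@positions)
  if (nrow(object@traces) > 0 && nrow(object@traces) != n)
    msg <- c(msg, "trace count must equal neuron count")
  if (length(object@spikes) != n)
    msg <- c(msg, "one spike train per neuron required")
  if (!object@label %in% diseaseClasses())
    msg <- c(msg, "label must be one of healthy/gof/lof")
  bad <- vapply(object@spikes, function(s) any(diff(s) <= 0), logical(1))
  if (any(bad)) msg <- c(msg, "spike times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Cohort of subjects with extracted electrophysiological features
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose single assay
#' holds the feature panel (features x subjects) and whose column data carries
#' the genetic class label and per-subject seed.
#'
#' @exportClass EpCohort
#' @import SummarizedExperiment
setClass("EpCohort", contains = "SummarizedExperiment")

setValidity("EpCohort", function(object) {
  msg <- character()
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  else if (!all(object$label %in% diseaseClasses()))
    msg <- c(msg, "labels must be healthy/gof/lof")
  if (length(msg)) msg else TRUE
})
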