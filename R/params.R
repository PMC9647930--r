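#' Genetic classes modeled
#'
#' The three subject classes: `"healthy"`, `"gof"` (global sodium-channel
#' gain-of-function, the Dravet-type Nav1.1 open-state mutation applied to
#' every neuron) and `"lof"` (sodium-channel loss-of-function restricted to
#' inhibitory neurons).
#'
#' @return character vector of class names, in the fixed tie-break order used
#'   by the ensemble rule.
#' @export
diseaseClasses <- function() c("healthy", "gof", "lof")

#' Construct the membrane parameter set
#'
#' Defaults are the healthy-subject values: leak 50 uS cm^-2 (0.05 mS cm^-2),
#' resting sodium/potassium ligand-channel conductances 100/30 mS cm^-2 with
#' 6 ms relaxation, Nernst potentials -65/50/-90 mV (leak/Na/K), membrane
#' capacitance 1 uF cm^-2, gating threshold parameter and spike threshold
#' both -63 mV, and a 0.1 ms integration step.
#'
#' @param Cm,gl,El,ENa,EK,gNa0,gK0,tauNa,tauK,VT,vSpike,dt see
#'   [HHParams-class]
#' @return an [HHParams-class] object
#' @export
hhParams <- function(Cm = 1, gl = 0.05, El = -65, ENa = 50, EK = -90,
                     gNa0 = 100, gK0 = 30, tauNa = 6, tauK = 6,
                     VT = -63, vSpike = -63, dt = 0.1) {
  new("HHParams", Cm = Cm, gl = gl, El = El, ENa = ENa, EK = EK,
      gNa0 = gNa0, gK0 = gK0, tauNa = tauNa, tauK = tauK, VT = VT,
      vSpike = vSpike, dt = dt)
}

#' Construct the synapse parameter set
#'
#' Defaults: facilitation decay 3.33 s^-1, depression recovery 2 s^-1,
#' release fraction U0 = 0.6, synaptic weights 70 mS (excitatory) and 20 mS
#' (inhibitory) with weight ratios 15.1 and 9, and Gaussian connection
#' profiles with amplitudes 0.83/0.41 and SDs 15.5/12 um.
#'
#' @param omegaF,omegaD,U0,wE,wI,RE,RI,ampE,ampI,sdE,sdI see
#'   [SynapseParams-class]
#' @return a [SynapseParams-class] object
#' @export
synapseParams <- function(omegaF = 3.33, omegaD = 2, U0 = 0.6,
                          wE = 70, wI = 20, RE = 15.1, RI = 9,
                          ampE = 0.83, ampI = 0.41, sdE = 15.5, sdI = 12) {
  new("SynapseParams", omegaF = omegaF, omegaD = omegaD, U0 = U0,
      wE = wE, wI = wI, RE = RE, RI = RI, ampE = ampE, ampI = ampI,
      sdE = sdE, sdI = sdI)
}

#' Effective resting sodium conductance under a channel-fraction mutation
#'
#' A fraction of membrane sodium channels carries the mutant isoform whose
#' conductance is `fold` times the wild-type closed-state value; the rest stay
#' wild type. The effective resting conductance density is
#' `(1 - fraction) * g0 + fraction * fold * g0`.
#'
#' @param g0 wild-type resting conductance density (mS cm^-2)
#' @param fraction fraction of channels carrying the mutant isoform
#' @param fold conductance of the mutant isoform relative to wild type
#' @return effective resting conductance density (mS cm^-2)
#' @examples
#' effectiveSodiumConductance(100, 0.2, 80) # gain-of-function: 1680
#' effectiveSodiumConductance(100, 0.2, 0)  # loss-of-function: 80
#' @export
effectiveSodiumConductance <- function(g0, fraction, fold) {
  stopifnot(fraction >= 0, fraction <= 1, fold >= 0)
  (1 - fraction) * g0 + fraction * fold * g0
}

#' Apply a genetic class to the membrane parameters
#'
#' Returns the per-neuron resting sodium conductance vector for a network:
#' healthy subjects keep the baseline; gain-of-function subjects express the
#' 80-fold-conducting mutant isoform in 20% of sodium channels in every
#' neuron (1680 mS cm^-2); loss-of-function subjects express a non-conducting
#' isoform in 20% of the sodium channels of inhibitory neurons only
#' (80 mS cm^-2), excitatory neurons unchanged.
#'
#' @param base an [HHParams-class] healthy parameter set
#' @param label one of [diseaseClasses()]
#' @param geom a [NetworkGeometry-class]
#' @param fraction mutant channel fraction (default 0.2)
#' @param gofFold conductance fold-change of the gain-of-function isoform
#' @return numeric vector of per-neuron resting sodium conductances
#'   (mS cm^-2)
#' @export
applyDisease <- function(base, label, geom, fraction = 0.2, gofFold = 80) {
  stopifnot(is(base, "HHParams"), is(geom, "NetworkGeometry"))
  n <- nrow(positions(geom))
  gNa <- rep(base@gNa0, n)
  switch(label,
    healthy = gNa,
    gof = rep(effectiveSodiumConductance(base@gNa0, fraction, gofFold), n),
    lof = {
      gNa[!isExcitatory(geom)] <-
        effectiveSodiumConductance(base@gNa0, fraction, 0)
      gNa
    },
    stop("unknown disease class: ", label))
}
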