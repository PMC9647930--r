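#' Derive stage sub-seeds from a master seed
#'
#' Each stochastic stage of a subject simulation (geometry, wiring, initial
#' state) consumes its own deterministic sub-seed so stages are independently
#' reproducible.
#'
#' @param seed master integer seed
#' @param n number of sub-seeds
#' @return integer vector of `n` sub-seeds
#' @export
deriveSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Initial neuron state
#'
#' Starting voltages are uniform between the leak Nernst potential and the
#' spike threshold. Initial ligand-channel conductances follow
#' `g = (eta + 1) * w * A` with `eta ~ U(0, 1)`, `w` the excitatory
#' (sodium) or inhibitory (potassium) synaptic weight, and `A` the membrane
#' area normalized by `areaNorm` (default 5,000 um^2). With this
#' normalization initial sodium conductances span 140-840 mS cm^-2, which
#' straddles the ~275 mS cm^-2 self-excitation boundary of the membrane
#' model: every network starts with a sparse subpopulation of
#' suprathreshold neurons whose initial volley seeds activity, while
#' remaining well below the gain-of-function resting conductance.
#' Gating variables start at their steady state for the initial voltage.
#'
#' @param geom a [NetworkGeometry-class]
#' @param hh an [HHParams-class]
#' @param syn a [SynapseParams-class]
#' @param seed integer RNG seed
#' @param areaNorm area normalization constant (um^2)
#' @return list with numeric vectors `V`, `m`, `n`, `h`, `gNa`, `gK`
#' @export
initState <- function(geom, hh, syn, seed, areaNorm = 5000) {
  stopifnot(is(geom, "NetworkGeometry"), is(hh, "HHParams"),
            is(syn, "SynapseParams"))
  set.seed(seed)
  n <- nrow(positions(geom))
  V <- stats::runif(n, hh@El, hh@vSpike)
  aHat <- areas(geom) / areaNorm
  etaNa <- stats::runif(n)
  etaK <- stats::runif(n)
  gNa <- (etaNa + 1) * syn@wE * aHat
  gK <- (etaK + 1) * syn@wI * aHat
  gate <- vapply(V, cpp_gating_steady, numeric(3), VT = hh@VT)
  list(V = V, m = gate["m", ], n = gate["n", ], h = gate["h", ],
       gNa = gNa, gK = gK)
}

#' One presynaptic release event (short-term plasticity)
#'
#' On a presynaptic spike a fraction `U0` of undocked resources docks
#' (`uS' = uS + U0 (1 - uS)`), the docked fraction of available resources is
#' released (`rS = uS' * xS`) and deducted (`xS' = xS - rS`).
#'
#' @param uS,xS synapse state in `[0, 1]`
#' @param U0 release fraction
#' @return list with `uS`, `xS`, `rS`
#' @examples
#' synapseEvent(0, 1, 0.6)  # uS 0.6, rS 0.6, xS 0.4
#' @export
synapseEvent <- function(uS, xS, U0) {
  stopifnot(uS >= 0, uS <= 1, xS >= 0, xS <= 1)
  u <- uS + U0 * (1 - uS)
  r <- u * xS
  list(uS = u, xS = xS - r, rS = r)
}

#' Decay of synapse state between events
#'
#' Closed-form exponentials: `uS` decays to 0 at rate `omegaF`, `xS` recovers
#' to 1 at rate `omegaD` (rates per second, gap in ms).
#'
#' @param uS,xS synapse state
#' @param gapMs elapsed time since the last event (ms)
#' @param syn a [SynapseParams-class]
#' @return list with decayed `uS`, `xS`
#' @export
synapseDecay <- function(uS, xS, gapMs, syn) {
  list(uS = uS * exp(-syn@omegaF / 1000 * gapMs),
       xS = 1 + (xS - 1) * exp(-syn@omegaD / 1000 * gapMs))
}

#' Integrate the network
#'
#' Advances the membrane, gating, conductance and synapse equations by
#' exponential Euler at step `hh@dt`, records a spike on each upward crossing
#' of the threshold (a neuron is refractory while its voltage stays at or
#' above threshold), and applies presynaptic release to postsynaptic
#' conductances at the end of the step in which a spike occurs: excitatory
#' edges increment the target's sodium conductance by `wE * rS * RE`,
#' inhibitory edges the potassium conductance by `wI * rS * RI`.
#'
#' @param state initial state list from [initState()]
#' @param synTable a [SynapseTable-class]
#' @param hh an [HHParams-class]
#' @param syn a [SynapseParams-class]
#' @param geom a [NetworkGeometry-class]
#' @param durationMs simulated duration (ms); must be a multiple of `hh@dt`
#' @param gNaRest optional per-neuron resting sodium conductance (from
#'   [applyDisease()]); defaults to the healthy baseline
#' @param label subject class recorded on the result
#' @param seed seed recorded on the result
#' @param keepTraces logical; store the voltage matrix (needed for feature
#'   extraction)
#' @return a [SimulationResult-class]
#' @export
integrateNetwork <- function(state, synTable, hh, syn, geom,
                             durationMs = 1000, gNaRest = NULL,
                             label = "healthy", seed = 0L,
                             keepTraces = TRUE) {
  stopifnot(is(synTable, "SynapseTable"), is(hh, "HHParams"),
            is(syn, "SynapseParams"), is(geom, "NetworkGeometry"))
  nSteps <- round(durationMs / hh@dt)
  if (abs(nSteps * hh@dt - durationMs) > 1e-9)
    stop("durationMs must be a multiple of dt")
  n <- length(state$V)
  if (is.null(gNaRest)) gNaRest <- rep(hh@gNa0, n)
  nEdges <- length(synTable@pre)
  incNa <- ifelse(synTable@excitatory, syn@wE * syn@RE, 0)
  incK <- ifelse(synTable@excitatory, 0, syn@wI * syn@RI)
  out <- cpp_integrate(
    state$V, state$m, state$n, state$h, state$gNa, state$gK,
    gNaRest, rep(hh@gK0, n),
    hh@gl, hh@El, hh@ENa, hh@EK, hh@Cm, hh@tauNa, hh@tauK, hh@VT,
    hh@vSpike, hh@dt, nSteps,
    synTable@pre - 1L, synTable@post - 1L,
    if (nEdges) incNa else numeric(0), if (nEdges) incK else numeric(0),
    syn@U0, syn@omegaF / 1000, syn@omegaD / 1000, keepTraces)
  traces <- if (keepTraces) out$traces else
    matrix(numeric(0), nrow = 0, ncol = 0)
  new("SimulationResult", traces = traces, spikes = out$spikes,
      geometry = geom, label = label, seed = as.integer(seed), dt = hh@dt,
      durationMs = durationMs)
}

#' Simulate one subject end to end
#'
#' Builds the geometry, wires the network, applies the genetic class to the
#' resting sodium conductance, initializes the state, and integrates for
#' `durationMs`. All randomness derives from the subject seed through fixed
#' stage sub-seeds, so results are bitwise reproducible.
#'
#' @param seed subject master seed
#' @param label one of [diseaseClasses()]
#' @param durationMs simulated duration (ms)
#' @param hh,syn parameter sets; defaults are the healthy study values
#' @param nExc,nInh,gridShape,pitch geometry configuration (see
#'   [buildGeometry()])
#' @param keepTraces logical; keep the voltage matrix
#' @return a [SimulationResult-class]
#' @examples
#' \donttest{
#' res <- simulateSubject(1, "healthy", durationMs = 200,
#'                        nExc = 13, nInh = 7, gridShape = c(5, 4))
#' mean(firingRates(res))
#' }
#' @export
simulateSubject <- function(seed, label = "healthy", durationMs = 1000,
                            hh = hhParams(), syn = synapseParams(),
                            nExc = 132, nInh = 68, gridShape = c(20, 10),
                            pitch = 10, keepTraces = TRUE) {
  label <- match.arg(label, diseaseClasses())
  ss <- deriveSeeds(seed, 3)
  geom <- buildGeometry(ss[1], nExc = nExc, nInh = nInh,
                        gridShape = gridShape, pitch = pitch)
  synTable <- connectNetwork(geom, syn, ss[2])
  state <- initState(geom, hh, syn, ss[3])
  gNaRest <- applyDisease(hh, label, geom)
  integrateNetwork(state, synTable, hh, syn, geom, durationMs = durationMs,
                   gNaRest = gNaRest, label = label, seed = seed,
                   keepTraces = keepTraces)
}
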