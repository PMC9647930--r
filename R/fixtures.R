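#' Small analytically tractable simulation fixtures
#'
#' Fast, reduced-scale simulation results for testing and exploration:
#' \describe{
#'   \item{`leak_only`}{a 2 x 2 network with no synapses and sodium/potassium
#'     conductances pinned to rest; subthreshold, silent, voltages relax
#'     toward the leak potential.}
#'   \item{`single_spiker`}{one tonically spiking neuron (2 x 1 lattice with a
#'     silent partner) driven by an elevated resting sodium conductance.}
#'   \item{`two_coupled`}{a driver neuron (elevated sodium rest) with a single
#'     excitatory synapse onto a quiet follower; used for transfer-entropy
#'     directionality checks.}
#'   \item{`tiny_network`}{a 5 x 4 lattice (13 excitatory, 7 inhibitory) wired
#'     and integrated with the study parameters; `label` selects the genetic
#'     class.}
#' }
#'
#' @param kind fixture name
#' @param seed integer seed
#' @param durationMs simulated duration (ms)
#' @param label genetic class for `tiny_network`
#' @return a [SimulationResult-class]
#' @export
makeFixture <- function(kind = c("leak_only", "single_spiker", "two_coupled",
                                 "tiny_network"),
                        seed = 1, durationMs = 200, label = "healthy") {
  kind <- match.arg(kind)
  hh <- hhParams()
  syn <- synapseParams()
  if (kind == "tiny_network") {
    return(simulateSubject(seed, label, durationMs = durationMs,
                           nExc = 13, nInh = 7, gridShape = c(5, 4)))
  }
  if (kind == "leak_only") {
    hh <- hhParams(gNa0 = 0, gK0 = 0)  # channels silenced: pure leak decay
    geom <- buildGeometry(seed, nExc = 3, nInh = 1, gridShape = c(2, 2))
    edges <- new("SynapseTable", pre = integer(0), post = integer(0),
                 excitatory = logical(0), uS = numeric(0), xS = numeric(0))
    set.seed(seed)
    V <- stats::runif(4, hh@El, hh@vSpike)
    gate <- vapply(V, cpp_gating_steady, numeric(3), VT = hh@VT)
    state <- list(V = V, m = gate["m", ], n = gate["n", ], h = gate["h", ],
                  gNa = rep(0, 4), gK = rep(0, 4))
    return(integrateNetwork(state, edges, hh, syn, geom,
                            durationMs = durationMs, label = "healthy",
                            seed = seed))
  }
  # single_spiker / two_coupled share a 2 x 1 lattice
  geom <- buildGeometry(seed, nExc = 2, nInh = 0, gridShape = c(2, 1))
  edges <- if (kind == "two_coupled")
    new("SynapseTable", pre = 1L, post = 2L, excitatory = TRUE,
        uS = 0, xS = 1)
  else
    new("SynapseTable", pre = integer(0), post = integer(0),
        excitatory = logical(0), uS = numeric(0), xS = numeric(0))
  set.seed(seed)
  V <- c(stats::runif(1, hh@El, hh@vSpike), hh@El)
  gate <- vapply(V, cpp_gating_steady, numeric(3), VT = hh@VT)
  state <- list(V = V, m = gate["m", ], n = gate["n", ], h = gate["h", ],
                gNa = c(900, hh@gNa0), gK = rep(hh@gK0, 2))
  # driver held in the periodic-spiking regime, follower at baseline
  gNaRest <- c(900, hh@gNa0)
  integrateNetwork(state, edges, hh, syn, geom, durationMs = durationMs,
                   gNaRest = gNaRest, label = "healthy", seed = seed)
}
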