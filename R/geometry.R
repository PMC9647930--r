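#' Build the network geometry on an electrode lattice
#'
#' Places one neuron on each electrode of a rectangular lattice (default
#' 20 x 10 electrodes at 10 um pitch, 200 sites). Excitatory/inhibitory
#' identity (default 132 excitatory, 68 inhibitory) is assigned by a random
#' permutation over sites, and each neuron draws a membrane area uniformly
#' from 10,000-30,000 um^2. Deterministic given the seed.
#'
#' @param seed integer RNG seed
#' @param nExc,nInh numbers of excitatory and inhibitory neurons; their sum
#'   must equal the number of lattice sites
#' @param gridShape integer c(columns, rows) of the lattice
#' @param pitch electrode spacing (um)
#' @param areaRange range of membrane areas (um^2)
#' @return a [NetworkGeometry-class]
#' @examples
#' g <- buildGeometry(seed = 1)
#' sum(isExcitatory(g))  # 132
#' @export
buildGeometry <- function(seed, nExc = 132, nInh = 68, gridShape = c(20, 10),
                          pitch = 10, areaRange = c(10000, 30000)) {
  gridShape <- as.integer(gridShape)
  nSites <- prod(gridShape)
  if (nExc + nInh != nSites)
    stop("nExc + nInh (", nExc + nInh, ") must equal the number of lattice ",
         "sites (", nSites, ")")
  set.seed(seed)
  xy <- expand.grid(x = (seq_len(gridShape[1]) - 1) * pitch,
                    y = (seq_len(gridShape[2]) - 1) * pitch)
  flags <- sample(rep(c(TRUE, FALSE), c(nExc, nInh)))
  areaDraw <- stats::runif(nSites, areaRange[1], areaRange[2])
  new("NetworkGeometry",
      positions = cbind(x = xy$x, y = xy$y),
      areas = areaDraw, isExcitatory = flags, gridShape = gridShape,
      pitch = pitch)
}

#' Distance-dependent connection probability
#'
#' Gaussian profile `amp * exp(-d^2 / (2 * sd^2))` with amplitude and SD
#' taken from the presynaptic neuron's identity.
#'
#' @param d Euclidean distance (um)
#' @param syn a [SynapseParams-class]
#' @param excitatory logical; presynaptic identity
#' @return connection probability in `[0, 1]`
#' @export
connectionProbability <- function(d, syn, excitatory) {
  amp <- ifelse(excitatory, syn@ampE, syn@ampI)
  sd <- ifelse(excitatory, syn@sdE, syn@sdI)
  amp * exp(-d^2 / (2 * sd^2))
}

#' Wire the network
#'
#' Draws a directed edge for every ordered neuron pair (no self-edges) with
#' the Gaussian distance-dependent probability of [connectionProbability()];
#' per-edge short-term-plasticity state is initialized to `uS = 0`,
#' `xS = 1`. Deterministic given the seed.
#'
#' @param geom a [NetworkGeometry-class]
#' @param syn a [SynapseParams-class]
#' @param seed integer RNG seed
#' @return a [SynapseTable-class]
#' @export
connectNetwork <- function(geom, syn, seed) {
  stopifnot(is(geom, "NetworkGeometry"), is(syn, "SynapseParams"))
  set.seed(seed)
  pos <- positions(geom)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  prob <- matrix(0, n, n)
  exc <- isExcitatory(geom)
  for (i in seq_len(n))
    prob[i, ] <- connectionProbability(d[i, ], syn, exc[i])
  diag(prob) <- 0
  draw <- matrix(stats::runif(n * n), n, n)
  hit <- which(draw < prob, arr.ind = TRUE)
  new("SynapseTable",
      pre = as.integer(hit[, 1]), post = as.integer(hit[, 2]),
      excitatory = exc[hit[, 1]],
      uS = rep(0, nrow(hit)), xS = rep(1, nrow(hit)))
}
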