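# Independent oracles (plain-R, brute force) and small shared fixtures.

# Brute-force sample entropy: direct O(N^2) template counting, Chebyshev
# distance, self-matches excluded.
sampenOracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nTemp <- n - m
  A <- 0; B <- 0
  for (i in 1:(nTemp - 1)) {
    for (j in (i + 1):nTemp) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B, sampen = if (B > 0 && A > 0) -log(A / B) else NA_real_)
}

# Plug-in transfer entropy from symbol sequences via contingency tables.
teOracle <- function(xb, yb, k = 3) {
  N <- length(yb) - 1
  a <- yb[-1]; b <- yb[-length(yb)]; cc <- xb[-length(xb)]
  te <- 0
  for (ai in 0:(k - 1)) for (bi in 0:(k - 1)) for (ci in 0:(k - 1)) {
    nabc <- sum(a == ai & b == bi & cc == ci)
    if (nabc == 0) next
    nab <- sum(a == ai & b == bi)
    nbc <- sum(b == bi & cc == ci)
    nb <- sum(b == bi)
    te <- te + nabc / N * log(nabc * nb / (nab * nbc))
  }
  max(te, 0)
}

# False-nearest-neighbor fraction, plain R, all vectors, for small traces.
fnnOracle <- function(x, delay, d, rtol = 10, atol = 2) {
  n <- length(x)
  last <- n - d * delay
  sdx <- sd(x)
  emb <- sapply(0:(d - 1), function(k) x[(1:last) + k * delay])
  if (d == 1) emb <- matrix(emb, ncol = 1)
  extra <- x[(1:last) + d * delay]
  nFalse <- 0
  for (i in 1:last) {
    d2 <- rowSums((emb - matrix(emb[i, ], last, d, byrow = TRUE))^2)
    d2[i] <- Inf
    j <- which.min(d2)
    rd <- sqrt(d2[j])
    ex <- abs(extra[i] - extra[j])
    isFalse <- if (rd == 0) ex > 0 else
      (ex / rd > rtol) || (sqrt(rd^2 + ex^2) / sdx > atol)
    nFalse <- nFalse + isFalse
  }
  nFalse / last
}

# Assemble a SimulationResult by hand (for feature-level tests).
fakeResult <- function(traces, spikes = NULL, gridShape = c(2, 2),
                       durationMs = ncol(traces) * 0.1, dt = 0.1,
                       label = "healthy", seed = 1L) {
  n <- prod(gridShape)
  geom <- buildGeometry(1, nExc = n - 1, nInh = 1, gridShape = gridShape)
  if (is.null(spikes))
    spikes <- apply(traces, 1, function(tr) detectAps(tr, dt)$onset,
                    simplify = FALSE)
  new("SimulationResult", traces = traces, spikes = spikes,
      geometry = geom, label = label, seed = seed, dt = dt,
      durationMs = durationMs)
}

# Reduced cohort shared by the statistical acceptance checks; built once per
# test run.
.cohortCache <- new.env(parent = emptyenv())
reducedCohort <- function() {
  if (is.null(.cohortCache$cohort)) {
    .cohortCache$cohort <- runCohort(reducedCohortSpec(masterSeed = 7))
  }
  .cohortCache$cohort
}
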