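test_that("geometry places one neuron per electrode with stated composition", {
  g <- buildGeometry(seed = 1)
  expect_equal(nrow(positions(g)), 200)
  expect_equal(sum(isExcitatory(g)), 132)
  expect_equal(sum(!isExcitatory(g)), 68)
  expect_true(all(areas(g) >= 10000 & areas(g) <= 30000))
  expect_true(all(positions(g)[, 1] >= 0 & positions(g)[, 1] <= 190))
  expect_true(all(positions(g)[, 2] >= 0 & positions(g)[, 2] <= 90))
  # every lattice site occupied exactly once
  expect_equal(nrow(unique(positions(g))), 200)
  # deterministic given seed; different seeds differ
  g2 <- buildGeometry(seed = 1)
  expect_identical(areas(g), areas(g2))
  expect_identical(isExcitatory(g), isExcitatory(g2))
  g3 <- buildGeometry(seed = 2)
  expect_false(identical(areas(g), areas(g3)))
  expect_error(buildGeometry(1, nExc = 100, nInh = 68),
               "must equal the number of lattice sites")
})

test_that("connection probability is the presynaptic Gaussian profile", {
  syn <- synapseParams()
  expect_equal(connectionProbability(0, syn, TRUE), 0.83)
  expect_equal(connectionProbability(0, syn, FALSE), 0.41)
  expect_equal(connectionProbability(15.5, syn, TRUE), 0.83 * exp(-0.5))
  expect_lt(connectionProbability(500, syn, TRUE), 1e-200)
  g <- buildGeometry(1, nExc = 13, nInh = 7, gridShape = c(5, 4))
  st <- connectNetwork(g, syn, seed = 3)
  expect_true(all(st@pre != st@post))
  expect_true(all(st@uS == 0) && all(st@xS == 1))
  expect_identical(st@excitatory, isExcitatory(g)[st@pre])
  st2 <- connectNetwork(g, syn, seed = 3)
  expect_identical(st@pre, st2@pre)
  expect_identical(st@post, st2@post)
})

test_that("empirical connection rate at fixed distance matches the profile", {
  # many independent draws of the 10-um-neighbor edge probability
  syn <- synapseParams()
  g <- buildGeometry(1, nExc = 2, nInh = 0, gridShape = c(2, 1))
  p <- connectionProbability(10, syn, TRUE)
  hits <- vapply(1:400, function(s) {
    length(connectNetwork(g, syn, seed = s)@pre)
  }, numeric(1))
  # 800 Bernoulli draws (two directed pairs per seed)
  expect_lt(abs(mean(hits) / 2 - p), 4 * sqrt(p * (1 - p) / 800))
})

test_that("disease classes set the resting sodium conductance", {
  hh <- hhParams()
  g <- buildGeometry(1, nExc = 13, nInh = 7, gridShape = c(5, 4))
  expect_equal(effectiveSodiumConductance(100, 0.2, 80), 1680)
  expect_equal(effectiveSodiumConductance(100, 0, 80), 100)
  expect_equal(effectiveSodiumConductance(100, 0.2, 0), 80)
  expect_equal(applyDisease(hh, "healthy", g), rep(100, 20))
  expect_equal(applyDisease(hh, "gof", g), rep(1680, 20))
  lof <- applyDisease(hh, "lof", g)
  expect_equal(lof[isExcitatory(g)], rep(100, 13))
  expect_equal(lof[!isExcitatory(g)], rep(80, 7))
  expect_error(applyDisease(hh, "unknown", g), "unknown disease class")
})

test_that("initial state respects the stated distributions", {
  hh <- hhParams(); syn <- synapseParams()
  g <- buildGeometry(2, nExc = 132, nInh = 68)
  st <- initState(g, hh, syn, seed = 5)
  expect_true(all(st$V >= -65 & st$V <= -63))
  aHat <- areas(g) / 5000
  expect_true(all(st$gNa >= syn@wE * aHat & st$gNa <= 2 * syn@wE * aHat))
  expect_true(all(st$gK >= syn@wI * aHat & st$gK <= 2 * syn@wI * aHat))
  expect_true(all(st$m >= 0 & st$m <= 1))
  expect_true(all(st$n >= 0 & st$n <= 1))
  expect_true(all(st$h >= 0 & st$h <= 1))
  # steady-state gating: dy/dt = alpha (1 - y) - beta y = 0 at the initial V
  r <- cpp_gating_rates(st$V[1], hh@VT)
  expect_equal(r[["alpha_m"]] * (1 - st$m[1]) - r[["beta_m"]] * st$m[1], 0,
               tolerance = 1e-12)
  expect_equal(r[["alpha_h"]] * (1 - st$h[1]) - r[["beta_h"]] * st$h[1], 0,
               tolerance = 1e-12)
})

test_that("release event and inter-event decay follow the stated maps", {
  ev <- synapseEvent(0, 1, 0.6)
  expect_equal(ev$uS, 0.6)
  expect_equal(ev$rS, 0.6)
  expect_equal(ev$xS, 0.4)
  ev2 <- synapseEvent(1, 0, 0.6)
  expect_equal(ev2$rS, 0)
  expect_equal(ev2$xS, 0)
  # arbitrary states stay in [0, 1]
  set.seed(1)
  for (k in 1:50) {
    u <- runif(1); x <- runif(1)
    e <- synapseEvent(u, x, 0.6)
    expect_true(e$uS >= 0 && e$uS <= 1 && e$xS >= 0 && e$xS <= 1 &&
                  e$rS >= 0 && e$rS <= 1)
  }
  syn <- synapseParams()
  d <- synapseDecay(0.6, 0.4, gapMs = 100, syn)
  expect_equal(d$uS, 0.6 * exp(-3.33 * 0.1))
  expect_equal(d$xS, 1 - 0.6 * exp(-2 * 0.1))
})

test_that("leak-only integration matches the analytic exponential exactly", {
  hh <- hhParams(gNa0 = 0, gK0 = 0)
  syn <- synapseParams()
  g <- buildGeometry(1, nExc = 2, nInh = 0, gridShape = c(2, 1))
  edges <- new("SynapseTable", pre = integer(0), post = integer(0),
               excitatory = logical(0), uS = numeric(0), xS = numeric(0))
  V0 <- c(-64, -63.5)
  gate <- vapply(V0, cpp_gating_steady, numeric(3), VT = hh@VT)
  state <- list(V = V0, m = gate["m", ], n = gate["n", ], h = gate["h", ],
                gNa = c(0, 0), gK = c(0, 0))
  res <- integrateNetwork(state, edges, hh, syn, g, durationMs = 50)
  tt <- seq_len(ncol(voltageTraces(res))) * hh@dt
  for (i in 1:2) {
    analytic <- hh@El + (V0[i] - hh@El) * exp(-hh@gl * tt / hh@Cm)
    expect_equal(voltageTraces(res)[i, ], analytic, tolerance = 1e-13)
  }
  expect_equal(lengths(spikeTimes(res)), c(0L, 0L))
})

test_that("a sustained suprathreshold excursion is counted as one spike", {
  res <- makeFixture("single_spiker", seed = 2, durationMs = 300)
  tr <- voltageTraces(res)[1, ]
  spk <- spikeTimes(res)[[1]]
  expect_gt(length(spk), 1)
  # refractory rule: spikes == maximal above-threshold runs that start
  # after t = 0 (initial V is below threshold)
  expect_equal(length(spk), nrow(detectAps(tr, dt = 0.1)))
  expect_true(all(diff(spk) > 0))
  # every inter-spike interval contains a subthreshold excursion
  steps <- round(spk / 0.1)
  for (k in seq_len(length(spk) - 1))
    expect_true(any(tr[steps[k]:steps[k + 1]] < -63))
})

test_that("coarse integration agrees with a fine-step reference solver", {
  hh <- hhParams()
  syn <- synapseParams()
  # one neuron under constant suprathreshold conductance drive
  gDrive <- 900
  g <- buildGeometry(1, nExc = 2, nInh = 0, gridShape = c(2, 1))
  edges <- new("SynapseTable", pre = integer(0), post = integer(0),
               excitatory = logical(0), uS = numeric(0), xS = numeric(0))
  V0 <- -64
  gate <- cpp_gating_steady(V0, hh@VT)
  state <- list(V = c(V0, V0), m = rep(gate[["m"]], 2),
                n = rep(gate[["n"]], 2), h = rep(gate[["h"]], 2),
                gNa = c(gDrive, 0), gK = c(hh@gK0, 0))
  res <- integrateNetwork(state, edges, hh, syn, g, durationMs = 300,
                          gNaRest = c(gDrive, 0))
  nCoarse <- length(spikeTimes(res)[[1]])
  expect_gt(nCoarse, 2)

  deriv <- function(t, y, p) {
    r <- cpp_gating_rates(y[1], hh@VT)
    gNaEff <- gDrive * y[2]^3 * y[4]
    gKEff <- hh@gK0 * y[3]^4
    dV <- (hh@gl * (hh@El - y[1]) + gNaEff * (hh@ENa - y[1]) +
             gKEff * (hh@EK - y[1])) / hh@Cm
    list(c(dV,
           r[["alpha_m"]] * (1 - y[2]) - r[["beta_m"]] * y[2],
           r[["alpha_n"]] * (1 - y[3]) - r[["beta_n"]] * y[3],
           r[["alpha_h"]] * (1 - y[4]) - r[["beta_h"]] * y[4]))
  }
  fine <- deSolve::rk4(c(V = V0, m = gate[["m"]], n = gate[["n"]],
                         h = gate[["h"]]),
                       times = seq(0, 300, by = 0.001), deriv, parms = NULL)
  vf <- fine[, "V"]
  nFine <- sum(vf[-1] >= -63 & vf[-length(vf)] < -63)
  expect_lte(abs(nCoarse - nFine), 1)
})

test_that("gating variables and synapse states stay in bounds over a run", {
  res <- makeFixture("tiny_network", seed = 3, durationMs = 1000,
                     label = "gof")
  expect_true(all(is.finite(voltageTraces(res))))
  # voltages bounded by the Nernst window
  expect_true(all(voltageTraces(res) > -90 & voltageTraces(res) < 50))
})

test_that("unconnected resting networks are silent for a full second", {
  # pure leak: monotone relaxation onto the leak potential
  res <- makeFixture("leak_only", seed = 4, durationMs = 1000)
  expect_equal(sum(lengths(spikeTimes(res))), 0)
  tr <- voltageTraces(res)
  expect_true(all(diff(t(tr)) <= 0))
  expect_true(all(abs(tr[, ncol(tr)] - (-65)) < 0.1))

  # healthy resting conductances, subthreshold start, no synapses: no spikes
  hh <- hhParams()
  syn <- synapseParams()
  g <- buildGeometry(4, nExc = 3, nInh = 1, gridShape = c(2, 2))
  edges <- new("SynapseTable", pre = integer(0), post = integer(0),
               excitatory = logical(0), uS = numeric(0), xS = numeric(0))
  set.seed(4)
  V0 <- runif(4, -65, -63)
  gate <- vapply(V0, epinetml:::cpp_gating_steady, numeric(3), VT = hh@VT)
  state <- list(V = V0, m = gate["m", ], n = gate["n", ], h = gate["h", ],
                gNa = rep(hh@gNa0, 4), gK = rep(hh@gK0, 4))
  quiet <- integrateNetwork(state, edges, hh, syn, g, durationMs = 1000)
  expect_equal(sum(lengths(spikeTimes(quiet))), 0)
})

test_that("identical seed and parameters give bitwise-identical results", {
  a <- simulateSubject(11, "lof", durationMs = 200, nExc = 13, nInh = 7,
                       gridShape = c(5, 4))
  b <- simulateSubject(11, "lof", durationMs = 200, nExc = 13, nInh = 7,
                       gridShape = c(5, 4))
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_identical(voltageTraces(a), voltageTraces(b))
  c2 <- simulateSubject(12, "lof", durationMs = 200, nExc = 13, nInh = 7,
                        gridShape = c(5, 4))
  expect_false(identical(voltageTraces(a), voltageTraces(c2)))
})

test_that("gain-of-function networks fire more than healthy ones", {
  rates <- sapply(1:10, function(s) {
    h <- makeFixture("tiny_network", seed = s, durationMs = 200,
                     label = "healthy")
    g <- makeFixture("tiny_network", seed = s, durationMs = 200,
                     label = "gof")
    c(healthy = mean(firingRates(h)), gof = mean(firingRates(g)))
  })
  expect_gt(mean(rates["gof", ]), mean(rates["healthy", ]))
})
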