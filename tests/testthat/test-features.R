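test_that("spatial gradient matches finite-difference hand calculations", {
  g <- buildGeometry(1, nExc = 13, nInh = 7, gridShape = c(5, 4))
  expect_equal(spatialGradient(rep(3.7, 20), g), rep(0, 20))

  # linear ramp v = 0.5 * x -> gx = 0.5 everywhere (one-sided edges agree
  # with the interior for a linear field)
  ramp <- 0.5 * positions(g)[, 1]
  expect_equal(spatialGradient(ramp, g), rep(0.5, 20))

  # 3 x 3 patch with hand-computed central differences at the center
  g3 <- buildGeometry(1, nExc = 8, nInh = 1, gridShape = c(3, 3))
  pos <- positions(g3)
  vals <- c(1, 2, 4,
            3, 5, 8,
            6, 9, 13)  # row-major over y = 0, 10, 20
  idx <- order(pos[, 2], pos[, 1])
  v <- numeric(9)
  v[idx] <- vals
  grad <- spatialGradient(v, g3)
  center <- which(pos[, 1] == 10 & pos[, 2] == 10)
  gx <- (8 - 3) / 20   # central difference in x at the center
  gy <- (9 - 2) / 20   # central difference in y
  expect_equal(grad[center], sqrt(gx^2 + gy^2))
  corner <- which(pos[, 1] == 0 & pos[, 2] == 0)
  expect_equal(grad[corner], sqrt(((2 - 1) / 10)^2 + ((3 - 1) / 10)^2))
  expect_error(spatialGradient(1:5, g3), "one value per neuron")
})

test_that("frequency features are rates and ramp gradients", {
  tr <- matrix(-70, 4, 10000)  # 1 s at dt 0.1: silent traces
  spikes7 <- list(seq(100, 700, by = 100), numeric(0), numeric(0),
                  numeric(0))
  res <- fakeResult(tr, spikes = spikes7, gridShape = c(2, 2),
                    durationMs = 1000)
  f <- frequencyFeatures(res)
  expect_equal(unname(f["freq_max"]), 7)
  expect_equal(unname(f["freq_mean"]), 7 / 4)

  silent <- fakeResult(tr, spikes = rep(list(numeric(0)), 4),
                       gridShape = c(2, 2), durationMs = 1000)
  expect_equal(unname(frequencyFeatures(silent)), rep(0, 4))

  # rates forming a linear ramp in x: mean gradient equals the slope
  g <- buildGeometry(1, nExc = 13, nInh = 7, gridShape = c(5, 4))
  rates <- 0.2 * positions(g)[, 1]
  spikes <- lapply(rates, function(r) if (r > 0) seq_len(r * 2) / 2 else
    numeric(0))
  res2 <- new("SimulationResult", traces = matrix(numeric(0), 0, 0),
              spikes = spikes, geometry = g, label = "healthy", seed = 1L,
              dt = 0.1, durationMs = 2000)
  f2 <- frequencyFeatures(res2)
  expect_equal(unname(f2["freq_grad_mean"]), 0.2)
})

test_that("AP detection finds maximal above-threshold runs", {
  tr <- rep(-70, 200)
  tr[101:125] <- -50  # 25 samples = 2.5 ms
  ev <- detectAps(tr, dt = 0.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 2.5)
  expect_equal(ev$onset, 10.0)

  expect_equal(nrow(detectAps(rep(-70, 100), dt = 0.1)), 0)

  tr2 <- rep(-70, 100)
  tr2[10:19] <- -60
  tr2[21:30] <- -60  # one subthreshold sample between runs
  expect_equal(nrow(detectAps(tr2, dt = 0.1)), 2)
})

test_that("waveform scalars implement the 50% PDS/IIS rules", {
  dt <- 0.1
  n <- 20000  # 2 s
  mk <- function(events) {
    tr <- rep(-70, n)
    for (e in events) tr[e[1]:(e[1] + e[2] - 1)] <- -50
    tr
  }
  # neuron 1: twenty 2.0 ms APs; neuron 2: one 3.5 ms (PDS), one isolated
  # 0.9 ms (IIS), one 2.5 ms (neither); neurons 3-4 silent
  ev1 <- lapply(seq(1000, 1000 + 19 * 900, by = 900), function(s) c(s, 20))
  ev2 <- list(c(1000, 35), c(8000, 9), c(15000, 25))
  traces <- rbind(mk(ev1), mk(ev2), rep(-70, n), rep(-70, n))
  res <- fakeResult(traces, gridShape = c(2, 2), durationMs = n * dt)
  sc <- waveformScalars(res)
  refDur <- mean(c(rep(2.0, 20), 3.5, 0.9, 2.5))
  expect_gt(3.5, 1.5 * refDur)   # the construction really forces a PDS
  expect_lt(0.9, 0.5 * refDur)   # ... and an IIS
  expect_equal(unname(sc["pds_rate", 2]), 1 / 2)   # one PDS in 2 s
  expect_equal(unname(sc["pds_dur", 2]), 3.5)
  expect_equal(unname(sc["iis_rate", 2]), 1 / 2)
  expect_equal(unname(sc["iis_dur", 2]), 0.9)
  expect_equal(unname(sc["pds_rate", 1]), 0)
  expect_equal(unname(sc["iis_rate", 1]), 0)  # 2.0 ms APs are neither
  expect_equal(unname(sc["pds_rate", 3]), 0)
  expect_equal(unname(sc["line_length", 3]), 0)  # constant trace

  # sawtooth with total variation 120 mV
  saw <- rep(-70, 1000)
  saw[1:13] <- -70 + c(0:6 * 10, 5:0 * 10)
  expect_equal(epinetml:::cpp_line_length(saw), 120)
})

test_that("IIS isolation window excludes burst members", {
  dt <- 0.1
  n <- 20000
  tr <- rep(-70, n)
  # reference APs: many 2 ms events in neuron 1
  for (s in seq(1000, 1000 + 19 * 900, by = 900)) tr[s:(s + 19)] <- -50
  # neuron 2: two short APs 10 ms apart (burst, not isolated), one isolated
  tr2 <- rep(-70, n)
  tr2[5000:5008] <- -50
  tr2[5100:5108] <- -50   # 10 ms later
  tr2[15000:15008] <- -50 # isolated short AP
  traces <- rbind(tr, tr2, rep(-70, n), rep(-70, n))
  res <- fakeResult(traces, gridShape = c(2, 2), durationMs = n * dt)
  sc <- waveformScalars(res)
  expect_equal(unname(sc["iis_rate", 2]), 1 / 2)  # only the isolated one counts
})

test_that("sample entropy matches the brute-force template count", {
  set.seed(42)
  x <- cumsum(rnorm(300))
  orc <- sampenOracle(x, m = 2, r = 0.2 * sd(x))
  cnt <- epinetml:::cpp_sampen_counts(x, 2L, 0.2 * sd(x))
  expect_identical(unname(cnt[["A"]]), unname(orc[["A"]]))
  expect_identical(unname(cnt[["B"]]), unname(orc[["B"]]))
  expect_equal(sampleEntropy(x), unname(orc[["sampen"]]), tolerance = 1e-12)

  # iid Gaussian, m = 2, r = 0.2 sd
  set.seed(7)
  y <- rnorm(800)
  expect_equal(sampleEntropy(y), unname(sampenOracle(y)[["sampen"]]),
               tolerance = 1e-12)
})

test_that("multiscale entropy behaves at its fixed points", {
  expect_equal(sampleEntropy(rep(5, 100)), 0)
  cst <- multiscaleEntropy(rep(5, 200), scales = 1:5)
  expect_equal(cst$sampen, rep(0, 5))
  expect_equal(cst$integral, 0)

  set.seed(1)
  x <- rnorm(2000)
  mse <- multiscaleEntropy(x, scales = 1:4)
  expect_equal(mse$sampen[1], sampleEntropy(x, m = 2, r = 0.2 * sd(x)))
  # coarse-graining at scale 2 is pairwise means
  cg <- epinetml:::cpp_coarse_grain(x, 2L)
  expect_equal(cg, colMeans(matrix(x[1:2000], 2)))

  # offset invariance with r tied to the SD
  expect_equal(sampleEntropy(x + 100), sampleEntropy(x))
})

test_that("embedding dimension separates signal classes", {
  # clean sine, sampled well above Nyquist
  tt <- seq(0, 60 * pi, length.out = 3000)
  sine <- sin(tt)
  med <- minEmbeddingDim(sine, delay = 25, maxDim = 6, maxVectors = 400)
  expect_equal(med, 2L)
  # agreement with the plain-R FNN oracle on a small trace
  short <- sine[1:400]
  fr1 <- fnnOracle(short, delay = 25, d = 1)
  fr2 <- fnnOracle(short, delay = 25, d = 2)
  expect_gt(fr1, 0.01)
  expect_lt(fr2, 0.01)
  expect_equal(minEmbeddingDim(short, delay = 25, maxDim = 6,
                               maxVectors = 400), 2L)

  expect_equal(minEmbeddingDim(rep(1, 1000)), 1L)

  set.seed(3)
  noise <- runif(2000)
  expect_equal(minEmbeddingDim(noise, delay = 2, maxDim = 5,
                               maxVectors = 300), 5L)

  # offset invariance
  expect_equal(minEmbeddingDim(sine + 10, delay = 25, maxDim = 6,
                               maxVectors = 400), 2L)
  expect_error(minEmbeddingDim(rnorm(100), delay = 500), "too short")
})

test_that("transfer entropy matches its oracle and detects coupling", {
  set.seed(11)
  xb <- sample(0:2, 400, replace = TRUE)
  yb <- sample(0:2, 400, replace = TRUE)
  expect_equal(epinetml:::cpp_transfer_entropy(xb, yb, 3L),
               teOracle(xb, yb), tolerance = 1e-12)

  # independent pairs at n = 10,000: small (estimator bias bound)
  set.seed(12)
  vals <- replicate(5, transferEntropy(rnorm(10000), rnorm(10000)))
  expect_true(all(vals >= 0))
  expect_true(all(vals < 5e-3))

  # deterministic lag-1 coupling forces information transfer
  set.seed(13)
  x <- cumsum(rnorm(5000))
  y <- c(0, x[-5000])
  expect_gt(transferEntropy(x, y), 5e-5)

  # a series with itself: own past already carries everything
  expect_equal(transferEntropy(x, x), 0)
  expect_error(transferEntropy(1:5, 1:4), "lengths differ")
})

test_that("frequency bands follow the stated ranges", {
  expect_equal(as.character(frequencyBand(c(0, 10, 12.5, 29, 30, 79, 80))),
               c("alpha", "alpha", "beta", "beta", "gamma", "gamma", "none"))
})

test_that("TE connectivity features count outgoing edges per band", {
  # constant traces: TE identically zero, empty graph, all features 0
  tr <- matrix(-65, 4, 500)
  res <- fakeResult(tr, spikes = rep(list(numeric(0)), 4),
                    gridShape = c(2, 2), durationMs = 50)
  tc <- teConnectivityFeatures(res)
  expect_true(all(tc$te == 0))
  expect_false(any(tc$adjacency))
  expect_equal(unname(tc$features), rep(0, 28))
  expect_equal(names(tc$features)[1], "te_alpha_mean")

  # deterministic coupling 1 -> 2 with known origin band
  set.seed(5)
  n <- 4000
  src <- cumsum(rnorm(n))
  traces <- rbind(src, c(0, src[-n]), rnorm(n), rnorm(n))
  spikes <- list(seq(10, 100, by = 10), numeric(0), numeric(0), numeric(0))
  res2 <- fakeResult(traces, spikes = spikes, gridShape = c(2, 2),
                     durationMs = 400)  # origin rate 10/0.4s = 25 Hz: beta
  tc2 <- teConnectivityFeatures(res2)
  expect_true(tc2$adjacency[1, 2])
  expect_equal(unname(tc2$features["te_beta_total"]),
               sum(tc2$adjacency[1, ]))
  expect_gte(unname(tc2$features["te_all_total"]),
             unname(tc2$features["te_beta_total"]))
})

test_that("the assembled panel has 92 named features in fixed blocks", {
  res <- makeFixture("tiny_network", seed = 2, durationMs = 200,
                     label = "gof")
  fv <- extractFeatures(res, mseScales = 1:5, medDelay = 100)
  expect_length(fv, 92)
  expect_identical(names(fv), featureNames())
  expect_true(all(is.finite(fv)))
  expect_equal(unname(featureBlockSizes()), c(4L, 6L, 18L, 36L, 28L))
  expect_equal(sum(featureBlockSizes()), 92L)
  # deterministic: same input, same vector
  fv2 <- extractFeatures(res, mseScales = 1:5, medDelay = 100)
  expect_identical(fv, fv2)
})
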