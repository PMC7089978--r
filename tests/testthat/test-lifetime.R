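# TCSPC decay reconvolution analysis

delta_irf <- function() histogramIRF(c(1, rep(0, 1562)), channelWidth = 16)

test_that("a delta IRF reproduces the pure wrapped exponential", {
  m <- reconvolveModel(100, 4.0, delta_irf(), 16, 1563)
  tc <- (seq_len(1563) - 0.5) * 16
  period <- 16 * 1563
  pure <- 100 * exp(-tc / 4000) / (1 - exp(-period / 4000))
  expect_equal(m, pure, tolerance = 1e-10)
})

test_that("reconvolution conserves total intensity (unit kernel)", {
  irf <- gaussianIRF(110, center = 1000)
  m <- reconvolveModel(c(50, 20), c(0.5, 3.0), irf, 16, 1563)
  pure <- reconvolveModel(c(50, 20), c(0.5, 3.0), delta_irf(), 16, 1563)
  expect_equal(sum(m), sum(pure), tolerance = 1e-9)
})

test_that("shifting the IRF shifts the model by the same amount", {
  shift_ch <- 25
  m1 <- reconvolveModel(10, 2.5, gaussianIRF(110, center = 1000), 16, 1563)
  m2 <- reconvolveModel(10, 2.5,
                        gaussianIRF(110, center = 1000 + shift_ch * 16),
                        16, 1563)
  rolled <- c(tail(m1, shift_ch), head(m1, -shift_ch))
  expect_equal(m2, rolled, tolerance = 1e-8)
})

test_that("the model tail slope equals -1/tau on a log plot", {
  irf <- gaussianIRF(110, center = 1000)
  m <- reconvolveModel(1000, 3.0, irf, 16, 1563)
  tc <- (seq_len(1563) - 0.5) * 16
  sel <- tc > 3000 & tc < 15000  # far from edge and from the wrap
  co <- coef(lm(log(m[sel]) ~ tc[sel]))
  expect_equal(unname(co[2]), -1 / 3000, tolerance = 0.01)
})

test_that("intensity-weighted average lifetime follows its formula", {
  expect_equal(intensityWeightedLifetime(1, 1.4), 1.4)
  expect_equal(intensityWeightedLifetime(c(0.5, 0.5), c(1, 3)), 2.5)
  expect_error(intensityWeightedLifetime(numeric(0), numeric(0)), "no comp")
  # invariant to amplitude rescaling; bounded by component lifetimes
  withr::local_seed(2)
  for (i in 1:25) {
    a <- runif(3); tau <- sort(runif(3, 0.2, 5))
    v <- intensityWeightedLifetime(a, tau)
    expect_equal(intensityWeightedLifetime(17 * a, tau), v)
    expect_gte(v, min(tau))
    expect_lte(v, max(tau))
  }
})

test_that("lifetime fold change reproduces the benchmark worked examples", {
  expect_equal(lifetimeFoldChange(3.5, 1.78), 1.966, tolerance = 1e-3)
  expect_equal(lifetimeFoldChange(4.0, 1.41), 2.837, tolerance = 1e-3)
  expect_equal(lifetimeFoldChange(2, 2), 1)
  expect_error(lifetimeFoldChange(0, 1), "> 0")
  expect_error(lifetimeFoldChange(1, -2), "> 0")
})

test_that("noiseless model counts are recovered essentially exactly", {
  irf <- gaussianIRF(110, center = 1000)
  m <- reconvolveModel(5000, 4.0, irf, 16, 1563)
  h <- new("TCSPCHistogram", channelWidth = 16, counts = round(m * 20),
           syncPeriod = 25000)
  f <- fitDecay(h, irf, nExp = 1)
  expect_equal(f@lifetimes, 4.0, tolerance = 1e-3)
})

test_that("single-exponential photon data is recovered within 2%", {
  irf <- gaussianIRF(110, center = 1000)
  tr <- simulateDecayPhotons(1e5, 1, 4.0, irf, seed = 13)
  f <- fitDecay(buildTCSPCHistogram(tr, 16), irf, nExp = 1)
  expect_true(f@converged)
  expect_equal(f@lifetimes, 4.0, tolerance = 0.02)
  expect_equal(f@avgLifetime, 4.0, tolerance = 0.02)
  # the 95% photon gate
  cnt <- counts(buildTCSPCHistogram(tr, 16))
  tc0 <- (seq_along(cnt) - 1) * 16
  inside <- sum(cnt[tc0 >= f@gate[1]])
  expect_gte(inside / sum(cnt), 0.95)
})

test_that("biexponential components are recovered within tolerance", {
  irf <- gaussianIRF(110, center = 1000)
  tr <- simulateDecayPhotons(2e5, c(0.7, 0.3), c(0.5, 3.0), irf, seed = 4)
  f <- fitDecay(buildTCSPCHistogram(tr, 16), irf, nExp = 2)
  expect_equal(f@lifetimes[1], 0.5, tolerance = 0.05)
  expect_equal(f@lifetimes[2], 3.0, tolerance = 0.05)
  amp <- f@amplitudes / sum(f@amplitudes)
  expect_lt(abs(amp[1] - 0.7), 0.05)
  expect_lt(abs(amp[2] - 0.3), 0.05)
})

test_that("an ultrafast scatter spike is excluded from the average", {
  irf <- gaussianIRF(110, center = 1000)
  clean <- fitDecay(buildTCSPCHistogram(
    simulateDecayPhotons(1e5, 1, 4.0, irf, seed = 3), 16), irf, nExp = 1)
  spiked <- fitDecay(buildTCSPCHistogram(
    simulateDecayPhotons(1e5, 1, 4.0, irf, scatterFraction = 0.12,
                         seed = 3), 16), irf, nExp = 2)
  expect_true(spiked@excluded[1])
  expect_false(spiked@excluded[2])
  expect_lt(spiked@lifetimes[1], 0.02)
  expect_lt(abs(spiked@avgLifetime - clean@avgLifetime) /
              clean@avgLifetime, 0.01)
})

test_that("automatic model order stops when an extra term stops helping", {
  irf <- gaussianIRF(110, center = 1000)
  tr1 <- simulateDecayPhotons(1e5, 1, 4.0, irf, seed = 23)
  f1 <- fitDecay(buildTCSPCHistogram(tr1, 16), irf, nExp = "auto")
  expect_equal(length(f1@lifetimes), 1L)
  tr2 <- simulateDecayPhotons(2e5, c(0.7, 0.3), c(0.5, 3.0), irf, seed = 24)
  f2 <- fitDecay(buildTCSPCHistogram(tr2, 16), irf, nExp = "auto")
  expect_gte(length(f2@lifetimes), 2L)
  expect_equal(f2@avgLifetime,
               intensityWeightedLifetime(c(0.7, 0.3), c(0.5, 3.0)),
               tolerance = 0.05)
})

test_that("a 1.02 ns component is still recovered with the 38 ps IRF", {
  irf <- gaussianIRF(38, center = 800)
  tr <- simulateDecayPhotons(1e5, 1, 1.02, irf, seed = 6)
  f <- fitDecay(buildTCSPCHistogram(tr, 16), irf, nExp = 1)
  expect_equal(f@lifetimes, 1.02, tolerance = 0.05)
})

test_that("sparse histograms are rejected", {
  irf <- gaussianIRF(110, center = 1000)
  tr <- simulateDecayPhotons(500, 1, 4.0, irf, seed = 7)
  expect_error(fitDecay(buildTCSPCHistogram(tr, 16), irf, nExp = 1),
               "1000 photons")
})
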