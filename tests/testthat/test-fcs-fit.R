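# Correlation model and its fit

test_that("model evaluation matches hand-computed values", {
  expect_equal(evalFCSModel(0, fcsParams(N = 4, tauD = 1e-3)), 0.25)
  # at tau = tauD with kappa = 1: (1/2) * (1/sqrt(2))
  expect_equal(evalFCSModel(1e-3, fcsParams(N = 1, tauD = 1e-3)),
               2^-1 * 2^-0.5, tolerance = 1e-12)
  # long-lag limit vanishes
  expect_lt(evalFCSModel(1e4, fcsParams(N = 1, tauD = 1e-3,
                                        Tds = 0.3, tauDs = 5e-6)), 1e-5)
})

test_that("zero-lag amplitude is (1/N) / (1 - Tds)", {
  for (tds in c(0.1, 0.3, 0.5)) {
    p <- fcsParams(N = 2.5, tauD = 2e-4, Tds = tds, tauDs = 5e-6)
    expect_equal(evalFCSModel(0, p), (1 / 2.5) / (1 - tds),
                 tolerance = 1e-12)
  }
})

test_that("the model is non-increasing in lag when blinking is off", {
  tau <- 10^seq(-7, 1, length.out = 400)
  for (td in c(1e-5, 1e-3, 0.1)) {
    g <- evalFCSModel(tau, fcsParams(N = 1, tauD = td))
    expect_true(all(diff(g) <= 1e-15))
  }
})

test_that("parameter validity is enforced", {
  expect_error(fcsParams(N = -1, tauD = 1e-3), "N")
  expect_error(fcsParams(N = 1, tauD = c(1e-3, 1e-3)), "increasing")
  expect_error(fcsParams(N = 1, tauD = 1e-3, Tds = 1), "Tds")
  expect_error(evalFCSModel(-1, fcsParams(N = 1, tauD = 1e-3)), "tau")
})

test_that("fit recovers exact-model parameters to 0.1%", {
  truth <- fcsParams(N = 5, tauD = 1e-3, Tds = 0.2, tauDs = 5e-6)
  cv <- modelCurve(truth)
  fit <- fitFCS(cv, nSpecies = 1)
  expect_true(fit@converged)
  expect_equal(fit@params@N, 5, tolerance = 1e-3)
  expect_equal(fit@params@tauD, 1e-3, tolerance = 1e-3)
  expect_equal(fit@params@Tds, 0.2, tolerance = 1e-3)
  expect_equal(fit@params@tauDs, 5e-6, tolerance = 1e-3)
})

test_that("fit recovers an exact two-species mixture", {
  truth <- fcsParams(N = 0.05, tauD = c(3e-4, 0.15), alpha = c(0.8, 0.2),
                     Tds = 0.2, tauDs = 5e-6)
  cv <- modelCurve(truth, lags = 10^seq(-6, 0.5, length.out = 150))
  fit <- fitFCS(cv, nSpecies = 2, fixed = list(Tds = 0.2, tauDs = 5e-6))
  expect_equal(fit@nSpecies, 2L)
  expect_equal(fit@params@alpha[2], 0.2, tolerance = 0.01)
  expect_equal(fit@params@tauD[1], 3e-4, tolerance = 0.01)
  expect_equal(fit@params@tauD[2], 0.15, tolerance = 0.01)
  expect_equal(fit@params@N, 0.05, tolerance = 0.01)
})

test_that("fit results are invariant to uniform weight rescaling", {
  truth <- fcsParams(N = 2, tauD = 5e-4, Tds = 0.15, tauDs = 3e-6)
  cv <- modelCurve(truth)
  cv@weights <- rep(0.01, length(cv@lags))
  f1 <- fitFCS(cv, nSpecies = 1, weighting = "estimated")
  cv@weights <- cv@weights * 10
  f2 <- fitFCS(cv, nSpecies = 1, weighting = "estimated")
  expect_equal(f1@params@N, f2@params@N, tolerance = 1e-6)
  expect_equal(f1@params@tauD, f2@params@tauD, tolerance = 1e-6)
})

test_that("a second species collapses on single-species truth", {
  truth <- fcsParams(N = 1.5, tauD = 4e-4, Tds = 0.2, tauDs = 5e-6)
  cv <- modelCurve(truth)
  fit <- fitFCS(cv, nSpecies = 2, fixed = list(Tds = 0.2, tauDs = 5e-6))
  expect_equal(fit@nSpecies, 1L)
  expect_equal(unname(stickingFractions(fit)["slow"]), 0)
  auto <- fitFCS(cv, nSpecies = "auto", fixed = list(Tds = 0.2,
                                                     tauDs = 5e-6))
  expect_equal(auto@nSpecies, 1L)
})

test_that("sticking fractions follow the amplitude convention", {
  truth <- fcsParams(N = 0.05, tauD = c(3e-4, 0.15), alpha = c(0.8, 0.2),
                     Tds = 0.2, tauDs = 5e-6)
  cv <- modelCurve(truth, lags = 10^seq(-6, 0.5, length.out = 150))
  fit <- fitFCS(cv, nSpecies = 2, fixed = list(Tds = 0.2, tauDs = 5e-6))
  fr <- stickingFractions(fit)
  expect_equal(unname(fr["fast"]), 80, tolerance = 0.02)
  expect_equal(unname(fr["slow"]), 20, tolerance = 0.02)
  expect_equal(sum(fr), 100)
  fit1 <- fitFCS(modelCurve(fcsParams(N = 1, tauD = 1e-3)), nSpecies = 1)
  expect_equal(stickingFractions(fit1), c(fast = 100, slow = 0))
})

test_that("molecule number and brightness follow the arithmetic contract", {
  cv <- modelCurve(fcsParams(N = 5, tauD = 1e-3), meanRate = 1e4)
  fit <- fitFCS(cv, nSpecies = 1)
  mb <- moleculesAndBrightness(fit, cv)
  expect_equal(mb$N, 5, tolerance = 1e-3)
  expect_equal(mb$brightness, 1e4 / mb$N)
})

test_that("degenerate curves are rejected with clear errors", {
  cv <- new("CorrelationCurve", lags = c(1e-6, 2e-6, 3e-6),
            g = c(1, 0.9, 0.8), weights = rep(NA_real_, 3),
            totalPhotons = 10, meanRate = 1, binWidth = 1e-6)
  expect_error(fitFCS(cv), "too few")
})
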