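# Synthetic photon-stream generator

test_that("identical seed and config give a bit-identical stream", {
  cfg <- quickConfig(duration = 1, seed = 11,
                     adsorptionProbPerContact = defaultStickingProb("none"))
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(macrotimes(a), macrotimes(b))
  expect_identical(microtimes(a), microtimes(b))
  expect_identical(a@labels, b@labels)
  expect_identical(a@metadata$adsorptionEvents, b@metadata$adsorptionEvents)
  cfg2 <- quickConfig(duration = 1, seed = 12,
                      adsorptionProbPerContact = defaultStickingProb("none"))
  c <- simulateExperiment(cfg2)
  expect_false(identical(macrotimes(a), macrotimes(c)))
})

test_that("zero adsorption probability never enters the adsorbed state", {
  cfg <- quickConfig(duration = 1, seed = 2, adsorptionProbPerContact = 0)
  tj <- simulateTrajectories(cfg, recordInterval = 1e-4)
  expect_equal(nrow(tj$events), 0)
  expect_true(all(tj$paths$adsorbed == 0))
  tr <- simulateExperiment(cfg)
  expect_false(any(tr@labels == 1L))
})

test_that("vanishing diffusion keeps molecules in place", {
  cfg <- quickConfig(duration = 0.5, seed = 3,
                     diffusionCoefficient = 1e-10, concentration = 20000)
  tj <- simulateTrajectories(cfg, recordInterval = 0.01)
  p <- tj$paths
  expect_gt(nrow(p), 0)
  for (m in unique(p$molecule)) {
    sel <- p$molecule == m
    expect_lt(max(sd(p$x[sel]), sd(p$y[sel]), sd(p$z[sel]), na.rm = TRUE),
              1)  # nm
  }
})

test_that("adsorbed dwell times average to the configured mean", {
  cfg <- quickConfig(duration = 4, seed = 4,
                     adsorptionProbPerContact = 5e-3,
                     adsorbedDwellMean = 2e-3)
  tj <- simulateTrajectories(cfg, recordInterval = 1)
  dw <- tj$events$dwell
  expect_gt(length(dw), 150)
  se <- sd(dw) / sqrt(length(dw))
  expect_lt(abs(mean(dw) - 2e-3), 3 * se)
})

test_that("immobile bright molecules emit Poisson counts", {
  # flat detection profile and (near) zero diffusion: every resident
  # molecule emits at the configured brightness for the whole acquisition
  cfg <- quickConfig(duration = 2, seed = 6, diffusionCoefficient = 1e-10,
                     axialDecayLength = 1e9, brightnessFree = 1000,
                     darkFraction = 0, backgroundRate = 1e-9,
                     concentration = 1500)
  k <- zmwFCS:::.runKernel(cfg)
  n_mol <- k$n_molecules
  expect_gt(n_mol, 0)
  mu <- n_mol * 1000 * 2
  expect_lt(abs(length(k$t) - mu), 4 * sqrt(mu))
})

test_that("microtimes follow the configured excited-state decay", {
  cfg <- quickConfig(duration = 6, seed = 8, lifetimeFree = 4.0,
                     irf = gaussianIRF(fwhm = 1e-3, center = 0),
                     darkFraction = 0, backgroundRate = 1e-9)
  tr <- simulateExperiment(cfg)
  micro <- microtimes(tr)[tr@labels == 0L]
  expect_gt(length(micro), 5000)
  # closed-form MLE of the wrapped-exponential mean
  p <- 25000
  wrapped_mean <- function(tau) tau - p * exp(-p / tau) / (1 - exp(-p / tau))
  tau_hat <- uniroot(function(tt) wrapped_mean(tt) - mean(micro),
                     c(500, 20000))$root
  se <- 4000 / sqrt(length(micro))
  expect_lt(abs(tau_hat - 4000), 3 * se)
})

test_that("zero brightness and zero background give an empty stream", {
  cfg <- quickConfig(duration = 0.5, seed = 5, brightnessFree = 0,
                     brightnessAdsorbed = 0, backgroundRate = 1e-12)
  tr <- simulateExperiment(cfg)
  expect_equal(nPhotons(tr), 0)
  expect_true(validObject(tr))
})

test_that("photon stream can be generated from recorded trajectories", {
  cfg <- quickConfig(duration = 1, seed = 9)
  tj <- simulateTrajectories(cfg, recordInterval = 2e-5)
  tr <- generatePhotonStream(tj$paths, cfg)
  expect_true(validObject(tr))
  expect_gt(nPhotons(tr), 200)
  expect_true(all(tr@labels %in% c(0L, 1L, 2L)))
  expect_true(all(diff(macrotimes(tr)) >= 0))
  # mean rate consistent with the fused full-resolution pass
  tr2 <- simulateExperiment(cfg)
  expect_lt(abs(nPhotons(tr) - nPhotons(tr2)) /
              max(nPhotons(tr2), 1), 0.5)
})

test_that("long adsorption events appear as >100 ms intensity spikes", {
  cfg <- quickConfig(duration = 20, seed = 13,
                     adsorptionProbPerContact = 4 * defaultStickingProb("none"))
  tr <- simulateExperiment(cfg)
  it <- binIntensity(tr, 0.01)
  sp <- detectSpikes(it, minDuration = 0.1)
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$duration_s > 0.1))
})

test_that("configuration files round trip through YAML and JSON", {
  cfg <- simConfig(concentration = 400, adsorptionProbPerContact = 1e-5,
                   rngSeed = 99)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    writeSimConfig(cfg, path)
    cfg2 <- readSimConfig(path)
    expect_equal(cfg2@concentration, 400)
    expect_equal(cfg2@adsorptionProbPerContact, 1e-5)
    expect_equal(cfg2@rngSeed, 99)
    expect_equal(cfg2@irf@fwhm, cfg@irf@fwhm)
  }
})

test_that("config validity rejects unphysical values", {
  expect_error(simConfig(darkFraction = 1.2), "darkFraction")
  expect_error(simConfig(adsorptionProbPerContact = 2), "adsorption")
  expect_error(simConfig(duration = -1), "> 0")
  expect_error(simConfig(diffusionCoefficient = 0), "> 0")
})

test_that("ground-truth expectations are finite and scale sensibly", {
  cfg <- simConfig()
  expect_gt(expectedMoleculeNumber(cfg), 0)
  # doubling concentration doubles N exactly (open-system occupancy)
  cfg2 <- simConfig(concentration = 200)
  expect_equal(expectedMoleculeNumber(cfg2),
               2 * expectedMoleculeNumber(cfg))
  # slower diffusion lengthens the expected diffusion time
  slow <- simConfig(diffusionCoefficient = 10)
  expect_gt(expectedDiffusionTime(slow), expectedDiffusionTime(cfg))
  expect_equal(expectedDiffusionTime(slow) / expectedDiffusionTime(cfg), 3,
               tolerance = 0.02)  # pure diffusive time scaling 1/D
})
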