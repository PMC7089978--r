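# Shared fixtures: all synthetic, generated in code at test time.

# a short acquisition with sensible physics, cheap enough for unit tests
quickConfig <- function(duration = 2, seed = 1, ...) {
  simConfig(duration = duration, rngSeed = seed, ...)
}

# bursty correlated count trace: Poisson counts driven by a smoothly
# varying (AR(1)) intensity, correlation time ~ `corBins` bins
burstTrace <- function(nBins = 1e4, corBins = 50, meanCounts = 5,
                      amplitude = 0.8, binWidth = 1e-3) {
  rho <- exp(-1 / corBins)
  z <- numeric(nBins)
  z[1] <- rnorm(1)
  innov <- rnorm(nBins - 1)
  for (i in 2:nBins) z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * innov[i - 1]
  lambda <- meanCounts * exp(amplitude * z - amplitude^2 / 2)
  new("IntensityTrace", binWidth = binWidth,
      counts = as.numeric(rpois(nBins, lambda)), originTime = 0)
}

# simulate -> bin -> correlate -> background-correct, the standard path
simFCSCurve <- function(config, binWidth = 1e-6, maxLag = 2) {
  tr <- simulateExperiment(config)
  it <- binIntensity(tr, binWidth)
  cv <- correlateMultitau(it, maxLag = maxLag)
  if (config@backgroundRate > 0)
    cv <- correctBackground(cv, config@backgroundRate)
  list(trace = tr, curve = cv)
}

# noiseless correlation curve evaluated from model parameters
modelCurve <- function(params, lags = 10^seq(-6, 0, length.out = 120),
                       meanRate = 1e3) {
  new("CorrelationCurve", lags = lags, g = evalFCSModel(lags, params),
      weights = rep(NA_real_, length(lags)), totalPhotons = 1e5,
      meanRate = meanRate, binWidth = lags[1])
}
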