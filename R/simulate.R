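# Synthetic photon-stream generator: configuration, trajectory simulation,
# photon emission, and the closed-form expectations used as ground truth in
# parameter-recovery tests.

# Avogadro-derived conversion: 1 nM = 6.02214e-10 molecules / nm^3
.NM_PER_NM3 <- 6.02214076e-10

#' Build a simulation configuration
#'
#' Defaults reproduce the benchmark acquisition conditions: a 110 nm
#' diameter aperture in a 100 nm metal film, evanescent detection profile
#' with 30 nm decay length, 100 nM labelled double-stranded DNA
#' (D = 30 um^2/s for a 51 bp duplex), 40 MHz sync rate, 60 s acquisition.
#' Sticking is off by default (`adsorptionProbPerContact = 0`); see
#' [defaultStickingProb()] for the calibrated per-contact probability that
#' realises the unpassivated-surface regime (~20% slow-component amplitude).
#'
#' @param apertureDiameter,apertureHeight,reservoirHeight,axialDecayLength
#'   geometry, nm.
#' @param diffusionCoefficient um^2/s.
#' @param concentration nM.
#' @param brightnessFree,brightnessAdsorbed counts/s per molecule at the
#'   detection profile maximum. The adsorbed brightness default is ~1/3 of
#'   the free one, consistent with quenching near the metal walls.
#' @param darkFraction,darkLifetime blinking parameters T_ds and tau_ds (s).
#' @param adsorptionProbPerContact probability of adsorbing on wall contact.
#' @param adsorbedDwellMean mean adsorbed dwell time, s.
#' @param lifetimeFree,lifetimeAdsorbed excited-state lifetimes, ns.
#' @param irf an [IRFModel-class]; default Gaussian FWHM 110 ps (red path).
#' @param syncRate Hz. @param duration s. @param backgroundRate counts/s.
#' @param rngSeed integer.
#' @return a validated [SimulationConfig-class]
#' @export
simConfig <- function(apertureDiameter = 110, apertureHeight = 100,
                      reservoirHeight = 150, axialDecayLength = 30,
                      diffusionCoefficient = 30, concentration = 100,
                      brightnessFree = 1e5, brightnessAdsorbed = 3.3e4,
                      darkFraction = 0.2, darkLifetime = 5e-6,
                      adsorptionProbPerContact = 0,
                      adsorbedDwellMean = 0.15,
                      lifetimeFree = 1.74, lifetimeAdsorbed = 1.0,
                      irf = gaussianIRF(110), syncRate = 4e7, duration = 60,
                      backgroundRate = 200, rngSeed = 1) {
  new("SimulationConfig",
      apertureDiameter = apertureDiameter, apertureHeight = apertureHeight,
      reservoirHeight = reservoirHeight,
      axialDecayLength = axialDecayLength,
      diffusionCoefficient = diffusionCoefficient,
      concentration = concentration, brightnessFree = brightnessFree,
      brightnessAdsorbed = brightnessAdsorbed, darkFraction = darkFraction,
      darkLifetime = darkLifetime,
      adsorptionProbPerContact = adsorptionProbPerContact,
      adsorbedDwellMean = adsorbedDwellMean, lifetimeFree = lifetimeFree,
      lifetimeAdsorbed = lifetimeAdsorbed, irf = irf, syncRate = syncRate,
      duration = duration, backgroundRate = backgroundRate,
      rngSeed = rngSeed)
}

# geometry helpers ---------------------------------------------------------

.boxHeight <- function(config) config@apertureHeight + config@reservoirHeight
.apertureArea <- function(config) pi * (config@apertureDiameter / 2)^2

# mean occupancy of the simulated box (the top boundary is a bath, so the
# occupancy is Poisson with exactly this mean)
.meanOccupancy <- function(config) {
  config@concentration * .NM_PER_NM3 * .apertureArea(config) *
    .boxHeight(config)
}

# fine time step: 5 nm RMS step per axis resolves wall contacts
.fineStep <- function(config) {
  d <- config@diffusionCoefficient * 1e6  # nm^2/s
  min(25 / (2 * d), config@duration / 1e3)
}

#' Run a config through a local R RNG scope
#' @noRd
withLocalSeed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  code
}

.runKernel <- function(config, recordInterval = 0, emitPhotons = TRUE) {
  validObject(config)
  d_nm2s <- config@diffusionCoefficient * 1e6
  .sim_kernel(
    radius_nm = config@apertureDiameter / 2,
    h_ap_nm = config@apertureHeight,
    height_nm = .boxHeight(config),
    lambda_nm = config@axialDecayLength,
    D_nm2s = d_nm2s,
    dt_s = .fineStep(config),
    conc_per_nm3 = config@concentration * .NM_PER_NM3,
    b_free = config@brightnessFree,
    b_ads = config@brightnessAdsorbed,
    t_ds = config@darkFraction,
    tau_ds_s = config@darkLifetime,
    p_ads = config@adsorptionProbPerContact,
    dwell_mean_s = config@adsorbedDwellMean,
    duration_s = config@duration,
    seed = as.numeric(config@rngSeed),
    record_dt_s = recordInterval,
    emit_photons = emitPhotons)
}

#' Simulate molecule trajectories in the ZMW
#'
#' Brownian steps with per-axis variance 2 D dt, reflecting floor and side
#' walls, re-injection at the open top; wall contacts inside the aperture
#' adsorb with probability `adsorptionProbPerContact`, adsorbed dwell times
#' are exponential with mean `adsorbedDwellMean`. Positions are recorded
#' every `recordInterval` seconds; the full-resolution adsorption event log
#' is always returned.
#'
#' @param config a [SimulationConfig-class]
#' @param recordInterval recording interval, s.
#' @return list with `paths` (data.frame: t, molecule, x, y, z, adsorbed,
#'   bright) and `events` (data.frame: t, dwell, x, y, z per adsorption
#'   event)
#' @export
simulateTrajectories <- function(config, recordInterval = 1e-4) {
  if (recordInterval <= 0) stop("recordInterval must be > 0")
  k <- .runKernel(config, recordInterval = recordInterval,
                  emitPhotons = FALSE)
  list(paths = as.data.frame(k$paths), events = as.data.frame(k$events))
}

#' Generate a photon stream from recorded trajectories
#'
#' Photon emission is an inhomogeneous Poisson process with rate
#' brightness(state) x exp(-z / axialDecayLength), zero while dark. Each
#' photon microtime is an exponential excited-state delay (lifetime by
#' kinetic state) convolved with the IRF and wrapped into the sync period;
#' uniform background photons are added at `backgroundRate`. Uses the
#' piecewise-constant state between recorded path points, so it is meant for
#' inspection-scale runs; [simulateExperiment()] generates photons at full
#' step resolution.
#'
#' @param paths data.frame as returned by [simulateTrajectories()]
#' @param config the [SimulationConfig-class] used for the trajectories
#' @param seed RNG seed for the emission draw (default `config@rngSeed + 1`)
#' @return a [TTTRTrace-class] with ground-truth `labels`
#' @export
generatePhotonStream <- function(paths, config, seed = config@rngSeed + 1) {
  validObject(config)
  p <- paths
  if (!all(c("t", "molecule", "z", "adsorbed", "bright") %in% names(p)))
    stop("paths must come from simulateTrajectories()")
  withLocalSeed(seed, {
    t_all <- numeric(0); s_all <- integer(0)
    if (nrow(p)) {
      ord <- order(p$molecule, p$t)
      p <- p[ord, ]
      last_of_mol <- c(diff(p$molecule) != 0, TRUE)
      dt_rec <- c(diff(p$t), 0)
      # a molecule's final record emits for at most one recording interval:
      # molecules that left through the bath boundary are gone, not frozen
      step <- median(dt_rec[!last_of_mol & dt_rec > 0])
      if (!is.finite(step)) step <- config@duration
      dt_rec[last_of_mol] <-
        pmin(step, pmax(0, config@duration - p$t[last_of_mol]))
      bright <- p$bright == 1
      rate <- ifelse(p$adsorbed == 1, config@brightnessAdsorbed,
                     config@brightnessFree) *
        exp(-p$z / config@axialDecayLength) * bright
      mu <- rate * dt_rec
      nph <- rpois(length(mu), mu)
      idx <- rep.int(seq_along(nph), nph)
      if (length(idx)) {
        t_all <- p$t[idx] + runif(length(idx)) * dt_rec[idx]
        s_all <- as.integer(p$adsorbed[idx])
      }
    }
    .assemblePhotons(t_all, s_all, config)
  })
}

# Shared photon post-processing: background, microtimes, packaging.
# Caller must have seeded the RNG.
.assemblePhotons <- function(t_sig, state_sig, config) {
  period_ps <- 1e12 / config@syncRate
  n_bg <- rpois(1, config@backgroundRate * config@duration)
  t_bg <- runif(n_bg) * config@duration
  t_all <- c(t_sig, t_bg)
  state <- c(state_sig, rep.int(2L, n_bg))
  ord <- order(t_all)
  t_all <- t_all[ord]; state <- state[ord]

  n <- length(t_all)
  micro <- numeric(n)
  is_bg <- state == 2L
  if (any(is_bg)) micro[is_bg] <- runif(sum(is_bg)) * period_ps
  for (st in 0:1) {
    sel <- state == st
    if (!any(sel)) next
    tau_ns <- if (st == 0L) config@lifetimeFree else config@lifetimeAdsorbed
    delay_ps <- rexp(sum(sel), rate = 1 / tau_ns) * 1e3
    micro[sel] <- (sampleIRF(config@irf, sum(sel)) + delay_ps) %% period_ps
  }
  micro <- floor(micro)
  micro[micro >= period_ps] <- period_ps - 1

  TTTRTrace(macrotimes = floor(t_all * config@syncRate),
            microtimes = micro,
            channels = rep.int(0L, n),
            syncRate = config@syncRate,
            duration = config@duration,
            metadata = list(),
            labels = state)
}

#' Simulate a full acquisition
#'
#' Runs the trajectory and emission models in one pass at full step
#' resolution and returns the photon stream, with the adsorption-event log
#' and the configuration attached to the trace metadata. Deterministic:
#' identical seed + config yields a bit-identical stream.
#'
#' @param config a [SimulationConfig-class]
#' @return a [TTTRTrace-class]; `metadata$adsorptionEvents` holds the event
#'   log, `metadata$config` the configuration, and `labels` the per-photon
#'   emitter state (0 free, 1 adsorbed, 2 background)
#' @examples
#' cfg <- simConfig(duration = 0.5, rngSeed = 7)
#' tr <- simulateExperiment(cfg)
#' tr
#' @export
simulateExperiment <- function(config) {
  k <- .runKernel(config, recordInterval = 0, emitPhotons = TRUE)
  tr <- withLocalSeed(config@rngSeed,
                      .assemblePhotons(k$t, k$state, config))
  tr@metadata <- list(adsorptionEvents = as.data.frame(k$events),
                      config = config)
  tr
}

# IRF -----------------------------------------------------------------------

#' Instrument response models
#'
#' `gaussianIRF` builds a parametric Gaussian IRF; defaults match the red
#' detection path (110 ps FWHM; use 38 ps for the green path).
#' `histogramIRF` wraps a measured IRF histogram.
#'
#' @param fwhm full width at half maximum, ps.
#' @param center peak position within the sync period, ps.
#' @return an [IRFModel-class]
#' @export
gaussianIRF <- function(fwhm = 110, center = 1000) {
  new("IRFModel", type = "gaussian", fwhm = fwhm, center = center)
}

#' @rdname gaussianIRF
#' @param counts histogram counts per channel.
#' @param channelWidth channel width, ps.
#' @export
histogramIRF <- function(counts, channelWidth = 16) {
  new("IRFModel", type = "histogram", counts = as.numeric(counts),
      channelWidth = channelWidth)
}

#' Draw photon timing jitter from an IRF
#'
#' @param irf an [IRFModel-class]
#' @param n number of draws
#' @return numeric vector of arrival offsets (ps)
#' @export
sampleIRF <- function(irf, n) {
  validObject(irf)
  if (irf@type == "gaussian") {
    rnorm(n, mean = irf@center, sd = irf@fwhm / 2.3548200450309493)
  } else {
    ch <- sample.int(length(irf@counts), n, replace = TRUE,
                     prob = irf@counts)
    (ch - 1 + runif(n)) * irf@channelWidth
  }
}

#' Synthesize a pure TCSPC decay photon stream
#'
#' Draws `n` microtimes from a multi-exponential decay (pre-exponential
#' amplitudes `amplitudes`, so photon fractions are proportional to
#' `amplitudes * lifetimes`) convolved with the IRF, plus an optional
#' ultrafast scatter fraction emulating laser back-reflection. Macrotimes
#' are spread uniformly at `photonRate`.
#'
#' @param n photons.
#' @param amplitudes,lifetimes decay components (lifetimes in ns).
#' @param irf an [IRFModel-class].
#' @param syncRate Hz.
#' @param scatterFraction fraction of photons drawn from the scatter spike.
#' @param scatterLifetime scatter decay constant, ns (default 0.005 = 5 ps).
#' @param photonRate counts/s used to lay out macrotimes.
#' @param seed RNG seed.
#' @return a [TTTRTrace-class]
#' @export
simulateDecayPhotons <- function(n, amplitudes, lifetimes,
                                 irf = gaussianIRF(110), syncRate = 4e7,
                                 scatterFraction = 0,
                                 scatterLifetime = 0.005,
                                 photonRate = 1e4, seed = 1) {
  stopifnot(length(amplitudes) == length(lifetimes), all(amplitudes >= 0),
            all(lifetimes > 0), scatterFraction >= 0, scatterFraction < 1)
  period_ps <- 1e12 / syncRate
  withLocalSeed(seed, {
    n_sc <- rbinom(1, n, scatterFraction)
    n_fl <- n - n_sc
    frac <- amplitudes * lifetimes
    comp <- sample.int(length(lifetimes), n_fl, replace = TRUE, prob = frac)
    delay <- rexp(n_fl, rate = 1) * lifetimes[comp] * 1e3
    if (n_sc > 0)
      delay <- c(delay, rexp(n_sc, rate = 1) * scatterLifetime * 1e3)
    delay <- sample(delay)  # interleave scatter photons
    micro <- floor((sampleIRF(irf, n) + delay) %% period_ps)
    micro[micro >= period_ps] <- period_ps - 1
    macro <- floor(seq(0, by = syncRate / photonRate, length.out = n))
    TTTRTrace(macro, micro, syncRate = syncRate, duration = n / photonRate)
  })
}

# ground-truth expectations --------------------------------------------------

# Normalized axial autocorrelation of the detection profile exp(-z/Lambda)
# for Brownian motion on [0, H] with a reflecting floor and the bath
# (absorbing + re-injecting) boundary at the top: cosine eigenexpansion
# cos(omega_k z), omega_k = (k + 1/2) pi / H, with closed-form
# coefficients. Molecules that cross the bath boundary never return, so
# the propagator is the absorbing-top kernel; re-injected molecules are
# uncorrelated and contribute nothing. Diffusion-only (no blinking; the
# lateral profile is uniform across the aperture, so lateral motion drops
# out).
.axialACF <- function(tau, config) {
  lam <- config@axialDecayLength
  H <- .boxHeight(config)
  d <- config@diffusionCoefficient * 1e6
  kmax <- min(10000L, max(300L, ceiling(30 * H / (pi * lam))))
  a <- 1 / lam
  wk <- (seq_len(kmax) - 0.5) * pi / H
  sgn <- rep_len(c(1, -1), kmax)  # sin(w_k H) = (-1)^k for k = 0, 1, ...
  ik <- (a + sgn * wk * exp(-H / lam)) / (a^2 + wk^2)  # integral f*cos_k
  bk <- (2 / H) * ik^2
  rates <- d * wk^2
  num <- vapply(tau, function(tt) sum(bk * exp(-rates * tt)), numeric(1))
  num / sum(bk)
}

#' Expected diffusion time for a configuration
#'
#' The diffusion time that a correlation fit should recover: the lag at
#' which the exact axial autocorrelation of the evanescent detection
#' profile under reflected Brownian motion has decayed to
#' \eqn{2^{-1} \cdot 2^{-1/2} \approx 0.3536} — the decay point that defines
#' \eqn{\tau_D} in the fitted model with \eqn{\kappa = 1}.
#'
#' @param config a [SimulationConfig-class]
#' @return expected diffusion time, s
#' @export
expectedDiffusionTime <- function(config) {
  target <- 2^-1.5
  f <- function(tt) .axialACF(tt, config) - target
  lam <- config@axialDecayLength
  d <- config@diffusionCoefficient * 1e6
  t0 <- lam^2 / d
  lo <- t0 * 1e-4; hi <- t0 * 1e4
  while (f(hi) > 0 && hi < 1e4) hi <- hi * 10
  uniroot(f, c(lo, hi), tol = t0 * 1e-6)$root
}

#' Expected correlation-fit recovery for a configuration
#'
#' The asymptotic (infinite-data) values that the correlation-model fit
#' converges to under a configuration without sticking: the exact
#' diffusion-theory curve for the configured geometry (eigenmode
#' autocorrelation times the configured blinking factor and physical
#' amplitude) is projected onto the fitted model by the same deterministic
#' fit the pipeline uses (structure parameter 1, calibrated photophysics
#' fixed). These estimands, not the bare physical values, are the reference
#' for parameter-recovery checks: the fitted model is an empirical
#' description of the confined-volume correlation, and its best projection
#' sits a few percent away from the physical values ([expectedMoleculeNumber()],
#' [expectedDiffusionTime()]); a recovery test measures the scatter of the
#' pipeline around the estimand, not that offset.
#'
#' @param config a [SimulationConfig-class]
#' @param maxLag longest lag of the reference grid, s.
#' @return list with `N`, `tauD` (asymptotic estimands), `Nphysical` and
#'   `tauDphysical`
#' @export
expectedFCSRecovery <- function(config, maxLag = 2) {
  n_phys <- expectedMoleculeNumber(config)
  # the production multi-tau lag grid at 1 us base binning
  lags_s <- .multitauLagGrid(1e-6, 16L, maxLag)
  blink <- 1 + if (config@darkFraction > 0)
    config@darkFraction / (1 - config@darkFraction) *
      exp(-lags_s / config@darkLifetime) else 0
  gth <- blink * .axialACF(lags_s, config) / n_phys
  cv <- new("CorrelationCurve", lags = lags_s, g = gth,
            weights = rep(NA_real_, length(lags_s)), totalPhotons = 0,
            meanRate = 0, binWidth = 1e-6)
  f <- suppressWarnings(fitFCS(cv, nSpecies = 1,
                               fixed = list(Tds = config@darkFraction,
                                            tauDs = config@darkLifetime)))
  list(N = f@params@N, tauD = f@params@tauD[1],
       Nphysical = n_phys, tauDphysical = expectedDiffusionTime(config))
}

# lag grid of the multi-tau scheme (m linear lags, then m/2 per octave)
.multitauLagGrid <- function(binWidth, m = 16L, maxLag = 2) {
  lags <- seq_len(m) * binWidth
  w <- binWidth
  repeat {
    w <- 2 * w
    nxt <- seq.int(m / 2 + 1L, m) * w
    nxt <- nxt[nxt <= maxLag]
    if (!length(nxt)) break
    lags <- c(lags, nxt)
    if (max(nxt) >= maxLag) break
  }
  lags
}

#' Expected molecule number for a configuration
#'
#' Mean occupancy of the effective detection volume,
#' \eqn{N = C V_{eff}} with
#' \eqn{V_{eff} = (\int I\,dV)^2 / \int I^2\,dV} for the evanescent profile
#' (about \eqn{2 A \Lambda} for a column much deeper than the decay
#' length). The simulated occupancy is Poisson (bath top boundary), so this
#' is exactly the amplitude a correlation fit estimates as \eqn{1/G(0)}
#' after blinking and background corrections.
#'
#' @param config a [SimulationConfig-class]
#' @return expected mean molecule number in the observation volume
#' @export
expectedMoleculeNumber <- function(config) {
  lam <- config@axialDecayLength
  H <- .boxHeight(config)
  A <- .apertureArea(config)
  i1 <- lam * (1 - exp(-H / lam))
  i2 <- (lam / 2) * (1 - exp(-2 * H / lam))
  v_eff <- A * i1^2 / i2
  config@concentration * .NM_PER_NM3 * v_eff
}

#' Ground-truth slow (sticking) amplitude fraction of a simulated stream
#'
#' Computes the expected relative amplitude of the slow correlation
#' component from the simulator's adsorption-event log, independently of any
#' correlator or fit. Adsorption events form a filtered point process whose
#' zero-lag fluctuation amplitude is \eqn{S = T^{-1}\sum_e b_e^2 \tau_e}
#' (event brightness \eqn{b_e}, dwell \eqn{\tau_e} clipped to the
#' acquisition window); the free-diffusion amplitude is
#' \eqn{F = \bar B^2 C \int I^2 dV} in closed form. Blinking boosts both
#' terms equally and cancels in the ratio \eqn{S / (S + F)}.
#'
#' @param trace a [TTTRTrace-class] from [simulateExperiment()]
#' @param config optional [SimulationConfig-class]; default taken from the
#'   trace metadata
#' @return the slow amplitude fraction in `[0, 1]`
#' @export
trueSlowFraction <- function(trace, config = NULL) {
  if (is.null(config)) config <- trace@metadata$config
  events <- trace@metadata$adsorptionEvents
  if (is.null(config) || is.null(events))
    stop("trace must carry simulator metadata (config + adsorptionEvents)")
  lam <- config@axialDecayLength
  dur <- config@duration
  b_free <- config@brightnessFree * (1 - config@darkFraction)
  b_ads <- config@brightnessAdsorbed * (1 - config@darkFraction)
  s_amp <- if (nrow(events)) {
    b_e <- b_ads * exp(-events$z / lam)
    tau_e <- pmin(events$dwell, pmax(0, dur - events$t))
    sum(b_e^2 * tau_e) / dur
  } else 0
  H <- .boxHeight(config)
  A <- .apertureArea(config)
  i2 <- (lam / 2) * (1 - exp(-2 * H / lam))
  f_amp <- b_free^2 * config@concentration * .NM_PER_NM3 * A * i2
  s_amp / (s_amp + f_amp)
}

# spikes ---------------------------------------------------------------------

#' Flag long fluorescence spikes in an intensity trace
#'
#' Diagnostic for surface adhesion: contiguous runs of bins above a
#' threshold, reported with their durations. Adsorption of a labelled
#' molecule produces spikes much longer (> 100 ms) than diffusion bursts.
#'
#' @param trace an [IntensityTrace-class]
#' @param threshold counts per bin; default `mean + 5 * sd` of the trace.
#' @param minDuration shortest spike to report, s.
#' @return data.frame with `start_s`, `end_s`, `duration_s`, `peak_counts`
#' @export
detectSpikes <- function(trace, threshold = NULL, minDuration = 0.1) {
  stopifnot(is(trace, "IntensityTrace"))
  x <- counts(trace)
  # robust threshold: long spikes inflate the plain SD, so use the median
  # level plus 5 robust SDs; genuine adsorption spikes are separated from
  # diffusion bursts by the minimum-duration filter, not the threshold
  if (is.null(threshold)) threshold <- median(x) + 5 * mad(x) + 1
  r <- rle(x > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * trace@binWidth >= minDuration)
  if (!any(keep))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_counts = numeric(0)))
  data.frame(
    start_s = (starts[keep] - 1) * trace@binWidth,
    end_s = ends[keep] * trace@binWidth,
    duration_s = r$lengths[keep] * trace@binWidth,
    peak_counts = vapply(which(keep), function(i)
      max(x[starts[i]:ends[i]]), numeric(1)))
}

# config files ----------------------------------------------------------------

#' Read / write simulation configurations as YAML or JSON
#'
#' Field names match the [simConfig()] arguments; the IRF is stored as
#' `irf_fwhm_ps` / `irf_center_ps`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return `readSimConfig`: a [SimulationConfig-class]
#' @export
readSimConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  irf <- gaussianIRF(
    fwhm = if (!is.null(vals$irf_fwhm_ps)) vals$irf_fwhm_ps else 110,
    center = if (!is.null(vals$irf_center_ps)) vals$irf_center_ps else 1000)
  vals$irf_fwhm_ps <- NULL; vals$irf_center_ps <- NULL
  args <- vals[names(vals) %in% names(formals(simConfig))]
  args$irf <- irf
  do.call(simConfig, args)
}

#' @rdname readSimConfig
#' @param config a [SimulationConfig-class]
#' @export
writeSimConfig <- function(config, path) {
  validObject(config)
  vals <- list(
    apertureDiameter = config@apertureDiameter,
    apertureHeight = config@apertureHeight,
    reservoirHeight = config@reservoirHeight,
    axialDecayLength = config@axialDecayLength,
    diffusionCoefficient = config@diffusionCoefficient,
    concentration = config@concentration,
    brightnessFree = config@brightnessFree,
    brightnessAdsorbed = config@brightnessAdsorbed,
    darkFraction = config@darkFraction,
    darkLifetime = config@darkLifetime,
    adsorptionProbPerContact = config@adsorptionProbPerContact,
    adsorbedDwellMean = config@adsorbedDwellMean,
    lifetimeFree = config@lifetimeFree,
    lifetimeAdsorbed = config@lifetimeAdsorbed,
    syncRate = config@syncRate,
    duration = config@duration,
    backgroundRate = config@backgroundRate,
    rngSeed = config@rngSeed,
    irf_fwhm_ps = if (config@irf@type == "gaussian") config@irf@fwhm else NA,
    irf_center_ps = if (config@irf@type == "gaussian") config@irf@center
                    else NA)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(path)
}
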