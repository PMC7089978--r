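#' @import methods
#' @importFrom stats approx coef convolve fft mad median optimize quantile
#'   rbinom rexp rnorm rpois runif sd setNames uniroot var
#' @importFrom utils head read.table tail write.table
NULL

# ---------------------------------------------------------------------------
# TTTRTrace: ordered time-tagged time-resolved photon records.
#
# Macrotimes are kept as integer sync counts (stored in a double vector:
# 60 s at 40 MHz is 2.4e9 counts, beyond .Machine$integer.max but exact in a
# double). Microtimes are picoseconds within one sync period. The optional
# `labels` slot carries per-photon ground truth when the trace comes from the
# simulator (0 = free emitter, 1 = adsorbed emitter, 2 = background); it is
# empty for traces read from disk.

#' TTTRTrace: time-tagged time-resolved photon records
#'
#' Ordered photon records as produced by a TCSPC module in TTTR mode: a
#' coarse arrival time (`macrotimes`, in units of the laser sync period), the
#' delay since the last sync pulse (`microtimes`, picoseconds) and a detector
#' channel id per photon.
#'
#' @slot macrotimes numeric, non-decreasing sync counts (exact integers).
#' @slot microtimes numeric, picoseconds in `[0, syncPeriod)`.
#' @slot channels integer detector ids.
#' @slot syncRate numeric, laser repetition rate in Hz.
#' @slot duration numeric, acquisition length in seconds.
#' @slot metadata list of free-form condition labels (dye, passivation, ...).
#' @slot labels integer, optional per-photon emitter-state ground truth from
#'   the simulator (0 free, 1 adsorbed, 2 background); length 0 otherwise.
#' @exportClass TTTRTrace
setClass("TTTRTrace",
  representation(
    macrotimes = "numeric",
    microtimes = "numeric",
    channels   = "integer",
    syncRate   = "numeric",
    duration   = "numeric",
    metadata   = "list",
    labels     = "integer"
  ),
  prototype(
    macrotimes = numeric(0), microtimes = numeric(0), channels = integer(0),
    syncRate = 4e7, duration = 0, metadata = list(), labels = integer(0)
  )
)

setValidity("TTTRTrace", function(object) {
  n <- length(object@macrotimes)
  msg <- character(0)
  if (length(object@microtimes) != n || length(object@channels) != n)
    msg <- c(msg, "macrotimes, microtimes and channels must have equal length")
  if (length(object@syncRate) != 1 || !is.finite(object@syncRate) ||
      object@syncRate <= 0)
    msg <- c(msg, "syncRate must be a single positive number")
  if (length(object@duration) != 1 || !is.finite(object@duration) ||
      object@duration < 0)
    msg <- c(msg, "duration must be a single non-negative number")
  if (n > 0) {
    if (any(diff(object@macrotimes) < 0))
      msg <- c(msg, "macrotimes must be non-decreasing")
    period_ps <- 1e12 / object@syncRate
    if (any(object@microtimes < 0) || any(object@microtimes >= period_ps))
      msg <- c(msg, sprintf("microtimes must lie in [0, %g) ps", period_ps))
    if (object@duration < object@macrotimes[n] / object@syncRate)
      msg <- c(msg, "duration must cover the last macrotime")
  }
  if (length(object@labels) != 0 && length(object@labels) != n)
    msg <- c(msg, "labels must be empty or one per photon")
  if (length(msg)) msg else TRUE
})

#' IntensityTrace: binned photon counts
#'
#' @slot binWidth numeric, bin width in seconds.
#' @slot counts numeric, non-negative integer counts per bin.
#' @slot originTime numeric, start time of the first bin (s).
#' @exportClass IntensityTrace
setClass("IntensityTrace",
  representation(binWidth = "numeric", counts = "numeric",
                 originTime = "numeric"),
  prototype(binWidth = 1e-3, counts = numeric(0), originTime = 0)
)

setValidity("IntensityTrace", function(object) {
  msg <- character(0)
  if (length(object@binWidth) != 1 || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (length(object@counts) &&
      (any(object@counts < 0) || any(object@counts != round(object@counts))))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' TCSPCHistogram: microtime histogram over one sync period
#'
#' @slot channelWidth numeric, TCSPC channel width in picoseconds.
#' @slot counts numeric, photon counts per microtime channel.
#' @slot syncPeriod numeric, sync period in picoseconds; the channel grid
#'   spans it (to within one channel).
#' @exportClass TCSPCHistogram
setClass("TCSPCHistogram",
  representation(channelWidth = "numeric", counts = "numeric",
                 syncPeriod = "numeric"),
  prototype(channelWidth = 16, counts = numeric(0), syncPeriod = 25000)
)

setValidity("TCSPCHistogram", function(object) {
  msg <- character(0)
  if (object@channelWidth <= 0) msg <- c(msg, "channelWidth must be > 0")
  if (object@syncPeriod <= 0) msg <- c(msg, "syncPeriod must be > 0")
  if (length(object@counts)) {
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    span <- length(object@counts) * object@channelWidth
    if (span < object@syncPeriod - object@channelWidth ||
        span >= object@syncPeriod + 2 * object@channelWidth)
      msg <- c(msg, "channel grid must span one sync period (within a channel)")
  }
  if (length(msg)) msg else TRUE
})

#' IRFModel: instrument response function
#'
#' Either a parametric Gaussian (`type = "gaussian"`, FWHM and centre in ps)
#' or a measured histogram on a channel grid (`type = "histogram"`). In both
#' cases the discretized kernel normalizes to 1 over the sync period.
#'
#' @slot type character, `"gaussian"` or `"histogram"`.
#' @slot fwhm numeric, full width at half maximum (ps; gaussian type).
#' @slot center numeric, peak position (ps; gaussian type).
#' @slot counts numeric, histogram counts (histogram type).
#' @slot channelWidth numeric, channel width (ps; histogram type).
#' @exportClass IRFModel
setClass("IRFModel",
  representation(type = "character", fwhm = "numeric", center = "numeric",
                 counts = "numeric", channelWidth = "numeric"),
  prototype(type = "gaussian", fwhm = 110, center = 1000,
            counts = numeric(0), channelWidth = 16)
)

setValidity("IRFModel", function(object) {
  msg <- character(0)
  if (!object@type %in% c("gaussian", "histogram"))
    msg <- c(msg, "type must be 'gaussian' or 'histogram'")
  if (object@type == "gaussian") {
    if (object@fwhm <= 0) msg <- c(msg, "fwhm must be > 0")
    if (object@center < 0) msg <- c(msg, "center must be >= 0")
  } else {
    if (!length(object@counts) || all(object@counts == 0))
      msg <- c(msg, "histogram IRF needs non-empty, non-zero counts")
    if (any(object@counts < 0)) msg <- c(msg, "IRF counts must be >= 0")
    if (object@channelWidth <= 0) msg <- c(msg, "channelWidth must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationCurve: normalized intensity fluctuation autocorrelation
#'
#' Fluctuation form: g(tau) = <dI(t) dI(t+tau)> / <I>^2, so g -> 0 at long
#' lag and the zero-lag diffusion amplitude is ~ 1/N.
#'
#' @slot lags numeric, strictly increasing lag times (s), first lag > 0.
#' @slot g numeric, correlation values.
#' @slot weights numeric, per-lag uncertainty estimates (same length; may be
#'   NA where no estimate is available).
#' @slot totalPhotons numeric, photons in the correlated trace.
#' @slot meanRate numeric, mean detected count rate (counts/s).
#' @slot binWidth numeric, base bin width used (s).
#' @exportClass CorrelationCurve
setClass("CorrelationCurve",
  representation(lags = "numeric", g = "numeric", weights = "numeric",
                 totalPhotons = "numeric", meanRate = "numeric",
                 binWidth = "numeric"),
  prototype(lags = numeric(0), g = numeric(0), weights = numeric(0),
            totalPhotons = 0, meanRate = 0, binWidth = NA_real_)
)

setValidity("CorrelationCurve", function(object) {
  msg <- character(0)
  if (length(object@g) != length(object@lags) ||
      length(object@weights) != length(object@lags))
    msg <- c(msg, "lags, g and weights must have equal length")
  if (length(object@lags)) {
    if (object@lags[1] <= 0) msg <- c(msg, "first lag must be > 0")
    if (any(diff(object@lags) <= 0))
      msg <- c(msg, "lags must be strictly increasing")
    if (any(!is.finite(object@g)))
      msg <- c(msg, "g must be finite at every lag")
  }
  if (length(msg)) msg else TRUE
})

#' FCSParams: parameters of the diffusion + dark-state correlation model
#'
#' Parameters of the 3D Brownian diffusion model with a dark-state
#' (blinking) term used to fit ZMW correlation curves:
#' \deqn{G(\tau)=\frac{1}{N}\Big[1+\frac{T_{ds}}{1-T_{ds}}
#'   e^{-\tau/\tau_{ds}}\Big]\sum_i \alpha_i
#'   \Big(1+\frac{\tau}{\tau_{D,i}}\Big)^{-1}
#'   \Big(1+\frac{\tau}{\kappa^2\tau_{D,i}}\Big)^{-1/2}}
#' with the structure parameter \eqn{\kappa} fixed to 1 for ZMW volumes.
#'
#' @slot N numeric, mean number of molecules in the observation volume.
#' @slot Tds numeric, dark-state fraction in `[0, 1)`.
#' @slot tauDs numeric, dark-state lifetime (s).
#' @slot alpha numeric, species amplitude fractions (sum to 1, fast first).
#' @slot tauD numeric, species diffusion times (s), strictly increasing.
#' @slot kappa numeric, structure parameter (fixed at 1).
#' @exportClass FCSParams
setClass("FCSParams",
  representation(N = "numeric", Tds = "numeric", tauDs = "numeric",
                 alpha = "numeric", tauD = "numeric", kappa = "numeric"),
  prototype(N = 1, Tds = 0, tauDs = 1e-6, alpha = 1, tauD = 1e-3, kappa = 1)
)

setValidity("FCSParams", function(object) {
  msg <- character(0)
  if (object@N <= 0) msg <- c(msg, "N must be > 0")
  if (object@Tds < 0 || object@Tds >= 1) msg <- c(msg, "Tds must be in [0,1)")
  if (object@tauDs <= 0) msg <- c(msg, "tauDs must be > 0")
  if (length(object@alpha) != length(object@tauD))
    msg <- c(msg, "alpha and tauD must have equal length")
  if (any(object@alpha < 0)) msg <- c(msg, "alpha must be >= 0")
  if (abs(sum(object@alpha) - 1) > 1e-8) msg <- c(msg, "alpha must sum to 1")
  if (any(object@tauD <= 0)) msg <- c(msg, "tauD must be > 0")
  if (length(object@tauD) > 1 && any(diff(object@tauD) <= 0))
    msg <- c(msg, "tauD must be strictly increasing (species fast to slow)")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (length(msg)) msg else TRUE
})

#' FCSFit: result of fitting the correlation model
#'
#' @slot params [FCSParams-class] point estimates (species ordered fast to
#'   slow).
#' @slot se named numeric, approximate standard errors.
#' @slot redChiSq numeric, reduced chi-square of the weighted fit.
#' @slot nSpecies integer, number of diffusing species fitted.
#' @slot converged logical.
#' @slot meanRate numeric, mean count rate of the fitted curve (counts/s).
#' @slot totalPhotons numeric.
#' @slot diagnostics list (iterations, message, initial values, restarts).
#' @exportClass FCSFit
setClass("FCSFit",
  representation(params = "FCSParams", se = "numeric", redChiSq = "numeric",
                 nSpecies = "integer", converged = "logical",
                 meanRate = "numeric", totalPhotons = "numeric",
                 diagnostics = "list"),
  prototype(se = numeric(0), redChiSq = NA_real_, nSpecies = 1L,
            converged = FALSE, meanRate = NA_real_, totalPhotons = NA_real_,
            diagnostics = list())
)

#' DecayFit: result of an IRF-reconvolved multi-exponential decay fit
#'
#' @slot amplitudes numeric, pre-exponential amplitudes (counts scale).
#' @slot lifetimes numeric, component lifetimes (ns).
#' @slot excluded logical, per component; TRUE for components below the
#'   scatter threshold (e.g. laser back-reflection), omitted from the
#'   intensity-weighted average.
#' @slot background numeric, fitted flat background (counts/channel).
#' @slot gate numeric length-2, fitted time window `[t_start, t_end]` (ps)
#'   holding at least 95% of the photons.
#' @slot redChiSq numeric, reduced chi-square (Poisson weights).
#' @slot avgLifetime numeric, intensity-weighted average lifetime over the
#'   retained components (ns).
#' @slot irf [IRFModel-class] used for reconvolution.
#' @slot converged logical.
#' @slot flags character, warnings such as near-zero amplitudes.
#' @slot diagnostics list.
#' @exportClass DecayFit
setClass("DecayFit",
  representation(amplitudes = "numeric", lifetimes = "numeric",
                 excluded = "logical", background = "numeric",
                 gate = "numeric", redChiSq = "numeric",
                 avgLifetime = "numeric", irf = "IRFModel",
                 converged = "logical", flags = "character",
                 diagnostics = "list"),
  prototype(amplitudes = numeric(0), lifetimes = numeric(0),
            excluded = logical(0), background = 0, gate = c(0, 25000),
            redChiSq = NA_real_, avgLifetime = NA_real_, converged = FALSE,
            flags = character(0), diagnostics = list())
)

setValidity("DecayFit", function(object) {
  msg <- character(0)
  k <- length(object@amplitudes)
  if (length(object@lifetimes) != k || length(object@excluded) != k)
    msg <- c(msg, "amplitudes, lifetimes, excluded must have equal length")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@lifetimes <= 0)) msg <- c(msg, "lifetimes must be > 0")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: geometry, kinetics, photophysics and acquisition
#'
#' Parameters of the synthetic photon-stream generator emulating labelled
#' DNA diffusing through (and transiently adsorbing inside) a zero-mode
#' waveguide. Defaults follow the benchmark conditions: 110 nm aperture in a
#' 100 nm metal film, evanescent detection profile, 40 MHz sync rate, 60 s
#' acquisition, 100 nM labelled molecules.
#'
#' @slot apertureDiameter numeric, nm.
#' @slot apertureHeight numeric, nm (metal film thickness).
#' @slot reservoirHeight numeric, nm of solution column simulated above the
#'   aperture; its top is a well-mixed bath boundary (molecules crossing it
#'   are removed, fresh ones enter as a Poisson flux, keeping the occupancy
#'   Poisson at concentration x volume).
#' @slot axialDecayLength numeric, nm, decay length of the evanescent
#'   detection profile exp(-z / axialDecayLength).
#' @slot diffusionCoefficient numeric, um^2/s.
#' @slot concentration numeric, nM.
#' @slot brightnessFree numeric, counts/s per free molecule at the profile
#'   maximum (z = 0).
#' @slot brightnessAdsorbed numeric, counts/s per adsorbed molecule at the
#'   profile maximum (metal quenching makes this lower than brightnessFree).
#' @slot darkFraction numeric, dark-state (blinking) fraction T_ds in [0,1).
#' @slot darkLifetime numeric, dark-state lifetime tau_ds (s).
#' @slot adsorptionProbPerContact numeric in [0,1], probability that a wall
#'   contact inside the aperture leads to adsorption.
#' @slot adsorbedDwellMean numeric, mean of the exponential adsorbed dwell
#'   time (s).
#' @slot lifetimeFree numeric, excited-state lifetime of free molecules (ns).
#' @slot lifetimeAdsorbed numeric, excited-state lifetime while adsorbed (ns).
#' @slot irf [IRFModel-class] applied to every photon microtime.
#' @slot syncRate numeric, Hz.
#' @slot duration numeric, s.
#' @slot backgroundRate numeric, counts/s of uncorrelated background.
#' @slot rngSeed integer seed; identical seed + config gives a bit-identical
#'   photon stream.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    apertureDiameter = "numeric", apertureHeight = "numeric",
    reservoirHeight = "numeric", axialDecayLength = "numeric",
    diffusionCoefficient = "numeric", concentration = "numeric",
    brightnessFree = "numeric", brightnessAdsorbed = "numeric",
    darkFraction = "numeric", darkLifetime = "numeric",
    adsorptionProbPerContact = "numeric", adsorbedDwellMean = "numeric",
    lifetimeFree = "numeric", lifetimeAdsorbed = "numeric",
    irf = "IRFModel", syncRate = "numeric", duration = "numeric",
    backgroundRate = "numeric", rngSeed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  pos <- c(apertureDiameter = object@apertureDiameter,
           apertureHeight = object@apertureHeight,
           reservoirHeight = object@reservoirHeight,
           axialDecayLength = object@axialDecayLength,
           diffusionCoefficient = object@diffusionCoefficient,
           concentration = object@concentration,
           adsorbedDwellMean = object@adsorbedDwellMean,
           lifetimeFree = object@lifetimeFree,
           lifetimeAdsorbed = object@lifetimeAdsorbed,
           darkLifetime = object@darkLifetime,
           syncRate = object@syncRate, duration = object@duration)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("must be > 0: ", paste(bad, collapse = ", ")))
  if (object@darkFraction < 0 || object@darkFraction >= 1)
    msg <- c(msg, "darkFraction must be in [0, 1)")
  if (object@adsorptionProbPerContact < 0 ||
      object@adsorptionProbPerContact > 1)
    msg <- c(msg, "adsorptionProbPerContact must be in [0, 1]")
  if (object@brightnessFree < 0 || object@brightnessAdsorbed < 0 ||
      object@backgroundRate < 0)
    msg <- c(msg, "brightness and background rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ConditionSpec: one dye x passivation condition for the benchmark
#'
#' Exactly one of `config` (simulate) or `path` (load a photon file) must be
#' given.
#'
#' @slot label character, e.g. "Atto647N / none".
#' @slot dye character, dye name (see [dyeTable()]).
#' @slot passivation character, one of none, BSA, PEG500, PEG1000, PEG5000,
#'   PVPA.
#' @slot concentration numeric, nM.
#' @slot config [SimulationConfig-class] or NULL.
#' @slot path character, photon-file path or NA.
#' @exportClass ConditionSpec
setClass("ConditionSpec",
  representation(label = "character", dye = "character",
                 passivation = "character", concentration = "numeric",
                 config = "ANY", path = "character"),
  prototype(label = "", dye = "", passivation = "none", concentration = NA_real_,
            config = NULL, path = NA_character_)
)

setValidity("ConditionSpec", function(object) {
  msg <- character(0)
  has_cfg <- !is.null(object@config)
  has_path <- !is.na(object@path)
  if (has_cfg == has_path)
    msg <- c(msg, "exactly one of config or path must be given")
  if (has_cfg && !is(object@config, "SimulationConfig"))
    msg <- c(msg, "config must be a SimulationConfig")
  if (!object@passivation %in%
      c("none", "BSA", "PEG500", "PEG1000", "PEG5000", "PVPA"))
    msg <- c(msg, "unknown passivation")
  if (length(msg)) msg else TRUE
})

#' BenchmarkReport: per-condition comparison table
#'
#' @slot table data.frame, one row per condition.
#' @slot baseline character, label of the baseline (least-sticking) condition.
#' @slot provenance list (seeds, config hashes).
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  representation(table = "data.frame", baseline = "character",
                 provenance = "list"),
  prototype(table = data.frame(), baseline = NA_character_,
            provenance = list())
)
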