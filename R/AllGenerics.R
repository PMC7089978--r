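# Generics and accessors. Slot access from user code goes through these.

#' @rdname TTTRTrace-class
#' @param object,x a package object
#' @export
setGeneric("macrotimes", function(x) standardGeneric("macrotimes"))
#' @rdname TTTRTrace-class
#' @export
setGeneric("microtimes", function(x) standardGeneric("microtimes"))
#' @rdname TTTRTrace-class
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname TTTRTrace-class
#' @export
setGeneric("syncRate", function(x) standardGeneric("syncRate"))
#' @rdname TTTRTrace-class
#' @export
setGeneric("acqDuration", function(x) standardGeneric("acqDuration"))
#' @rdname TTTRTrace-class
#' @export
setGeneric("nPhotons", function(x) standardGeneric("nPhotons"))
#' Arrival times in seconds
#'
#' Absolute photon arrival times, macrotime converted to seconds (the
#' sub-sync microtime offset is irrelevant at binning time scales).
#' @param x a [TTTRTrace-class]
#' @return numeric vector of seconds
#' @export
setGeneric("arrivalTimes", function(x) standardGeneric("arrivalTimes"))

#' @rdname IntensityTrace-class
#' @param x a package object
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname IntensityTrace-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname CorrelationCurve-class
#' @param x a package object
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))
#' @rdname CorrelationCurve-class
#' @export
setGeneric("gValues", function(x) standardGeneric("gValues"))
#' @rdname CorrelationCurve-class
#' @export
setGeneric("gWeights", function(x) standardGeneric("gWeights"))
#' @rdname CorrelationCurve-class
#' @export
setGeneric("meanRate", function(x) standardGeneric("meanRate"))

#' @rdname FCSFit-class
#' @param x a package object
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname FCSFit-class
#' @export
setGeneric("reducedChiSq", function(x) standardGeneric("reducedChiSq"))

# ---- methods -----------------------------------------------------------

setMethod("macrotimes", "TTTRTrace", function(x) x@macrotimes)
setMethod("microtimes", "TTTRTrace", function(x) x@microtimes)
setMethod("channels", "TTTRTrace", function(x) x@channels)
setMethod("syncRate", "TTTRTrace", function(x) x@syncRate)
setMethod("acqDuration", "TTTRTrace", function(x) x@duration)
setMethod("nPhotons", "TTTRTrace", function(x) length(x@macrotimes))
setMethod("arrivalTimes", "TTTRTrace", function(x) x@macrotimes / x@syncRate)

setMethod("binWidth", "IntensityTrace", function(x) x@binWidth)
setMethod("counts", "IntensityTrace", function(x) x@counts)
setMethod("counts", "TCSPCHistogram", function(x) x@counts)
setMethod("nPhotons", "IntensityTrace", function(x) sum(x@counts))
setMethod("nPhotons", "TCSPCHistogram", function(x) sum(x@counts))

setMethod("lags", "CorrelationCurve", function(x) x@lags)
setMethod("gValues", "CorrelationCurve", function(x) x@g)
setMethod("gWeights", "CorrelationCurve", function(x) x@weights)
setMethod("meanRate", "CorrelationCurve", function(x) x@meanRate)

setMethod("fitParams", "FCSFit", function(x) x@params)
setMethod("reducedChiSq", "FCSFit", function(x) x@redChiSq)
setMethod("reducedChiSq", "DecayFit", function(x) x@redChiSq)

# ---- show methods ------------------------------------------------------

setMethod("show", "TTTRTrace", function(object) {
  cat(sprintf("TTTRTrace: %d photons, %.3g s at %.4g MHz sync\n",
              length(object@macrotimes), object@duration,
              object@syncRate / 1e6))
  if (length(object@macrotimes))
    cat(sprintf("  mean rate %.4g counts/s\n",
                length(object@macrotimes) / max(object@duration, 1e-12)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), unlist(
      lapply(object@metadata, format)), sep = "=", collapse = ", "), "\n")
  if (length(object@labels))
    cat(sprintf("  ground-truth labels: %d free, %d adsorbed, %d background\n",
                sum(object@labels == 0L), sum(object@labels == 1L),
                sum(object@labels == 2L)))
  invisible(NULL)
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace: %d bins of %.4g s, %g photons\n",
              length(object@counts), object@binWidth, sum(object@counts)))
  invisible(NULL)
})

setMethod("show", "TCSPCHistogram", function(object) {
  cat(sprintf("TCSPCHistogram: %d channels of %g ps, %g photons\n",
              length(object@counts), object@channelWidth, sum(object@counts)))
  invisible(NULL)
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags (%.3g - %.3g s), mean rate %.4g/s\n",
              length(object@lags),
              if (length(object@lags)) object@lags[1] else NA,
              if (length(object@lags)) tail(object@lags, 1) else NA,
              object@meanRate))
  invisible(NULL)
})

setMethod("show", "FCSParams", function(object) {
  cat(sprintf("FCSParams: N = %.4g, Tds = %.3g, tauDs = %.3g s, kappa = %g\n",
              object@N, object@Tds, object@tauDs, object@kappa))
  for (i in seq_along(object@alpha))
    cat(sprintf("  species %d: alpha = %.3f, tauD = %.4g s\n",
                i, object@alpha[i], object@tauD[i]))
  invisible(NULL)
})

setMethod("show", "FCSFit", function(object) {
  cat(sprintf("FCSFit (%d species, %s, red. chi-sq %.3g)\n",
              object@nSpecies,
              if (object@converged) "converged" else "NOT converged",
              object@redChiSq))
  show(object@params)
  if (object@nSpecies > 1) {
    fr <- stickingFractions(object)
    cat(sprintf("  fast %.1f%% / slow %.1f%%\n", fr[1], fr[2]))
  }
  invisible(NULL)
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%d components, %s, red. chi-sq %.3g)\n",
              length(object@lifetimes),
              if (object@converged) "converged" else "NOT converged",
              object@redChiSq))
  amp <- object@amplitudes / sum(object@amplitudes)
  for (i in seq_along(object@lifetimes))
    cat(sprintf("  a%d = %.3f, tau%d = %.4g ns%s\n", i, amp[i], i,
                object@lifetimes[i],
                if (object@excluded[i]) "  [excluded: scatter]" else ""))
  cat(sprintf("  intensity-weighted average: %.4g ns (gate %g-%g ps)\n",
              object@avgLifetime, object@gate[1], object@gate[2]))
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %g nm aperture x %g nm film, Lambda = %g nm\n",
    "  D = %g um^2/s, %g nM, %g s at %.3g MHz, seed %d\n",
    "  sticking: p = %g per contact, dwell %g s; blinking Tds = %g, ",
    "tauDs = %g s\n"),
    object@apertureDiameter, object@apertureHeight, object@axialDecayLength,
    object@diffusionCoefficient, object@concentration, object@duration,
    object@syncRate / 1e6, as.integer(object@rngSeed),
    object@adsorptionProbPerContact, object@adsorbedDwellMean,
    object@darkFraction, object@darkLifetime))
  invisible(NULL)
})

setMethod("show", "ConditionSpec", function(object) {
  cat(sprintf("ConditionSpec: %s (dye %s, passivation %s, %g nM, %s)\n",
              object@label, object@dye, object@passivation,
              object@concentration,
              if (is.null(object@config)) paste0("file ", object@path)
              else "simulated"))
  invisible(NULL)
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport: %d conditions (baseline: %s)\n",
              nrow(object@table), object@baseline))
  print(object@table)
  invisible(NULL)
})
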