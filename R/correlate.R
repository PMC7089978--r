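# Intensity autocorrelation: a direct double-sum reference form and the
# multi-tau production correlator (C++ kernel), both in the normalized
# fluctuation convention g(tau) = <dI(t) dI(t+tau)> / <I>^2.

#' Direct (brute-force) intensity autocorrelation
#'
#' Computes g at every integer-bin lag up to `maxLag` by direct summation
#' over all overlapping bin pairs, with fluctuations taken about the global
#' trace mean: `g(k) = mean(dI[i] * dI[i+k]) / mean(I)^2`. This is the
#' reference implementation the multi-tau correlator is checked against; use
#' [correlateMultitau()] for long traces.
#'
#' @param trace an [IntensityTrace-class] with at least 2 bins
#' @param maxLag largest lag, s; must be smaller than the trace span.
#' @return a [CorrelationCurve-class] (weights are NA: the direct form
#'   carries no uncertainty estimate)
#' @examples
#' tr <- new("IntensityTrace", binWidth = 1, counts = c(2, 0))
#' gValues(correlateDirect(tr, maxLag = 1))  # -1: anticorrelated
#' @export
correlateDirect <- function(trace, maxLag) {
  stopifnot(is(trace, "IntensityTrace"))
  x <- counts(trace)
  n <- length(x)
  if (n < 2) stop("trace must have at least 2 bins")
  span <- n * trace@binWidth
  if (maxLag >= span) stop("maxLag must be smaller than the trace span")
  kmax <- max(1L, min(n - 1L, as.integer(floor(maxLag / trace@binWidth))))
  mu <- mean(x)
  if (mu == 0) stop("trace has no photons")
  d <- x - mu
  g <- vapply(seq_len(kmax), function(k) {
    mean(d[seq_len(n - k)] * d[seq.int(k + 1L, n)]) / mu^2
  }, numeric(1))
  new("CorrelationCurve",
      lags = seq_len(kmax) * trace@binWidth, g = g,
      weights = rep(NA_real_, kmax), totalPhotons = sum(x),
      meanRate = mu / trace@binWidth, binWidth = trace@binWidth)
}

#' Multi-tau intensity autocorrelation
#'
#' Standard multi-tau scheme: `m` linear lags in the first octave, then
#' `m/2` new lags per octave with pairwise bin coarsening (bin width doubles
#' each octave), giving a logarithmic lag grid from the base bin width out
#' to `maxLag`. Normalization uses symmetric means over the overlapping
#' head/tail segments at each lag. Per-lag uncertainty estimates come from
#' splitting the trace into `nSegments` blocks and taking the inter-segment
#' standard error of g.
#'
#' @param trace an [IntensityTrace-class]
#' @param m lags per octave; even, at least 8. Default 16.
#' @param maxLag largest lag, s. Default: a quarter of the trace span.
#' @param nSegments blocks for the uncertainty estimate (>= 2 to enable;
#'   default 8). Lags longer than a segment get NA weights.
#' @return a [CorrelationCurve-class]
#' @export
correlateMultitau <- function(trace, m = 16, maxLag = NULL, nSegments = 8) {
  stopifnot(is(trace, "IntensityTrace"))
  if (m %% 2 != 0 || m < 8) stop("m must be even and >= 8")
  x <- counts(trace)
  n <- length(x)
  if (n < 2 * m) stop("trace shorter than the first octave (need >= 2*m bins)")
  w <- trace@binWidth
  if (is.null(maxLag)) maxLag <- n * w / 4
  if (maxLag < w) stop("maxLag must be at least one bin")

  res <- .multitau_kernel(as.numeric(x), as.integer(m), w, maxLag)
  lags_s <- res$lag
  g <- res$g
  keep <- is.finite(g)
  lags_s <- lags_s[keep]; g <- g[keep]
  if (!length(lags_s)) stop("no finite correlation values (empty trace?)")

  weights <- rep(NA_real_, length(lags_s))
  if (nSegments >= 2) {
    seg_len <- n %/% nSegments
    if (seg_len >= 2 * m) {
      gseg <- matrix(NA_real_, nrow = length(lags_s), ncol = nSegments)
      for (s in seq_len(nSegments)) {
        xs <- x[seq.int((s - 1) * seg_len + 1L, s * seg_len)]
        rs <- .multitau_kernel(as.numeric(xs), as.integer(m), w, maxLag)
        idx <- match(round(lags_s / w), round(rs$lag / w))
        ok <- !is.na(idx)
        gseg[ok, s] <- rs$g[idx[ok]]
      }
      n_ok <- rowSums(is.finite(gseg))
      sds <- apply(gseg, 1, function(r) sd(r[is.finite(r)]))
      weights <- ifelse(n_ok >= 2, sds / sqrt(pmax(n_ok, 1)), NA_real_)
    }
  }
  new("CorrelationCurve", lags = lags_s, g = g, weights = weights,
      totalPhotons = sum(x), meanRate = mean(x) / w, binWidth = w)
}

#' Correct a correlation amplitude for uncorrelated background
#'
#' Uncorrelated background at rate `bgRate` dilutes the fluctuation
#' amplitude by `((S + B) / S)^2` where `S` is the signal and `B` the
#' background rate; this rescales g by that factor (standard background
#' correction with a separately measured background).
#'
#' @param curve a [CorrelationCurve-class]
#' @param bgRate background count rate, counts/s.
#' @return the corrected [CorrelationCurve-class]
#' @export
correctBackground <- function(curve, bgRate) {
  stopifnot(is(curve, "CorrelationCurve"))
  if (bgRate < 0) stop("bgRate must be >= 0")
  if (bgRate >= curve@meanRate)
    stop("background rate exceeds the measured rate")
  f <- (curve@meanRate / (curve@meanRate - bgRate))^2
  new("CorrelationCurve", lags = curve@lags, g = curve@g * f,
      weights = curve@weights * f, totalPhotons = curve@totalPhotons,
      meanRate = curve@meanRate, binWidth = curve@binWidth)
}
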