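# The correlation model for confined diffusion with dark-state blinking,
# and its weighted least-squares fit (Levenberg-Marquardt via minpack.lm).

#' Construct correlation-model parameters
#'
#' @param N mean molecules in the observation volume.
#' @param tauD diffusion time(s), s; one per species, fast first.
#' @param alpha species amplitude fractions (normalized to sum to 1).
#' @param Tds dark-state fraction.
#' @param tauDs dark-state lifetime, s.
#' @param kappa structure parameter; fixed at 1 for ZMW observation volumes
#'   and not fitted.
#' @return an [FCSParams-class]
#' @export
fcsParams <- function(N, tauD, alpha = rep(1 / length(tauD), length(tauD)),
                      Tds = 0, tauDs = 1e-6, kappa = 1) {
  o <- order(tauD)
  new("FCSParams", N = N, Tds = Tds, tauDs = tauDs,
      alpha = alpha[o] / sum(alpha), tauD = tauD[o], kappa = kappa)
}

#' Evaluate the diffusion + dark-state correlation model
#'
#' \deqn{G(\tau)=\frac{1}{N}\Big[1+\frac{T_{ds}}{1-T_{ds}}
#'   e^{-\tau/\tau_{ds}}\Big]\sum_i \alpha_i
#'   \Big(1+\frac{\tau}{\tau_{D,i}}\Big)^{-1}
#'   \Big(1+\frac{\tau}{\kappa^2\tau_{D,i}}\Big)^{-1/2}}
#'
#' At \eqn{\tau = 0} this gives \eqn{(1/N)/(1-T_{ds})}; for a single species
#' with \eqn{\kappa = 1}, \eqn{G(\tau_D) = (1/N)(1/2)(1/\sqrt2)}.
#'
#' @param tau lag times, s (vectorized).
#' @param params an [FCSParams-class]
#' @return numeric vector of g values
#' @examples
#' evalFCSModel(0, fcsParams(N = 4, tauD = 1e-3))       # 0.25
#' evalFCSModel(1e-3, fcsParams(N = 1, tauD = 1e-3))    # 0.3536
#' @export
evalFCSModel <- function(tau, params) {
  stopifnot(is(params, "FCSParams"))
  validObject(params)
  if (any(tau < 0)) stop("tau must be >= 0")
  blink <- 1 + params@Tds / (1 - params@Tds) * exp(-tau / params@tauDs)
  diff_sum <- 0
  for (i in seq_along(params@alpha)) {
    ti <- params@tauD[i]
    diff_sum <- diff_sum + params@alpha[i] *
      (1 + tau / ti)^-1 * (1 + tau / (params@kappa^2 * ti))^-0.5
  }
  blink * diff_sum / params@N
}

# parameter packing: all time scales and N on log10 scale
.packInit <- function(init, n_species) {
  p <- c(log10(init@N), init@Tds, log10(init@tauDs), log10(init@tauD[1]))
  if (n_species == 2)
    p <- c(p, init@alpha[2], log10(init@tauD[2]))
  p
}

.unpack <- function(p, n_species) {
  if (n_species == 1) {
    fcsParams(N = 10^p[1], tauD = 10^p[4], alpha = 1, Tds = p[2],
              tauDs = 10^p[3])
  } else {
    fcsParams(N = 10^p[1], tauD = c(10^p[4], 10^p[6]),
              alpha = c(1 - p[5], p[5]), Tds = p[2], tauDs = 10^p[3])
  }
}

.fcsBounds <- function(n_species) {
  # N in (0, 1e4], Tds in [0, 0.6], tauDs in [0.1 us, 100 us],
  # tauD1 in [1 us, 10 ms], tauD2 in [30 ms, 10 s]. Each term is confined
  # to its own time-scale regime: the dark state to photophysics (below
  # diffusion), the fast species to diffusion-limited transits, and the
  # slow species to adsorption dwells (the >100 ms spike regime). Without
  # the separation the terms can impersonate one another and the fit
  # degenerates.
  lower <- c(-6, 0, -7, -6)
  upper <- c(4, 0.6, -4, -2)
  if (n_species == 2) {
    lower <- c(lower, 0, log10(0.03))
    upper <- c(upper, 1, 1)
  }
  list(lower = lower, upper = upper)
}

.initFromCurve <- function(curve, n_species) {
  g <- curve@g; l <- curve@lags
  head_g <- max(g[seq_len(min(3, length(g)))])
  if (!is.finite(head_g) || head_g <= 0) head_g <- max(g[g > 0], 1e-3)
  n0 <- 1 / head_g
  half_idx <- which(g <= head_g / 2)
  tau_d0 <- if (length(half_idx)) l[half_idx[1]] else l[length(l) %/% 2]
  tau_d0 <- max(tau_d0, 2e-6)
  if (n_species == 1)
    return(fcsParams(N = n0, tauD = tau_d0, Tds = 0.05,
                     tauDs = max(1e-6, l[1])))
  slow_idx <- which(g <= head_g / 10)
  tau_d2 <- if (length(slow_idx)) max(l[slow_idx[1]], tau_d0 * 10)
            else tau_d0 * 100
  tau_d2 <- min(max(tau_d2, 0.05), 5)  # slow species: adsorption regime
  fcsParams(N = n0, tauD = c(min(tau_d0, 9e-3), tau_d2),
            alpha = c(0.8, 0.2), Tds = 0.05, tauDs = max(1e-6, l[1]))
}

.fitWeights <- function(curve, weighting = c("uniform", "estimated")) {
  weighting <- match.arg(weighting)
  w <- curve@weights
  g <- curve@g
  if (weighting == "uniform" || all(!is.finite(w)))
    return(rep(1, length(g)))
  cap <- max(w[is.finite(w)])
  w[!is.finite(w)] <- cap
  pmax(w, 1e-4 * max(abs(g)))
}

#' Fit the correlation model to a measured curve
#'
#' Weighted least-squares (Levenberg-Marquardt) fit of [evalFCSModel()] with
#' the structure parameter fixed at \eqn{\kappa = 1}. With
#' `nSpecies = "auto"`, a 1-species fit is tried first and a second (slow)
#' species added only if the residuals at lags beyond `10 * tauD` show
#' significant structure — the reproducible version of choosing the species
#' count by inspecting the long-lag tail.
#'
#' @param curve a [CorrelationCurve-class] spanning several decades of lag.
#' @param nSpecies 1, 2 or `"auto"`.
#' @param init optional [FCSParams-class] starting point; otherwise derived
#'   from curve features (amplitude, half-decay lag).
#' @param restarts random restarts (seeded, deterministic) if the first
#'   optimization does not converge or to escape shallow minima.
#' @param weighting `"uniform"` (default) for unit weights, which anchor
#'   the fit on the amplitude and main decay, or `"estimated"` to use the
#'   curve's block-splitting uncertainty estimates. The block estimates
#'   track the relative error of g, and inverse-variance weighting with
#'   them makes the fit chase the far tail, where any imperfection of the
#'   effective-volume shape dominates; uniform weighting is the robust
#'   default for parameter recovery.
#' @return an [FCSFit-class]; species are ordered fast to slow, and two
#'   species closer than 1% in diffusion time collapse to one.
#' @seealso [stickingFractions()], [moleculesAndBrightness()]
#' @export
fitFCS <- function(curve, nSpecies = 1, init = NULL, restarts = 5,
                   weighting = c("uniform", "estimated"), fixed = list()) {
  stopifnot(is(curve, "CorrelationCurve"), is.list(fixed))
  weighting <- match.arg(weighting)
  keep <- is.finite(curve@g)
  if (sum(keep) < 8) stop("too few finite correlation points to fit")
  if (log10(max(curve@lags) / curve@lags[1]) < 3)
    warning("curve spans less than 3 decades of lag; fit may be degenerate")

  if (identical(nSpecies, "auto"))
    return(.fitFCSAuto(curve, restarts, weighting, fixed))
  n_species <- as.integer(nSpecies)
  stopifnot(n_species %in% 1:2)

  w <- .fitWeights(curve, weighting)
  tau <- curve@lags
  g <- curve@g
  b <- .fcsBounds(n_species)
  if (is.null(init)) init <- .initFromCurve(curve, n_species)
  if (length(init@tauD) != n_species)
    stop("init has the wrong number of species")
  p0 <- pmin(pmax(.packInit(init, n_species), b$lower), b$upper)

  # clamp fixed parameters (calibrated photophysics): drop them from the
  # optimization vector
  fix_idx <- integer(0)
  if (!is.null(fixed$Tds)) { p0[2] <- fixed$Tds; fix_idx <- c(fix_idx, 2L) }
  if (!is.null(fixed$tauDs)) {
    p0[3] <- log10(fixed$tauDs); fix_idx <- c(fix_idx, 3L)
  }
  free_idx <- setdiff(seq_along(p0), fix_idx)
  expand <- function(pf) { p <- p0; p[free_idx] <- pf; p }
  resid_fn <- function(pf) {
    (evalFCSModel(tau, .unpack(expand(pf), n_species)) - g) / w
  }

  best <- NULL
  tried <- 0L
  for (r in 0:restarts) {
    p_start <- if (r == 0) p0 else withLocalSeed(1000 + r, {
      jit <- p0
      jit[c(1, 4)] <- jit[c(1, 4)] + rnorm(2, 0, 0.3)
      if (!2L %in% fix_idx) jit[2] <- runif(1, 0, 0.5)
      if (!3L %in% fix_idx) jit[3] <- runif(1, -6.5, -4.5)
      if (n_species == 2) jit[5:6] <- c(runif(1, 0.05, 0.5),
                                        jit[6] + rnorm(1, 0, 0.5))
      pmin(pmax(jit, b$lower), b$upper)
    })
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p_start[free_idx], fn = resid_fn,
                         lower = b$lower[free_idx],
                         upper = b$upper[free_idx],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    tried <- tried + 1L
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (!is.null(best) && best$deviance < 1e-18) break  # exact fit found
  }
  if (is.null(best))
    stop("FCS fit failed after ", tried, " starts")
  best$par_full <- expand(best$par)

  converged <- best$info %in% 1:3
  params <- .unpack(best$par_full, n_species)

  # collapse a 2-species fit to 1 species when the slow species is not
  # supported: indistinguishable diffusion times, or a reduced chi-square
  # improvement below 20% over the 1-species model (the slow species then
  # only absorbs residual shape error, not a real slow component)
  if (n_species == 2) {
    fit1 <- fitFCS(curve, nSpecies = 1, restarts = restarts,
                   weighting = weighting, fixed = fixed)
    dof2 <- max(1L, sum(keep) - length(best$par))
    chi2 <- best$deviance / dof2
    ratio <- chi2 / fit1@redChiSq
    if ((params@tauD[2] / params@tauD[1] - 1) < 0.01 ||
        params@alpha[2] < 5e-3 ||
        !is.finite(ratio) || ratio > 0.8) {
      fit1@diagnostics$collapsed_from_2_species <- TRUE
      fit1@diagnostics$chi_ratio_2_vs_1 <- ratio
      return(fit1)
    }
  }

  dof <- max(1L, sum(keep) - length(best$par))
  red_chi <- best$deviance / dof
  se_free <- tryCatch({
    cv <- solve(best$hessian) * red_chi
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, length(best$par)))
  se <- rep(0, length(p0))  # fixed parameters carry zero uncertainty
  se[free_idx] <- se_free
  # delta-method back-transform for log10-scale parameters
  nat <- c(params@N, params@Tds, params@tauDs, params@tauD[1])
  logsc <- c(TRUE, FALSE, TRUE, TRUE)
  if (n_species == 2) {
    nat <- c(nat, params@alpha[2], params@tauD[2])
    logsc <- c(logsc, FALSE, TRUE)
  }
  se_nat <- ifelse(logsc, se * nat * log(10), se)
  names(se_nat) <- if (n_species == 1)
    c("N", "Tds", "tauDs", "tauD") else
    c("N", "Tds", "tauDs", "tauD1", "alphaSlow", "tauD2")

  new("FCSFit", params = params, se = se_nat, redChiSq = red_chi,
      nSpecies = n_species, converged = converged,
      meanRate = curve@meanRate, totalPhotons = curve@totalPhotons,
      diagnostics = list(info = best$info, message = best$message,
                         niter = best$niter, starts = tried,
                         fixed = fixed))
}

# 1-vs-2 species choice: try the richer model, keep it only if the slow
# species survives the collapse rule; the long-lag residual t statistic of
# the 1-species fit is attached as a diagnostic
.fitFCSAuto <- function(curve, restarts, weighting = "uniform",
                        fixed = list()) {
  fit <- tryCatch(fitFCS(curve, nSpecies = 2, restarts = restarts,
                         weighting = weighting, fixed = fixed),
                  error = function(e) NULL)
  if (is.null(fit))
    fit <- fitFCS(curve, nSpecies = 1, restarts = restarts,
                  weighting = weighting, fixed = fixed)
  tau_d <- fit@params@tauD[1]
  w <- .fitWeights(curve, "estimated")
  long <- curve@lags > 10 * tau_d
  if (sum(long) >= 5) {
    base <- fit@params
    if (fit@nSpecies == 2L) {  # structure left after the fast species only
      base <- fcsParams(N = base@N / base@alpha[1], tauD = base@tauD[1],
                        Tds = base@Tds, tauDs = base@tauDs)
    }
    r <- (curve@g[long] -
            evalFCSModel(curve@lags[long], base)) / w[long]
    fit@diagnostics$long_lag_tstat <- mean(r) / (sd(r) / sqrt(length(r)))
  }
  fit
}

#' Fast / slow amplitude fractions of a correlation fit
#'
#' The relative amplitude of the slow diffusion component is the sticking
#' metric: it reflects the fraction of the correlation amplitude
#' contributed by surface-adhering molecules, while the fast fraction
#' tracks diffusion-limited transits. Without sticking the fast fraction
#' approaches 100%.
#'
#' @param fit an [FCSFit-class]
#' @return named numeric `c(fast = , slow = )` in percent; a 1-species fit
#'   returns `c(100, 0)`.
#' @export
stickingFractions <- function(fit) {
  stopifnot(is(fit, "FCSFit"))
  if (fit@nSpecies == 1L) return(c(fast = 100, slow = 0))
  c(fast = 100 * fit@params@alpha[1], slow = 100 * fit@params@alpha[2])
}

#' Molecule number and brightness per molecule
#'
#' @param fit an [FCSFit-class]
#' @param curve the fitted [CorrelationCurve-class] (supplies the mean
#'   count rate)
#' @return list with `N` and `brightness` (counts/s per molecule,
#'   `meanRate / N`)
#' @export
moleculesAndBrightness <- function(fit, curve) {
  stopifnot(is(fit, "FCSFit"), is(curve, "CorrelationCurve"))
  n <- fit@params@N
  if (n <= 0) stop("fit has non-positive N")
  list(N = n, brightness = curve@meanRate / n)
}
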