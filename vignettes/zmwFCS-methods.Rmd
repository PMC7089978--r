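---
title: "Quantifying dye-induced surface adhesion in zero-mode waveguides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dye-induced surface adhesion in zero-mode waveguides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zmwFCS)
```

## The problem

Zero-mode waveguides (ZMWs) are nanoapertures — here 110 nm holes in a
100 nm aluminum film — that confine the excitation light to an attoliter,
evanescently decaying volume, enabling single-molecule fluorescence work at
up to micromolar concentrations. Their weak point is non-specific adhesion:
a labelled molecule that sticks to the aperture wall parks a fluorophore in
the brightest part of the observation volume for hundreds of milliseconds,
producing long intensity spikes, a spurious slow component in the intensity
autocorrelation, and — because the metal quenches the excited state — a
shortened fluorescence lifetime. Whether sticking occurs turns out to be
governed largely by the dye label itself: positively charged, hydrophobic
dyes (high logD) promote DNA adhesion; negatively charged hydrophilic ones
do not.

zmwFCS packages the analysis chain used to quantify this: time-tagged
photon streams in, correlation curves and TCSPC histograms in the middle,
and three headline observables out —

* the relative amplitude of the slow diffusion component in a two-species
  correlation fit (the *sticking fraction*),
* the molecule number `N`, diffusion time `tauD` and per-molecule
  brightness from the fast component,
* the intensity-weighted fluorescence lifetime and its confocal-to-ZMW
  fold change.

Because real nanoaperture photon streams are not reproducible on a desk,
the package also contains a first-class synthetic-data generator that
emulates the statistical structure the analysis relies on, with known
ground truth.

## The correlation model

Intensity fluctuation autocorrelations, `g(tau) = <dI(t) dI(t+tau)> / <I>^2`,
are fitted with a three-dimensional Brownian diffusion model with a
dark-state (blinking) term:

$$G(\tau)=\frac{1}{N}\left[1+\frac{T_{ds}}{1-T_{ds}}
  e^{-\tau/\tau_{ds}}\right]\sum_i \alpha_i
  \left(1+\frac{\tau}{\tau_{D,i}}\right)^{-1}
  \left(1+\frac{\tau}{\kappa^2\tau_{D,i}}\right)^{-1/2}$$

with the structure parameter $\kappa$ fixed at 1, the established
empirical description of ZMW observation volumes; it is never fitted.
Useful analytic anchors: $G(0) = (1/N)/(1-T_{ds})$, and for one species
with $\kappa = 1$, $G(\tau_D) = (1/N)\,2^{-1}2^{-1/2} \approx 0.3536/N$.

Without sticking a single diffusing species suffices; adhesion adds a
second, much slower component whose relative amplitude
$100\,\alpha_{slow}$ is the sticking metric (`stickingFractions()`).

### Fitting choices, and why they matter

The model above is *empirical*: no confined-aperture geometry produces it
exactly. That makes the weighting and parameter-bound choices load-bearing,
and several defaults here differ from what a naive reading would suggest.
All of them were established on noiseless theory curves (see below) before
being applied to stochastic data.

* **Uniform weights by default.** `correlateMultitau()` estimates per-lag
  uncertainties by splitting the trace into 8 blocks; those estimates track
  the *relative* error of `g`. Using them as inverse-variance weights makes
  the fit chase the far tail of the curve, where the few-percent shape
  mismatch between the empirical model and any real (or simulated)
  confined volume dominates, and the parameters degrade catastrophically.
  Uniform weighting anchors the fit on the amplitude and the main decay;
  the block estimates remain available (`weighting = "estimated"`) and
  feed the long-lag residual diagnostic.
* **Time-scale-separated bounds.** The dark-state term is confined to the
  photophysical regime ($T_{ds} \le 0.6$, $\tau_{ds} \in$ 0.1–100 µs), the
  fast species to diffusion transits ($\tau_D \in$ 1 µs–10 ms) and the slow
  species to adsorption dwells ($\tau_{D,2} \in$ 30 ms–10 s, the >100 ms
  spike regime). With looser bounds the exponential blinking term can
  impersonate the diffusion decay (it is a better match to the true
  confined-volume correlation than the model's power law), and the global
  minimum wanders to wildly biased parameters.
* **Calibrated photophysics.** In the standard workflow the blinking
  parameters are measured independently (a solution/confocal calibration of
  the dye) and held fixed in the ZMW fit: `fitFCS(..., fixed = list(Tds =,
  tauDs =))`. The pipeline (`runCondition()`) does this automatically for
  simulated conditions. Free fitting remains supported and recovers exact
  model-generated curves to better than 0.1%.
* **Model selection.** `nSpecies = "auto"` accepts the slow species only if
  it improves the reduced chi-square by at least 20% (and never when its
  amplitude is negligible or its time constant degenerates into the fast
  species). On sticking-free data the improvement is 6–9%; with sticking it
  is 70–97%, so the rule separates cleanly. This mirrors the lifetime
  module's order selection.
* Multiple seeded restarts guard against the shallow minima that long-lag
  components create; restarts are deterministic, so fits are reproducible.

Background counts dilute the correlation amplitude by
$((S+B)/S)^2$; `correctBackground()` applies the standard correction with a
separately known background rate before fitting.

## Lifetime analysis

TCSPC histograms are fitted by iterative reconvolution: the model is the
circular convolution, over the 25 ns sync window, of the (wrapped)
multi-exponential decay with the unit-normalized instrument response
(Gaussian, FWHM 38 ps or 110 ps for the green/red detection path, or a
measured histogram). Numerical details that matter:

* The IRF kernel is sampled at channel *offsets* rather than centers;
  convolving two center-sampled grids shifts the model by half a channel
  (8 ps at the default 16 ps channels), which is visible as a systematic
  lifetime bias at realistic photon counts.
* Residuals are variance-stabilized, $2(\sqrt{m} - \sqrt{c})$, which
  approximates the Poisson deviance. Weighting by $1/\sqrt{\text{observed}}$
  instead biases lifetimes low by ~3% at $10^5$ photons, because sparse
  tail channels with downward fluctuations get over-weighted.
* The fit window is `[peak - 2 FWHM, end of window]`, extended earlier
  until it holds at least 95% of the photons.
* Components faster than 20 ps — faster than either instrument response,
  hence not fluorescence — are flagged as scatter (the laser
  back-reflection spike that metal apertures produce, ~5 ps) and excluded
  from the intensity-weighted average
  $\bar\tau = \sum a_i \tau_i^2 / \sum a_i \tau_i$.
* With `nExp = "auto"` the model order (1–3) grows while an extra
  component still improves the reduced chi-square by at least 5%.

The adhesion observable is the fold change `lifetimeFoldChange(tau0,
tauZMW)` between the confocal reference and the in-aperture
intensity-weighted lifetime: about 2-fold for non-adhering conjugates,
approaching 3-fold when molecules adsorb on the metal and energy transfer
opens an extra non-radiative channel.

## The synthetic photon-stream generator

`simulateExperiment()` produces TTTR photon records with the statistical
structure the analysis assumes:

* **Geometry.** A cylinder of the aperture diameter: a reflecting floor
  (the glass bottom), reflecting metal side walls up to the film height,
  and a 150 nm solution column above. Detection is evanescent,
  $I(z) = e^{-z/\Lambda}$ with $\Lambda = 30$ nm, laterally uniform across
  the aperture.
* **Bath boundary.** The top of the column is a grand-canonical bath:
  molecules crossing it are removed, and fresh molecules enter as a Poisson
  flux with the exact crossing statistics of a uniform reservoir under one
  Brownian step (rate $C A \sigma / \sqrt{2\pi}$, Rayleigh-overshoot entry
  depths). This keeps the occupancy Poisson at `concentration x volume`, so
  the correlation amplitude is exactly `1 / (C V_eff)`. A tall
  reflecting column instead produces one-dimensional Brownian recurrence —
  a $\tau^{-1/2}$ correlation tail that the diffusion model cannot
  represent at all; the 150 nm default was chosen by scanning the exact
  eigenmode autocorrelation (below) for agreement with the fitted model.
* **Dynamics.** Brownian steps with per-axis variance $2D\,\Delta t$,
  $\Delta t$ set so the RMS step is 5 nm (wall contacts are resolved).
  Wall contacts inside the aperture adsorb with probability
  `adsorptionProbPerContact`; adsorbed molecules sit still for an
  exponential dwell (mean 0.15 s, matching the >100 ms spike
  phenomenology) and emit at a quenched brightness (~1/3 of the free
  peak brightness, consistent with the shortened lifetime near metal).
  Note the contact probability is defined per attempted crossing at the
  simulation step, so its physical meaning is tied to the 5 nm step rule.
* **Photophysics.** A two-state dark model: stationary dark fraction
  $T_{ds} = 0.2$ with dark lifetime $\tau_{ds} = 5$ µs (typical µs-scale
  photoisomerization/redox blinking; resolvable two decades above the 1 µs
  correlator base bin and well below the ~250 µs diffusion time). Photon
  emission is an inhomogeneous Poisson process; each photon's microtime is
  an exponential excited-state delay (per kinetic state) plus an IRF draw,
  wrapped into the sync period. Within one 0.42 µs step, blinking is
  applied as the exact bright-time fraction; sub-step blink correlation is
  therefore slightly smoothed.
* **Acquisition.** 40 MHz sync rate, 60 s duration, 100 nM labelled
  molecules, 200 cps uncorrelated background; macrotimes are exact integer
  sync counts. Identical seed and configuration give a bit-identical
  stream (the kernel owns a xoshiro256++ generator; R-level draws use R's
  RNG under `set.seed`).

The defaults are the benchmark acquisition conditions; `D = 30` µm²/s is a
literature-scale diffusion coefficient for a ~51 bp DNA duplex. The
per-contact sticking probability for an untreated surface
(`defaultStickingProb("none")` = 2.5e-5) was calibrated once so that the
fitted slow-component amplitude of the default acquisition is ~20%, the
untreated-metal regime for an adhesive dye; surface treatments scale it
(BSA, PEG 500: half; PEG 5000: no improvement; PEG 1000, PVPA: zero), and
non-adhesive dyes never stick regardless of surface.

### Ground truth and recovery references

Three deterministic references accompany the generator:

* `expectedMoleculeNumber()` — $N = C\,V_{eff}$,
  $V_{eff} = (\int I)^2/\int I^2 \approx 2 A \Lambda$.
* `expectedDiffusionTime()` — the lag at which the *exact* axial
  autocorrelation of $e^{-z/\Lambda}$ under reflected Brownian motion with
  the absorbing bath top (a cosine eigenexpansion with closed-form
  coefficients) decays to $2^{-1}2^{-1/2}$, the decay point that defines
  $\tau_D$ in the fitted model. The simulated trajectory correlation
  matches this eigenexpansion to better than 1%.
* `expectedFCSRecovery()` — the asymptotic estimand: the exact theory
  curve projected onto the fitted model by the same deterministic fit the
  pipeline uses. Because the model is an empirical description of a
  confined volume, the projection sits systematically off the physical
  values — about +14% in `N` and +9% in `tauD` under the default geometry.
  Parameter-recovery tests therefore measure the scatter of the stochastic
  pipeline around the estimand; the projection offset itself is a
  deterministic, quantified property of the model, not noise.

For sticking, `trueSlowFraction()` computes an estimator-independent
zero-lag amplitude fraction from the simulator's event log:
$S/(S+F)$ with $S = T^{-1}\sum_e b_e^2 \tau_e$ (the filtered-Poisson
variance of the adsorbed-emission process) and $F = \bar B^2 C \int I^2$
(the free-diffusion amplitude in closed form); blinking boosts both terms
equally and cancels. The *fitted* slow amplitude sits systematically some
20–40% (relative) above this zero-lag fraction, because a power-law model
species extrapolates an exponential-dwell correlation upward, and because
rebinding and free-to-adsorbed correlations of the same molecule add slow
structure that a zero-lag decomposition does not count. The amplitude
metric, in other words, *reflects* the amount of sticking rather than
measuring it on an absolute scale — which is exactly how it should be read
on real data too.

### What the generator does not emulate

Detector dead time and afterpulsing; spectral crosstalk; photobleaching;
the electromagnetic mode structure of the aperture (the lateral profile is
uniform, the axial profile a single exponential, and fluorescence
enhancement is folded into one brightness number); heavy-tailed adsorption
dwell distributions (dwells are exponential by construction); and 3D
return paths through the reservoir beyond one box height (the bath
boundary erases them). Passing recovery tests therefore demonstrate that
the analysis chain is internally correct and unbiased *for data obeying
the stated model*, not that real nanoaperture data meet these tolerances.

## Problem sizes used in tests

Unit tests run on 1–20 s simulated acquisitions and $10^4$-bin traces; the
end-to-end recovery checks use five full 60 s acquisitions per condition
(the benchmark acquisition length) at ~1–3 kcps, $10^5$–$2\times10^5$
photon decay histograms, and 20 randomized traces for the
correlator-oracle comparison. These sizes keep each check's sampling error
several times smaller than the tolerance it asserts.

## A worked condition

```{r, eval = FALSE}
cfg <- conditionConfig("Atto647N", "none", duration = 60, seed = 1)
spec <- conditionSpec("Atto647N", "none", config = cfg)
row <- runCondition(spec, verbose = TRUE)
row[, c("slow_pct", "tau_d_fast_us", "n_molecules", "avg_lifetime_ns",
        "fold_change")]
```

`compareConditions()` ranks a set of such rows by slow amplitude (least
sticking first) and attaches deltas against the best-passivated baseline;
`renderReport()` writes the CSV and a text summary.
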