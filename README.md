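# zmwFCS

Quantifying dye-induced surface adhesion in zero-mode waveguides from
time-tagged photon streams.

Zero-mode waveguides (ZMWs) — subwavelength nanoapertures (here 110 nm
holes in a 100 nm aluminum film) — confine light to an attoliter
evanescent volume and make single-molecule fluorescence possible at high
concentrations. Their practical failure mode is non-specific adhesion:
a labelled molecule that sticks to the aperture wall produces long
(>100 ms) fluorescence spikes, a spurious slow component in the intensity
autocorrelation, and a metal-quenched, shortened fluorescence lifetime.
Whether that happens is driven largely by the fluorescent label
(positively charged, hydrophobic dyes such as Atto 550 and Atto 647N
adhere; negatively charged hydrophilic Alexa 546/647 do not) and by the
surface passivation (PEG 1000 and PVPA suppress it; BSA, PEG 500 and
PEG 5000 do not, or only partially).

zmwFCS is an R package, for single-molecule spectroscopists and method
developers, that implements the full quantification chain:

* **Photon data** — S4 classes for TTTR photon records, binned intensity
  traces, TCSPC histograms and instrument response functions, with a
  plain-text interchange format.
* **Correlator** — a multi-tau autocorrelator (m = 16 lags per octave,
  C++ kernel) with block-splitting uncertainty estimates, plus a direct
  double-sum reference implementation used as its oracle.
* **FCS model** — the 3D Brownian diffusion + dark-state model for ZMW
  volumes,

  ```
  G(tau) = (1/N) [1 + Tds/(1-Tds) exp(-tau/tau_ds)]
           * sum_i alpha_i (1 + tau/tau_D,i)^-1 (1 + tau/(kappa^2 tau_D,i))^-1/2
  ```

  with the structure parameter fixed at kappa = 1, fitted with one or two
  diffusing species (Levenberg–Marquardt). The relative amplitude of the
  slow species, `100 * alpha_slow`, is the sticking metric; `N`, `tau_D`
  and the per-molecule brightness come from the fast species.
* **Lifetime** — IRF-reconvolved multi-exponential TCSPC fits with a 95%
  photon time gate, automatic exclusion of ultrafast (~5 ps)
  back-reflection scatter, intensity-weighted average lifetimes
  `sum(a tau^2)/sum(a tau)`, and the confocal-to-ZMW fold change
  `tau0 / tauZMW` (about 2-fold without adhesion, approaching 3-fold when
  molecules park on the metal).
* **Simulator** — a first-class synthetic photon-stream generator:
  Brownian diffusion through the aperture with a grand-canonical bath
  boundary, transient wall adsorption with exponential dwells, two-state
  blinking, state-dependent excited-state decay and IRF jitter. Known
  ground truth (`expectedMoleculeNumber`, `expectedDiffusionTime`,
  `expectedFCSRecovery`, `trueSlowFraction`) makes every estimator
  testable.
* **Benchmark** — dye-by-passivation condition orchestration
  (`runCondition`, `compareConditions`, `renderReport`) and a thin CLI
  (`inst/cli/zmwfcs.R`) with `simulate`, `bin`, `correlate`, `fit-fcs`,
  `fit-decay` and `benchmark` subcommands.

See the methods vignette (`vignettes/zmwFCS-methods.Rmd`) for the models,
their assumptions, and the numerical choices.

## A worked example

Simulate the adhesive red dye on an untreated aperture at the benchmark
acquisition conditions (60 s, 100 nM, 40 MHz sync) and run the full
pipeline:

```r
library(zmwFCS)
cfg  <- conditionConfig("Atto647N", "none", duration = 60, seed = 1)
spec <- conditionSpec("Atto647N", "none", config = cfg)
row  <- runCondition(spec)
row[, c("slow_pct", "tau_d_fast_us", "n_molecules",
        "avg_lifetime_ns", "fold_change")]
#>  slow_pct tau_d_fast_us n_molecules avg_lifetime_ns fold_change
#>  19.69013      223.2426  0.05948739        1.571803    2.544849
```

The two-species fit assigns ~20% of the correlation amplitude to the slow
(adsorption) component — the untreated-surface regime — and the average
lifetime is pulled down by the quenched adsorbed population. Adding a
PVPA-passivated condition and comparing:

```r
cfg2 <- conditionConfig("Atto647N", "PVPA", duration = 60, seed = 2)
row2 <- runCondition(conditionSpec("Atto647N", "PVPA", config = cfg2))
rep  <- compareConditions(list(row, row2))
renderReport(rep, "report.csv")
#> condition             fast%   slow%  tauD(us)       N   tau(ns)  ratio
#> Atto647N / PVPA       100.0     0.0    287.65  0.0402      1.73   2.31
#> Atto647N / none        80.3    19.7    223.24  0.0595      1.57   2.54
```

Passivation removes the slow component entirely; on the untreated surface
the apparent molecule number is inflated (+48% here) and the diffusion
time distorted — the two classic sticking artefacts — and the lifetime
fold change moves from the ~2.3 free-diffusion value toward the
adhesion-quenched regime.

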