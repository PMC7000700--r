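---
title: "Methods: FLT-FRET screening analysis and fiber validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLT-FRET screening analysis and fiber validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

# Scope and model

`fretscreen` implements the analysis chain of a fluorescence-lifetime (FLT)
FRET high-throughput screen against the ryanodine receptor (RyR), together
with its downstream validation computations. The screen's readout is the
donor fluorescence lifetime of a FRET pair (donor-labeled FKBP, acceptor-labeled
calmodulin) bound to RyR in sarcoplasmic-reticulum membranes: compounds that
change the structure of the complex change the donor-to-acceptor distance and
hence the donor lifetime. The package covers, in order:

1. **Waveform fitting.** Per-well decay waveforms are modeled as a flat
   background plus a mono-exponential, $c(t) = b + A e^{-t/\tau}$, fitted by
   Levenberg–Marquardt least squares with Poisson weights
   $w_i = 1/\max(c_i, 1)$. FRET efficiency is the fractional donor-lifetime
   decrease, $E = 1 - \tau_{DA}/\tau_D$.
2. **Plate-screen analysis.** 1536-well plates (32 × 48) with library
   compounds in 40 columns (1280 wells) and DMSO controls in 8 columns
   (256 wells). Per run, three physically distinct plates are read:
   donor-acceptor, donor-only, and unlabeled. E is computed per
   donor-acceptor well against the donor-only plate's DMSO mean lifetime,
   normalized as $E/E_0$ against the plate's DMSO mean E; hits change
   $E/E_0$ by strictly more than 4 control SDs and must survive two
   false-hit filters (donor-only lifetime and unlabeled-spectrum integrated
   intensity, each at 3 control SDs). Reproducible hits recur with the same
   sign in at least 2 of 3 runs. QC comprises the Z′ screening-window
   statistic, a Gaussian fit of the pooled $E/E_0$ distribution, and per-run
   hit rates.
3. **Dose-response.** Four-parameter Hill fits on log concentration,
   $R(c) = bottom + (top - bottom)/(1 + (c/IC_{50})^h)$, for FRET and
   radioligand-binding series, plus a biphasic-response detector.
4. **Buffer chemistry.** A 1:1 Ca–EGTA equilibrium solver replacing the
   chelator-calculator step that sets assay free Ca²⁺.
5. **Fiber calcium.** Rhod-5N calibration
   $[\mathrm{Ca}^{2+}] = K_d (F - F_{min})/(F_{max} - F)$, plateau
   steady-state extraction, the tetracaine-referenced leak fraction, and
   peak analysis of electrically evoked F/F₀ transients.

Every input the pipeline consumes can be generated in-package, so the whole
chain is testable without instrument recordings.

# The synthetic screen and what it emulates

`screen_sim_config()` fixes the study conditions: 3 runs, a 1280-compound
library on the default layout, and a narrow Gaussian $E/E_0$ distribution
with $\mu = 1.004$ and $\sigma = 0.016$. Two centering choices deserve
explanation:

* **DMSO wells draw around 1, compound wells around `control_mu`.** $E/E_0$
  is by construction centered at 1 for the controls (they define $E_0$), so
  the slight positive offset of the observed compound-well distribution
  (1.004) is a property of the library wells relative to DMSO. Drawing
  controls at `control_mu` would be self-defeating — normalization would
  re-center everything at 1.000 and the offset could never be observed.
* **Lifetimes derive from E.** Each well's $E/E_0$ draw is converted to a
  lifetime via $\tau_{DA} = \tau_D (1 - E)$ with $E = E_{base} \cdot E/E_0$;
  the E/E₀ draw is the *total* well-to-well variability, so the recovered
  Gaussian width matches the generating $\sigma$ without double-counting
  noise sources.

Defaults not printed in the study were set once to representative values: a
4.0 ns donor lifetime (typical of fluorescein-family donors), a baseline
FRET efficiency of 0.2 at the sub-saturating acceptor concentration, a
0.5 % well-to-well lifetime CV (which reproduces the reported Z′ class of
0.8–0.9 for DMSO vs suramin plates), and a 1 % CV on unlabeled-spectrum
intensity. The read time defaults to 120 min, the read at which hit effects
are largest.

**The demonstration effect table** (`demo_effect_table()`) ships 17 strong
modulators (10–16 SD shifts, both signs) and 5 marginal ones. Run-to-run
variability is modeled as independent noise redraws with identical true
effects — except that the marginal compounds carry their 7 SD effect in
exactly two of the three runs. A purely noise-driven marginal compound
(effect ≈ 4–5 SD in all runs) would make the demo's defining outcome — 17
compounds hitting in all runs, 22 in at least two — a coin flip; the
active-run mask makes the outcome structural, modeling compounds with
genuinely inconsistent activity. Similarly, effect-table compounds are
genuine FRET modulators with no companion-plate artifact, so their
donor-only and unlabeled draws are truncated at |z| ≤ 2.5: a chance draw in
a companion plate cannot contradict the scenario's construction. Compounds
*with* real artifacts are specified explicitly via `donor_only_effects` /
`intensity_effects`.

What the generator does **not** emulate: spatial plate effects (edge
evaporation, dispenser gradients), read-time drift, correlated run-to-run
compound effects, compound fluorescence spectra (only integrated
intensities), and multi-exponential photophysics. Passing tests therefore
demonstrate correctness of the analysis chain under idealized Gaussian
well statistics, not robustness to spatially structured artifacts — which
the screen's own design addresses with in-plate controls rather than
post-hoc correction.

# Numerical choices

* **Lifetime fitting** initializes deterministically: background from the
  mean of the last 10 % of bins, then $(A, \tau)$ from a log-linear
  regression of background-subtracted counts. The same data always give the
  same fit. Non-convergence returns a flagged result carrying the initial
  estimates, never an exception. An instrument response function is not
  modeled (delta-IRF): the screen consumes *relative* lifetime changes, for
  which IRF convolution is immaterial at the 0.05 ns binning used here.
* **Hit threshold boundary.** "More than 4 SD" is implemented as a strict
  inequality; a compound at exactly 4.000 SD is not a hit.
* **Hill fitting** works on $\log_{10} c$ with deterministic starts
  (asymptotes from the extreme-concentration means, $IC_{50}$ from the
  midpoint crossing, slope 1). The $IC_{50}$ SE comes from the delta method
  on $\log_{10} IC_{50}$. Fits with $SE(IC_{50})/IC_{50} > 1$ warn as
  poorly constrained (typically monotone data without a plateau inside the
  tested range). Both the 4-parameter and the slope-fixed 3-parameter
  variants are available.
* **Biphasic detection** uses a peak-contrast statistic on the
  per-concentration means (the smaller of the two excursions from the
  lowest mean on either side of a candidate turning point, maximized over
  interior points) with its null distribution obtained by parametric
  bootstrap around the best monotone description of the data (isotonic
  regression, both directions, pooled within-concentration noise). A naive
  lack-of-fit F-test against the Hill fit is badly miscalibrated here
  because the 4-parameter Hill model is degenerate under a flat truth; the
  bootstrap construction holds the null flag rate at the nominal 5 % level
  while flagging rise-then-fall series decisively.
* **Free calcium** is the positive root of the 1:1 binding quadratic,
  computed in the cancellation-free form. The apparent Ca–EGTA $K_d$
  defaults to 431.5 nM, calibrated so that 65 µM total Ca in 1 mM EGTA
  gives 30 nM free Ca²⁺ at the assay's pH 7.0 / 150 mM KCl conditions. The
  companion condition (1.02 mM total → 30 µM free) implies ≈ 303 nM: full
  chelator calculators apply pH, ionic-strength and competing-ion
  corrections that a single-constant 1:1 model absorbs into $K_d$, which is
  why the constant is a parameter rather than a hard-coded value. Mg²⁺/ATP
  competition is out of scope.
* **Plateau extraction** averages the final 20 % of an inter-event window
  and flags non-plateau segments when the fitted linear drift over that
  window exceeds 2 % of the trace's fluorescence range. Both fractions are
  configurable; the defaults give sub-percent steady-state error once ~5
  time constants have elapsed for typical solution-change step sizes.
* **Transient peaks** use a 100 ms post-stimulus search window and a 200 ms
  pre-stimulus baseline — unambiguous at 1 Hz pacing sampled at 2 ms per
  line.
* **Leak fractions** below the tetracaine floor are kept (negative) and
  flagged `beyond_tetracaine`; they indicate off-target effects on
  t-system Ca²⁺ handling, as seen with 10 µM myricetin, and zeroing them
  would hide exactly that finding.

# Error propagation in the pooled-Gaussian QC

Each well's $E/E_0$ divides by its plate's *estimated* control mean, so the
pooled-mean estimator carries a plate-level variance component
$\sigma^2/(n_{ctrl}\, n_{runs})$ beyond the usual $\sigma^2/n$.
`screen_gaussian_qc()` reports both the plain MLE standard errors and the
propagated `se_mu_total`; recovery checks on the mean use the latter, since
ignoring the normalization wobble would understate the estimator's true
sampling error by a factor of ~2.5 at the default plate geometry.

# Problem sizes used in the test suite

The suite exercises the pipeline at the study's native scale where that is
cheap (3 × 1536-well runs; 8-concentration, n = 4 dose designs) and at
reduced Monte-Carlo depth where full fidelity is unnecessary for the
property under test: 100–200 replicates for lifetime-estimator bias and
$IC_{50}$ recovery, $10^5$ wells for the 4-SD tail check, 399 bootstrap
draws in the biphasic detector. All stochastic tests fix their seeds.

# Known limitations

* The one-exponential lifetime model is a deliberate simplification of a
  multi-component physical decay; the bi-exponential lack-of-fit test shows
  the residual diagnostic detects gross violations, but subtle
  multi-exponential structure biases $\tau$ and, by design, cancels in the
  $E/E_0$ ratio only to first order.
* Per-compound library effect sizes are not public; the demonstration
  scenario reproduces the *structure* of the screen outcome (hit counts,
  rates, reproducibility classes), not per-compound values.
* Whether the original analysis applied its SD thresholds to E or to
  $E/E_0$, and per-plate or pooled, is not fully specified; this package
  defaults to per-plate thresholds on $E/E_0$ (the normalized quantity it
  plots and reports), with the raw-E mode available by calling the same
  functions on unnormalized columns.
* Fiber analyses report per-trace metrics; pooling across fibers (and any
  fiber-to-fiber normalization) is left to the caller.
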