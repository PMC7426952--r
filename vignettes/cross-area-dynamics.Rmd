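---
title: "Identifying shared and local cortical population dynamics with crossdyn"
author: "crossdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying shared and local cortical population dynamics with crossdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdyn)
```

## The scientific problem

During skilled forelimb movements, premotor cortex (M2) and primary motor
cortex (M1) are simultaneously active, and part of their population activity
is shared between the areas on a moment-to-moment basis. `crossdyn`
implements an analysis pipeline for simultaneously recorded spike trains from
two such regions:

1. **Cross-area dynamics.** Canonical correlation analysis (CCA) on binned,
   trial-concatenated, mean-subtracted spike counts finds paired unit-weight
   vectors — canonical variables (CVs) — whose projections are maximally
   correlated between the regions. The span of the significant CV weights in
   each region is that region's *cross-area subspace* (CS).
2. **Significance by trial shuffling.** A CV is significant when its tenfold
   cross-validated $R^2$ (squared Pearson correlation of the paired held-out
   projections) exceeds the 95th percentile of a null distribution built by
   permuting one region's trials before concatenation. The shuffle preserves
   within-trial structure and trial-averaged (peri-event) modulation while
   destroying moment-to-moment inter-area correspondence, so it controls
   exactly for the correlation that time-locked movement modulation alone
   would produce.
3. **Local dynamics.** Each region's *local* activity is the magnitude of the
   population vector's projection onto the orthogonal complement of its CS.
   Per-trial timing of local activity is compared between regions with
   permutation tests.
4. **Behavioral coupling.** The single-trial coupling of the CS signal to
   reach behavior is quantified by a d′ modulation statistic, its regression
   on reach duration, median pre-reach/initiation separability, and logistic
   regression detection of reach initiation scored by ROC/AUC.
5. **Group inference.** Hierarchical (animal-level, then trial-level)
   bootstrap tests and factor-analysis shared-over-total variance summaries.

Because raw recordings of this kind are typically not deposited, the package
ships a synthetic session generator with planted ground truth; every stage of
the pipeline is validated against what was planted.

## The generative model of the synthetic session

Each unit $u$ in region $r$ spikes as an inhomogeneous Poisson process with a
log-link rate

$$\lambda_u(t) \;=\; b_u \exp\!\big(w^{S}_u\, a_i\, z_i(t)\;+\;w^{L}_u\, a_L\, \ell_{r,i}(t)\big),$$

where $b_u$ is a per-unit baseline (uniform on 2–15 Hz), $z_i(t)$ is a
Gaussian bump peaking at the trial's reach start whose width scales with
reach duration, and $\ell_{r,i}(t)$ is the region-local transient. The
per-trial shared amplitude is duration-coupled,
$a_i = a_{\text{stage}} (d_i/d_{\text{ref}})^{\beta}$ with $\beta = -0.25 <
0$: faster (shorter) reaches carry larger shared amplitude. The M2 local
transient leads the M1 one by 100 ms on average.

Design choices that matter, and why:

* **Log link.** Guarantees positive rates and is the standard generative
  model for spike simulation. A consequence worth knowing: the *count-space*
  signal direction is $b \odot w^S$ distorted by the curvature of
  $\exp$, so linear CCA weights recover the planted loading only
  approximately — the planted-axis angle plateaus near 20–25° at realistic
  amplitudes however much data is supplied. This is an identifiability
  property of the generative model, not an estimation bug; tests that assert
  a tighter angle document the gap.
* **Shared loadings orthogonal to the baseline vector.** The shared axis is
  drawn orthogonal to $(b_1,\dots,b_p)$, i.e. shared dynamics are *balanced*
  and do not change total population rate. Without this, the Poisson noise
  variance (proportional to rate) acquires a session-random time course that
  contaminates magnitude-based local-timing measures.
* **All-positive local loadings with per-unit offsets.** Reach-locked local
  transients are excitatory population-wide, with each unit's transient at a
  small fixed offset (sd 0.02 s) around the region's local latent time —
  sequential activation in miniature. This makes the local *variance* bump
  coherent in time, so the residual-magnitude trajectory carries the planted
  lead.
* **Stage-dependent trial jitter of the local transient** (sd 0.40 s early,
  0.20 s late). Early, exploratory movements are behaviorally variable;
  skilled movements are stereotyped. The jitter is what separates early from
  late detection AUC (about 0.67 vs 0.88 at the defaults) while leaving
  single-trial local transients strong.
* **Amplitudes** ($a_{\text{early}} = 1.0$, $a_{\text{late}} = 3.5$,
  $a_L = 3.0$) were chosen once so that the pipeline's outputs land on the
  scale reported for real rat M2–M1 recordings — top-CV cross-validated
  $R^2 \approx 0.3\text{–}0.4$, CA-modulation d′ around 0.7 early and 2.9
  late, detection AUC 0.67/0.88 — and were then frozen.
* **Behavioral parameters are the published ones.** Mean reach durations
  0.30 s (early), 0.20 s (late), 0.18 s (baseline), 0.29 s (perturbed);
  reaction times 32.23/0.89/1.26/3.23 s as shifted exponentials; success
  rates 27.3/57.6/56.8/37.5 %. Durations are log-normal with
  $\sigma_{\log} = 0.35$, a realistic trial-to-trial spread.
* **Rates are clipped at 200 Hz** (with a warning) and spikes closer than
  1 ms are removed (dead time). Perturbation (muscimol-style) sessions set
  the shared amplitude to 0.

Two subtleties discovered while validating the pipeline are worth spelling
out, because both are properties of the science rather than of the code:

* **"No shared latent" is not "no shared information."** Local transients are
  anchored to reach start while analysis windows align to grasp onset, so the
  trial's reach duration shifts both regions' local activity together: even
  with the shared amplitude at zero, the two regions carry common,
  trial-varying behavioral information, and the trial-shuffle test correctly
  flags a significant CV in well over 5% of such sessions. Calibration of
  the significance machinery therefore uses sessions with *all* latent
  amplitudes at zero — the exchangeable null the test's guarantee refers
  to — and the elevated rate under duration coupling is documented here as a
  feature of the test, not an error.
* **d′ tracks the planted amplitude only when the latent bump is matched to
  the reach window.** With a narrow bump, the signal rises and falls inside
  the reach window, so the reach-segment standard deviation grows with
  amplitude and d′ compresses (roughly d′ ∝ a^0.8), flattening the measured
  duration–modulation slope; with a too-wide bump the tail leaks into the
  baseline window and over-steepens it. The duration-coupling recovery
  experiment uses a kernel width of 0.20 s at the reference duration, chosen
  so that a β = 0 control shows no spurious duration dependence; the
  calibration target is that null control.

The `symmetricRegions` option re-uses one region's baseline and loading draws
for the other (spiking stays independent). This makes the two regions
exchangeable and is the correct null construction for calibrating the timing
permutation test, which assumes exchangeability; with independent unit draws
a zero-lag session still has genuine (if incidental) timing asymmetries that
the test rightly detects.

### What the generator does *not* emulate

Refractoriness beyond a fixed dead time, bursting, non-Poisson count
dispersion, slow drift and electrode instability, behavioral covariates
beyond reaction time/duration/success, and — importantly — *ongoing* shared
dynamics outside reach events: in real data, cross-area correlation is
similar during spontaneous behavior and reaching, whereas here shared
activity is reach-locked. Passing tests therefore certify the machinery on a
known model, not the biology of any particular dataset.

## Conventions and numerical choices

* **Times are seconds; bin widths are milliseconds** at every API boundary.
* **Bins are half-open** $[t, t+\Delta)$; a spike exactly on a window's right
  edge is excluded.
* **z-scoring** uses the sample (n−1) standard deviation; zero-variance
  units map to zeros, not `NaN`.
* **CCA** is computed from Cholesky-whitened covariances with a relative
  $10^{-12}$ diagonal jitter; zero-variance units are dropped (weights
  reported as 0) and remaining rank deficiency is removed by pivoted QR,
  with warnings. Canonical correlations are clamped to $[0,1]$; training
  projections of CV $j$ correlate at exactly $\rho_j$.
* **CV signs** are not identified by CCA. `sessionCCA()` orients each CV
  pair jointly so the region-A projection averaged over a reach-initiation
  window (default −0.6 to +0.2 s relative to grasp) is nonnegative. All
  sign-sensitive comparisons align first (subset models in
  `weightStability()` align by maximal weight dot product).
* **Cross-validated $R^2$** partitions rows into ten folds *ignoring trial
  structure*, matches CVs across folds by index, and averages the squared
  held-out projection correlation. Cross-fold CV matching by index is a
  documented limitation: if two CVs swap order between folds their averages
  mix.
* **The shuffle null is cross-validated by default.** Whether the null fits
  should also be cross-validated is genuinely open; we default to the
  cross-validated null because only then are observed and null statistics
  exchangeable under the null, giving an exact ~5% family positive rate
  (verified on amplitude-0 sessions). `nullType = "training"` provides the
  faster training-fit null, which is conservative. Identity permutations are
  re-drawn; all permutation and shuffle p-values use the +1 correction and
  can never be exactly zero.
* **d′ (CA-modulation)** implements the published denominator literally:
  $d' = (\mu_r - \mu_b) / \tfrac12\sqrt{\sigma_r + \sigma_b}$ with $\sigma$
  the *standard deviations* — under the square root their sum, halved. This
  differs from the textbook pooled form and scales as $\sqrt{c}$ when the
  signal is scaled by $c$ (asserted in tests as evidence of faithful
  implementation). Whether $\sigma$ was meant as a variance cannot be
  resolved from the text, so `variant = "pooled"` offers
  $\sqrt{(\sigma_r^2 + \sigma_b^2)/2}$ for sensitivity analysis; the printed
  form is the default. The baseline-period median is subtracted from both
  segments first.
* **Windows.** Reach period: −0.1 s before reach onset to +0.1 s after grasp
  onset; baseline: equal length, ending 1 s before the reach period.
  Pre-reach: −2 to −0.1 s; initiation: −0.1 to +0.3 s around reach start.
  Pre-reach windows truncate at the door-open cue when reaction time is
  under 2 s (counted); trials whose baseline precedes the recording are
  dropped (counted). Trials missing events are dropped, never imputed.
* **Median timing** of a local-magnitude trajectory is the magnitude-weighted
  median (smallest bin-center time where the cumulative magnitude reaches
  half the total) on the −1 to +1 s peri-grasp window; trajectories are
  z-scored across the session and negative values clipped at 0 before
  weighting. The timing window and weighting are configurable. The statistic
  is deliberately parameter-free, at a cost: the clipped noise floor dilutes
  a planted 100 ms lead to roughly −75 ms measured.
* **Detection** uses maximum-likelihood logistic regression on the two CS
  channels by default (whether one or both regions' CS drove the published
  analysis is ambiguous; both are supported). Perfect separation falls back
  to a small L2 ridge, flagged. AUC is the rank statistic (ties averaged),
  computed in-sample by default with the ROC over all thresholds.
* **Hierarchical bootstrap** resamples animals with replacement, then values
  within each sampled animal *within condition*, preserving each animal's
  condition composition; the statistic is pluggable (difference of condition
  means by default, as most analyses use; difference of medians can be
  passed). One-sided p-values floor at $1/n$ (0.0001 at $10^4$ resamples),
  two-sided at $2/n$.
* **Factor analysis** is fit by EM on the sample covariance with private
  variances floored at $10^{-6}$ of each unit's variance; the log-likelihood
  is nondecreasing by construction and checked. $k = 3$ by default;
  leave-one-out selection of $k$ is out of scope. Only rotation-invariant
  quantities (shared/private variances, their ratio) are contract-bearing.
  On independent units the ML solution itself shows a finite-sample floor of
  spurious shared variance (~0.05–0.1 at 5000 rows), which the tests compare
  against `stats::factanal` rather than against zero.
* **Lag sweep** grids bin widths {100, 75, 50} ms against lags within
  ±500 ms stepped by one bin; positive lag shifts region B's window later,
  so a latent in B that trails A by $\delta$ peaks at lag $+\delta$.

## Problem sizes used by the tests and the acceptance script

Simulation experiments use compact sessions chosen to keep the whole suite
comfortably reproducible on a laptop-class single core: null calibration uses
200 sessions of 8 units/region × 25 trials with 500 shuffles (100 sessions of
10 units × 30 trials with 400 shuffles in the script); axis recovery uses 40
units × 300 trials with 60-shuffle significance;
timing power and level use 20 units × 200 trials with 1000 permutations;
detection ordering uses 25 units × 100 trials per stage; duration-coupling
recovery uses 500 trials across two synthetic animals; factor-analysis
recovery uses 15 units × 10^4 rows. Test sessions shorten reaction times
(means 2/0.9 s) to keep recordings small; all other defaults are untouched.

## Known limitations

* Linear CCA under the log-link generator recovers the planted loading
  direction only up to the curvature bias discussed above; recovery is
  excellent in correlation terms (one significant CV, top-CV $R^2$ at the
  planted level) while the weight-vector angle saturates near 20–25°.
* Local-timing estimates are diluted toward zero by the clipped noise floor;
  between-region *differences* keep their sign, and the permutation test is
  exact under exchangeability, but absolute lead magnitudes are
  underestimated.
* The spike-train d′ inherits the non-standard scaling of the published
  denominator; comparisons across signals of very different scale should use
  the pooled variant.
* No NWB ingestion; sessions enter via the TSV interchange format or the
  generator.
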