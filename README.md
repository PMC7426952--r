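# crossdyn

Cross-area neural population dynamics from paired spike recordings.

`crossdyn` is for systems neuroscientists analyzing simultaneous extracellular
recordings from two cortical regions — canonically rat premotor (M2) and
primary motor (M1) cortex during a reach-to-grasp task — who want to separate
*shared* (cross-area) from *local* population dynamics and relate both to
single-trial behavior.

## What it computes

Given per-unit spike times and a trial event table (door-open cue, reach
start, grasp onset), the pipeline:

* bins spikes (100 ms default) around grasp onset, concatenates trials and
  mean-subtracts, and fits **canonical correlation analysis**: paired weight
  vectors \(a_j, b_j\) maximizing \(\mathrm{corr}(X_{M2} a_j,\, X_{M1} b_j)\).
  The projections are the **cross-area dynamics**; the span of the
  significant weight vectors is each region's cross-area subspace (CS);
* assesses CV significance against a **trial-shuffle null** (one region's
  trials permuted before concatenation, 10^4 shuffles by default), comparing
  each CV's tenfold cross-validated R² with the null's 95th percentile;
* computes **local dynamics** as the magnitude of the population vector's
  projection onto the orthogonal complement of the CS, with per-trial
  magnitude-weighted median timing and permutation tests
  (10^5 permutations by default) for the M2-leads-M1 hypothesis and for
  learning-related tightening of the inter-area lag;
* quantifies single-trial behavioral coupling: the **CA-modulation d′**
  statistic
  \(d' = (\mu_{\text{reach}} - \mu_{\text{base}}) / \tfrac12\sqrt{\sigma_{\text{reach}} + \sigma_{\text{base}}}\),
  its log–log regression on reach duration, median pre-reach/initiation
  separability, and **logistic-regression detection of reach initiation**
  scored by ROC/AUC;
* runs group-level statistics: **hierarchical bootstrap** (animals, then
  trials; p-value floors 0.0001 one-sided / 0.0002 two-sided at 10^4
  resamples) and **factor-analysis shared-over-total variance** (EM, k = 3);
* and provides a **synthetic two-region session generator** — inhomogeneous
  Poisson spiking driven by a duration-coupled shared latent plus lagged,
  jittered local latents — with full ground truth for validating every stage.

See `vignettes/cross-area-dynamics.Rmd` for the model, conventions and
numerical choices.

## Worked example

```r
library(crossdyn)

cfg <- syntheticConfig(stage = "late", nUnits = c(20, 20), nTrials = 150, seed = 1,
                       rtMean = c(early = 2, late = 0.9, baseline = 1.1, perturbed = 2.5))
sim <- generateSession(cfg)
fit <- sessionCCA(sim$session)            # grasp-aligned, -1..+1 s, 100 ms bins
sig <- trialShuffleSignificance(fit$tensorsA, fit$tensorsB, nShuffles = 200, seed = 2)
mt  <- modulationTable(sim$session, fit$model, "M2")
tt  <- localTimingTable(fit, nCV = sig$nSignificant)
pt  <- timingPermutationTest(tt$diff, nPerm = 10000, seed = 3)
```

Output:

```
CCAModel (M2 ~ M1): 20 CVs, 100 ms bins, lag 0 ms
  canonical correlations: 0.621 0.152 0.133 0.121 0.120 ...
significant CVs: 1 (top-CV cv R2 = 0.367, null 95th pct = 0.290)
planted-axis angle (M2): 31.0 deg
median CA-modulation (d'): 2.74 over 150 trials
mean M2-M1 local timing difference: -82 ms (p = 0.0008)
```

Reading this: exactly one canonical variable beats the trial-shuffle null —
the planted one-dimensional shared latent — with held-out R² 0.37, on the
scale seen in real late-learning M2–M1 recordings. The skilled-stage CS
signal is strongly reach-modulated (median d′ ≈ 2.7), and M2 local activity
precedes M1 local activity (measured lead ≈ 82 ms for a planted 100 ms lead;
the sign-flip permutation test rejects no-lead at p < 0.001).

Sessions can also be read from plain TSV tables (`readSessionTSV()`: one row
per spike with region/unit/time, one row per trial with event times) and
written back (`writeSessionTSV()`, `writeSyntheticSession()`).

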