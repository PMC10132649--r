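---
title: "Methods: target-based fusion of survey SDoH into clinical risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-based fusion of survey SDoH into clinical risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sdohfusion)
```

## The problem and the estimand

A clinical *target* cohort records demographics, three-digit diagnosis
category indicators and a rare binary outcome; an external survey *source*
cohort records demographics, mock diagnosis indicators constructed from
survey items, social-determinant-of-health (SDoH) measures and its own
outcome. The two cohorts share no individuals. The question the package
answers is operational: **does transferring outcome-relevant SDoH features
from the source cohort into the target cohort, via patient similarity on
the shared feature block, improve out-of-sample prediction of the target
outcome over a diagnosis-only model?**

The pipeline has four stages, each an exported function:

1. **Harmonize** (`as_cohort()`, `impute_sdoh()`, `build_shared_matrices()`):
   validate both tables, median-impute source SDoH, and build aligned
   shared-feature matrices rescaled to `[0, 1]` with bounds pooled across
   the cohorts, so a given age means the same thing on both sides. Pooled
   bounds are the default because the similarity stage compares rows
   *across* cohorts; per-side bounds remain available
   (`pooled_bounds = FALSE`) for sensitivity analysis. Age and sex enter
   the shared block rescaled like every other feature — the alternative
   (raw demographics) would let age dominate the distance purely by scale.

2. **Select in the source** (`select_source_sdoh()`): mock diagnosis and
   SDoH candidates are marginally screened by per-feature logistic Wald
   tests adjusted for age and sex, with Benjamini–Hochberg control and a
   0.10 threshold on the *adjusted* p-value (strict `<`); survivors enter
   an elastic-net logistic model whose penalty is chosen by stratified
   cross-validation; the screen-then-fit step repeats over ten stratified
   90/10 resamples, and SDoH features with nonzero coefficients in at
   least half the resamples are kept.

3. **Fuse** (`importance_weights()`, `similarity_matrix()`,
   `expand_candidates()`, or the `fuse_cohorts()` wrapper): shared-feature
   importance weights are the renormalized absolute coefficients of an
   elastic-net outcome model fit in the source cohort (all-zero
   coefficients fall back to uniform weights with a warning, which makes
   the weighted measures collapse to their unweighted forms rather than
   fail). Pairwise similarity is computed under four methods — Pearson and
   Manhattan, each weighted and unweighted — and each kept SDoH feature is
   averaged (unweighted mean, on the raw survey scale) over every target
   patient's top-*k* matches for *k* in {10, 20, 50, 100, 200}. Fused
   columns are renormalized to `[0, 1]` when they enter modeling.

4. **Model and evaluate** (`fit_model()`, `repeated_split_evaluate()`):
   three variants — *conventional* (age, sex, diagnosis indicators),
   *sdoh_only* (age, sex, fused columns) and *fusion* (all blocks) — are
   fit by the same screen-then-fit recipe; fused candidates are screened
   adjusting additionally for the diagnosis indicators that survived the
   within-split dx screen. Out-of-sample AUC and sensitivity/PPV at 90%
   and 95% specificity are averaged over ten stratified 90/10 splits with
   normal-approximation 95% intervals, and the fusion-minus-conventional
   contrast is computed per split (same split sequence for every variant)
   before averaging.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| screening threshold `alpha` | 0.10 on BH-adjusted p | standard FDR level for a *screening* (not confirmatory) stage |
| elastic-net mixing `enet_alpha` | 0.5 | equal ridge/lasso blend: sparse but tolerant of correlated fused versions; configurable |
| CV folds `nfolds` | 5, stratified | cases are rare; stratification keeps them in every fold |
| resamples `n_repeats` / `n_splits` | 10 × 90/10, stratified | enough to estimate selection frequency at 0.1 resolution |
| stability rule `freq_threshold` | 0.5 | a feature must be selected in at least half the resampled fits |
| neighbourhood grid `k_grid` | 10, 20, 50, 100, 200 | spans sharp local matching to broad pooling; all versions enter as candidates and the data decide |
| overlap-report family `family_size` | 20 | each SDoH has 4 × 5 fused versions, so contrasts on fused columns are judged at 0.05/20 = 0.0025 |

"Selected" always means a nonzero elastic-net coefficient at the
cross-validated penalty. Penalty paths use 60 values down to 1% of the
null penalty; on unit-scale predictors the cross-validated optimum sits
well inside that range, and the truncation only removes the expensive,
never-chosen tail of the path.

## The simulator: what it emulates, and what it does not

`simulate_cohorts()` generates both cohorts from a shared latent vector
*z* (default dimension 2, standard normal per subject), interpretable as
latent social/behavioral domains:

* **Shared mock diagnosis items** are Bernoulli with logit linear in *z*
  (identical coefficients in both cohorts): by default 40 items with weak
  individual loadings (norm 0.3) and idiosyncratic prevalences drawn from
  (0.05, 0.35). Individually such items carry little signal; collectively
  they localize a subject on the latent axes — exactly the regime in which
  similarity matching can "borrow" information that a per-coefficient
  regression on the same items, estimated from a few hundred cases,
  cannot fully exploit. This mirrors the motivating application's shape:
  far more candidate diagnosis features than outcome events.
* **SDoH features** are linear-Gaussian in *z* (noise sd 0.8). Two are
  informative by default — one protective, one risk, echoing the
  mother-cares / body-image pattern reported in this literature — each
  anchored to its own latent axis with loading 1.3, so their fused
  versions carry *distinct* transferable signals and recovered coefficient
  signs are interpretable. The remaining 21 have near-zero loadings
  (0.1): filler survey items off the health axis. Informative SDoH
  effects on the outcome are ±2.0 on the log-odds scale.
* **Target-only diagnosis categories** (80, of which 12 carry direct
  log-odds effects of 1.2) are latent-free independent Bernoulli draws:
  clinical events such as poisonings that predict the outcome directly
  but sit outside the social latent axes. They give the conventional
  model honest signal of its own and keep the screening stage's
  false-discovery control meaningful (a large mostly-null family).
* **Outcomes** are Bernoulli with logit linear in the signal diagnosis
  indicators and the subject's own SDoH values — in the target cohort the
  SDoH values exist but are withheld from the emitted table (they are in
  the ground truth). Intercepts are calibrated by monotone root-finding
  so realized case rates match the configuration; the default rates
  (1.24% target, 3.54% source) reproduce the cohort composition of the
  motivating registry and survey. Missingness is applied completely at
  random to emitted source SDoH at 1.2%.

What the simulator does **not** emulate: realistic ICD code-frequency
distributions, longitudinal visit structure, informative missingness,
measurement heterogeneity between survey waves, and cohort-level
covariate shift beyond what the shared latent structure induces. Passing
tests therefore demonstrate that the pipeline is internally correct and
recovers planted structure under its stated assumptions — not that fusion
improves prediction on any particular real registry.

### Study-condition fixtures

The recovery experiments run at `n_target = 4000`, `n_source = 2000`.
That is roughly a tenth of the motivating study's scale, and keeping the
registry case *rate* at that size would leave ~50 target cases — too few
for any screening stage to act on. The directional-recovery fixture
therefore preserves case *counts* of the right order instead: target rate
0.0354 (~142 cases) and source rate 230/2000 (the source case count at
scale). The registry-scale rates remain the generator defaults and are
verified separately at `n = 38943` in the acceptance script. The null
fixture uses the same sizes with every effect set to zero; since nothing
passes source-side selection under the null, the null pipeline fuses an
arbitrary fixed subset of three SDoH columns so the fusion variant still
has candidates to reject.

An analysis note recorded during design: with all three generative links
linear (dx logit-linear in *z*, SDoH linear-Gaussian in *z*, outcome logit
linear in features), a penalized linear model that is given *many* cases
absorbs the entire latent signal through the shared indicators directly,
and top-k fusion cannot add to it — the fused columns are functions of the
same shared block. The fusion gain is therefore intrinsically a
limited-cases phenomenon (estimation variance and screening loss in the
conventional model), which is precisely the rare-outcome setting the
method was designed for. The fixtures operate in that regime
deliberately.

## Numerical and degenerate-input choices

* **Weighted Pearson** centers at *weighted* means (the `center`
  argument exposes unweighted centering); a pair with zero weighted
  variance on either side is assigned similarity −1 — never matched —
  and counted, rather than aborting an `n_target × n_source` computation
  for one pathological row.
* **Manhattan orientation** is lower-is-more-similar; every similarity
  matrix carries its orientation, and `top_k_indices()` breaks ties by
  ascending source index so fusion is fully deterministic.
* **Constant features** rescale to 0 and are flagged; screening excludes
  them with a `"constant"` status. Separation or non-convergence in a
  per-feature screen yields an `"unstable"` flag (detected by
  non-convergence, aliasing, |coef| > 15 or SE > 30), exclusion, and no
  further consequence.
* **Thresholds at fixed specificity** take the smallest observed score
  cut whose specificity among controls is at least the level (prediction
  rule `score >= threshold`); no ROC interpolation. Top-decile
  classification flags the `ceiling(0.10 n)` highest scores, ties broken
  by row index.
* **Confidence intervals** over repeated splits are mean ± 1.96·SE
  across the split values; with 10 splits these are approximate by
  construction and are read as summaries, not tests.
* **Normalization bounds** recorded on training rows are reapplied to
  new rows as-is; values outside the training range map outside `[0, 1]`
  and are scored without clipping.
* **Reproducibility**: every stochastic step (simulation, fold
  assignment, split assignment) derives from an explicit integer seed;
  repeat *r* of a resampling procedure uses `seed + r`. The simulator
  saves and restores the caller's RNG state.

## Known limitations

* Fused features are deterministic functions of the shared block; the
  framework transfers latent-structure information, never the
  subject-specific residual of an SDoH measure. Gains should be read as
  "borrowed structure", not as recovered individual survey answers.
* With two planted SDoH features on two latent axes, fused versions of
  different features are correlated; the elastic net may spread
  coefficients across them. Kept-set membership is stable in the tested
  regime, but exact version identity (`method`, `k`) is not.
* The Wald screen is calibrated for moderate case counts; below ~50
  events per screen its power is essentially nil and the pipeline
  degrades to the demographic model (with a warning), which is the safe
  but uninformative outcome.
* `case_overlap_comparison()` follows the convention of full-data refits
  for group definition; a held-out variant is a caller decision
  (`top_decile_classify()` composes with any score vector).
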