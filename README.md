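# sdohfusion

Cross-cohort fusion of social determinants of health (SDoH) for clinical
risk prediction.

## The problem

Clinical databases (hospital discharge records, claims) carry diagnosis
codes but rarely carry the social context — parental support, religiosity,
perceived safety — that is known to shape risks such as youth suicide
attempts. Large survey studies carry exactly that context, but for
different people. `sdohfusion` implements a target-based transfer-learning
framework that bridges the two: for each patient in a clinical *target*
cohort it finds the most similar participants of an external survey
*source* cohort over a block of shared features (age, sex, and mock
diagnosis indicators built from survey items), and transfers the selected
SDoH features by averaging them over those matches. The fused features
then join the diagnosis features in a penalized risk model, and the
package quantifies what they add.

## The method

For target patient *i* and source participant *j* with shared feature
vectors *x<sub>i</sub>*, *y<sub>j</sub>* and non-negative importance
weights *w* (from an outcome model fit in the source cohort), the package
computes four outcome-specific similarities:

* weighted Pearson `r_w = Σ w (x−x̄_w)(y−ȳ_w) / √(Σ w (x−x̄_w)² Σ w (y−ȳ_w)²)`
  (`rw`; uniform weights give ordinary Pearson, `r`)
* weighted Manhattan `d_w = Σ_k w_k |x_k − y_k|` (`dw`; uniform weights
  give the Manhattan distance up to a constant, `d`)

For each selected SDoH feature *s*, method *m* and neighbourhood size
*k ∈ {10, 20, 50, 100, 200}*, the fused value is the plain mean of *s*
over patient *i*'s top-*k* matches — one candidate column
`"s (m, k)"` per combination (12 features × 4 methods × 5 ranks = 240
candidates).

Model fitting follows a two-stage *marginal screening + regularized
logistic modeling* recipe: each candidate is screened by a Wald test
adjusted for age, sex (and, for fused candidates, the screened diagnosis
codes) with Benjamini–Hochberg FDR control at 0.10; survivors enter an
elastic-net logistic model tuned by stratified cross-validation.
Stability selection repeats this over stratified 90/10 splits and keeps
features selected in at least half of the repeats. Evaluation reports
out-of-sample AUC and sensitivity/PPV at 90% and 95% specificity, paired
across model variants (diagnosis-only, SDoH-only, fusion) on a shared
split sequence.

Restricted registry data cannot ship with the package, so a linked-cohort
simulator (`simulate_cohorts()`) generates both cohorts from a shared
latent structure with planted, signed SDoH effects — enough to test the
entire pipeline end to end and check that it recovers what was planted.

## Worked example

```r
library(sdohfusion)

sim    <- simulate_cohorts(sim_config(target_case_rate = 0.0354,
                                      source_case_rate = 0.115, seed = 1))
target <- as_cohort(sim$target, "target")
source <- impute_sdoh(as_cohort(sim$source, "source"))

# survey-side selection of outcome-relevant SDoH features
sel <- select_source_sdoh(source, seed = 1)

# similarity, weighting and top-k fusion in one call
fz <- fuse_cohorts(target, source, sim$shared_map,
                   sdoh_features = sel$kept_sdoh, seed = 1)

# paired repeated-split comparison of the model variants
ev <- repeated_split_evaluate(target, fz$fused,
                              c("conventional", "fusion"),
                              n_splits = 10, seed = 1)
ev
```

The run above prints (abbreviated):

```
performance_summary over 10 splits (seed 1)
  variant      auc                   sens_95               sens_90
1 conventional 0.701 (0.668, 0.734)  0.171 (0.108, 0.235)  0.250 (0.188, 0.312)
2 fusion       0.726 (0.700, 0.753)  0.193 (0.126, 0.260)  0.279 (0.223, 0.334)
fusion - conventional (paired):
  metric    mean   ci_lo  ci_hi
1 auc     0.0254  0.0022 0.0486
...
```

Read: on cohorts where two planted SDoH features carry real signal, the
fusion model beats the diagnosis-only model by 0.025 AUC on average over
ten paired 90/10 splits, with a 95% interval excluding zero; sensitivity
at 90% specificity rises from 0.250 to 0.279. `ev$selection$fusion` lists
which fused columns were kept — the planted features' versions appear with
coefficient signs matching their planted direction (`autoplot(ev)` and
`autoplot(ev$selection$fusion)` visualize both).

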