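# goldstage

Ordinal neural networks for COPD GOLD-stage prediction from heterogeneous
clinical cohorts.

## The problem

COPD severity is graded into four *ordered* GOLD stages (1 = mild to
4 = very severe). Predicting the stage from routine clinical variables runs
into three practical obstacles at once:

* the stages are ordinal — confusing adjacent stages is a small error,
  skipping two stages is a serious one, and a softmax classifier cannot
  tell the difference;
* different cohorts measure different variables — here, one cohort carries
  symptom burden (CAT score, exacerbation count) while the other carries
  six-minute walk tests, with demographics, smoking exposure and spirometry
  shared;
* records are incomplete, and a measured zero must stay distinguishable
  from a missing value.

`goldstage` addresses all three with a **shared-private ordinal network**:

* **value-mask encoding** — every feature becomes a `(value, mask)` pair
  (missing → `(0, 0)`, measured `v` → `(v, 1)`), doubling each input block;
  shared features are min-max normalized on fixed clinical ranges first,
  private features enter unscaled; nothing is imputed;
* a **shared encoder** (input → 32 → 16, ReLU) for the common features and
  a one-layer **private encoder** (input → 8, ReLU) per cohort, their
  embeddings concatenated into a 24-d joint representation;
* a **cumulative-threshold ordinal head** — linear 24 → 3 with sigmoids
  estimating `P(g ≥ 2), P(g ≥ 3), P(g ≥ 4)`; stage `g` is encoded as
  `([g≥2], [g≥3], [g≥4])` and decoded by counting thresholds above 0.5;
* **full-batch training** with Adam (lr 3e-4), per-threshold binary
  cross-entropy pooled over both cohorts, global gradient clipping at norm
  1.0, up to 3,000 epochs, and checkpoint selection at minimum validation
  MAE.

Evaluation uses ordinal metrics: exact accuracy, stage MAE, quadratic
weighted kappa

    kappa = 1 - sum(W * O) / sum(W * E),   W[i,j] = (i-j)^2 / (K-1)^2,

and the fraction of *errors* within ±1 stage. The package also ships the
paper-style comparison suite (multiclass softmax baseline, multinomial
logistic baseline, shared-only and private-only ablations, repeated runs on
one fixed stratified split) and a synthetic paired-cohort generator so the
entire pipeline runs without any external data.

## Worked example

```r
library(goldstage)

# A synthetic pair at the default study scale: 224 source / 101 target
# patients, stage mixes 80/60/43/41 and 23/43/27/8, 10% missing cells.
pair <- generate_pair(sim_spec(seed = 1))

# Stratified 20% split of the target cohort, full-batch ordinal training.
fit <- fit_gold_onn(pair$source, pair$target,
                    control = train_control(seed = 1))
fit
#> <onn_fit> full_ordinal: best epoch 1050 (validation MAE 0.250) over 3000 epochs
#> Ordinal evaluation (n = 20): accuracy 0.750 | MAE 0.250 stages | QWK 0.829 | 100% of errors within +/-1
#> Confusion (rows = true, cols = predicted):
#>     predicted
#> true 1 2 3 4
#>    1 4 1 0 0
#>    2 0 5 3 0
#>    3 0 1 5 0
#>    4 0 0 0 1
```

Reading the output: on the 20 held-out target patients the selected
checkpoint stages 75% exactly; the average error is a quarter of a stage;
quadratic weighted kappa 0.829 indicates strong ordinal agreement (> 0.8 is
the conventional bar); and every misclassification lands on an adjacent
stage — the clinically benign error pattern an ordinal model is supposed to
produce.

The training log, tidied views and plots follow broom/ggplot2 conventions:

```r
tidy(fit)                      # epoch, loss, validation metrics
glance(fit)                    # one-row checkpoint summary
autoplot(fit)                  # training curves
autoplot(fit$validation$report)  # confusion heatmap
predict(fit, pair$target)      # tibble: .pred_stage + threshold probs
```

The full comparison suite (5 variants × repeated runs, one shared split):

```r
suite <- run_suite(sim_spec(seed = 1), repeats = 5, base_seed = 1)
suite$summary   # per-variant mean ± sd of accuracy, MAE, QWK
```

On synthetic cohorts the private-only ablation degrades sharply while
variants that see the stage-defining shared spirometry stay close together;
the methods vignette (`vignettes/goldstage-methods.Rmd`) discusses why the
synthetic regime compresses this spread and what that does and does not say
about real cohort pairs.

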