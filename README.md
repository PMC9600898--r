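# copdgnn

Classify chronic obstructive pulmonary disease (COPD) severity — four GOLD
stages, with III and IV merged — from tabular CT-derived features: radiomics
descriptors of segmented lung parenchyma, or flattened 3D-CNN feature maps.

The package implements the full pipeline:

- **Combination-vector feature selection.** K *risk factors* are the top
  features by the R² of a univariate identity-link GLM of the ordinal stage
  on each feature; d *node features* are selected by the Lasso,
  `Σᵢ (yᵢ − β₀ − Σⱼ βⱼxᵢⱼ)² + λ Σⱼ |βⱼ|`, with λ* chosen by minimum mean
  squared error under 10-fold stratified cross-validation. Their
  concatenation (K + d) is the combination vector. PCA fusion is included
  as a comparator.
- **An auto-metric graph neural network (AMGNN).** Each classification is an
  N-way-K-shot episode: 40 labelled support nodes (10 per stage) plus the
  unknown node. Edge weights are learned from pairwise absolute feature
  differences through a 1×1-kernel metric network, `W_ij = σ(f_θ(|vᵢ − vⱼ|))`,
  gated by a risk-factor constraint `E_ij = Πₖ exp(−(r_ik − r_jk)²/τₖ)`, and
  row-normalized into the adjacency `Ã = norm(W ⊙ E)`. Two graph layers
  (`V ← [V ‖ LeakyReLU(Ã V W_f + b_f)]`, adjacency recomputed per layer) feed
  a softmax head. Training is episodic meta-learning: 600 iterations × 28
  episodes, cross-entropy on the query node, Adam. Forward and backward
  passes are implemented natively (analytic gradients, verified against
  finite differences in the test suite).
- **Evaluation harness.** Six reference classifiers (RBF SVM, a 400+100 MLP,
  random forest with 200 trees, multinomial logistic regression, gradient
  boosting, LDA) under stratified 5-fold CV with best-AUC model selection;
  metrics are accuracy, macro precision/recall/F1 and macro one-vs-rest ROC
  AUC; `run_experiment_grid()` reproduces the four benchmark experiment
  designs.
- **A synthetic cohort generator** that emulates the shape of the clinical
  cohort the method targets (465 participants in strata 129/108/121/107,
  1316 features): ordered stage-mean shifts on informative features and
  correlated feature blocks mimicking wavelet/LoG-derived redundancy. The
  real cohort is private; all shipped studies run on generated data.

## Worked example

```r
library(copdgnn)

coh <- generate_cohort(cohort_spec(n_per_class = rep(50L, 4), p_total = 120L,
                                   p_informative = 12L, effect_size = 1.5,
                                   block_size = 12L, seed = 7L))
coh
#> copd_cohort: 200 participants x 120 features
#>   per stage: 50/50/50/50
#>   informative features: 12

sp  <- stratified_split(coh$stages, 0.7, seed = 8L)
std <- standardize_features(coh$features, fit_on = sp$train)

lasso <- lasso_select(std$features[sp$train, ], coh$stages[sp$train],
                      n_folds = 10L, seed = 9L)
lasso
#> lasso_fit: lambda* = 0.013492, 44 features selected (10-fold CV)

rank <- glm_rank(std$features[sp$train, ], coh$stages[sp$train], K = 3L)
spec <- build_combination(rank$risk_factors, lasso$selected)
spec
#> combination_spec: (3 + 44) = K risk factors + d node features

model <- meta_train(std$features[sp$train, ], coh$stages[sp$train], spec,
                    amgnn_config(iterations = 150L, seed = 42L))
pred  <- predict(model, std$features[sp$test, ],
                 train_features = std$features[sp$train, ],
                 train_stages = coh$stages[sp$train], seed = 10L)
compute_metrics(coh$stages[sp$test], pred$stage, pred$probs)
#> accuracy 0.833 | precision 0.838 | recall 0.833 | F1 0.835 | AUC 0.975
```

Reading the output: the Lasso keeps 44 of 120 standardized features as node
features at the CV-chosen penalty; the three highest-R² features become risk
factors constraining graph edges; after 150 training iterations the model
stages 83% of the 60 held-out participants correctly, with macro one-vs-rest
AUC 0.975 (1.0 would be perfect ranking of every stage against the rest;
0.5 is chance). The defaults (`amgnn_config()`) train for 600 iterations.

A command-line interface wraps the same steps
(`inst/exec/copdgnn simulate | select | train | evaluate | grid`); see
`?copd_cli`.

## Package layout

- `R/cohort.R` — synthetic cohort and CNN-like feature generation, splits.
- `R/selection.R` — standardization, Lasso, GLM ranking, PCA fusion,
  combination vectors.
- `R/amgnn.R` — episodes, edge matrices, forward/backward, meta-training,
  prediction.
- `R/metrics.R`, `R/baselines.R`, `R/grid.R` — metrics, reference
  classifiers, cross-validated selection and the experiment grid.
- `R/io.R`, `R/cli.R` — CSV/JSON I/O, provenance hashing, the CLI.
- `vignettes/copdgnn-methods.Rmd` — the model, its assumptions, design
  decisions and limitations.
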