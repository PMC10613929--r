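# moephen: outcome-driven mixture-of-experts phenotyping

`moephen` discovers clinical phenotypes and models in-hospital mortality
risk *jointly*, for tabular cohorts whose features arrive in two tiers:
presentation data (available before treatment decisions) and treatment
data (available only afterwards). It was built for cohorts like acute
myocardial infarction complicated by cardiogenic shock (AMI-CS), where
subpopulations may carry opposite relationships between treatment and
outcome, so that pooled risk models and propensity matching both
mislead.

## The model

A selector network over the presentation features produces a softmax
gate vector `g` on the K-simplex — the patient's soft phenotype
membership — plus a pass-through representation and, optionally, an
initial pre-treatment risk estimate. Each of K expert networks sees the
pass-through concatenated with the treatment features and outputs a risk
`p_k`; the final prediction is the weighted vote

    ŷ = Σ_k g_k · p_k .

Because the gates depend only on pre-treatment data, the trained
selector clusters new patients *before* treatment, yet its clusters were
shaped by which risk models actually differ — outcome-driven
phenotyping rather than appearance-driven clustering. An L2 penalty
`λ · mean_i Σ_k g_ik²` on the gate output controls expert utilisation:
`λ = 0` lets the mixture concentrate, large `λ` forces even use of all
experts.

The package also provides the surrounding methodology:

* stratified 5-fold cross-validation with 20% inner validation splits;
* a `(λ, K)` grid search scored by AUROC/AUPRC, the Brier decomposition
  (uncertainty / resolution / reliability), and clustering *stability*
  as mean pairwise adjusted Rand index across fold partitions, with the
  two-stage stability-then-AUROC configuration rule;
* per-phenotype characteristics and mortality tables with exact
  Clopper–Pearson 95% intervals and significance flags;
* ternary (simplex) latent-space plots with local AUROC/AUPRC heatmaps;
* a synthetic AMI-CS-like cohort generator with three planted subgroups,
  an exact per-patient risk oracle, and calibrated ~25% mortality, so
  the whole pipeline is testable without restricted registry data.

## Worked example

```r
library(moephen)

# simulate a synthetic shock cohort with three planted phenotypes
spec <- default_amics_spec()
cohort <- generate_cohort(spec, n = 6000, seed = 1)
print(cohort)
#> MoE cohort: 6000 patients, 27 features, outcome rate 0.250, 3 latent subgroups

set.seed(1)
idx <- sample(cohort_size(cohort))
train <- cohort_subset(cohort, idx[1:4200])
val   <- cohort_subset(cohort, idx[4201:5100])
test  <- cohort_subset(cohort, idx[5101:6000])

config <- moe_config(n_experts = 3, gating_l2 = 0.01, seed = 1)
model <- train_moe(build_moe(config, cohort$schema), train, val)

pred <- moe_forward(model, test)
auroc(test$outcome, pred$final_risk)
#> test AUROC: 0.822 (exact-risk ceiling 0.850)

full <- moe_forward(model, cohort)
clusters <- assign_clusters(full)
weight_contribution(full$gates)
#> weight shares: 0.307 0.340 0.353
adjusted_rand_index(clusters$hard, cohort$latent)
#> ARI vs planted subgroups: 0.911

# per-phenotype mortality with exact 95% intervals
ord <- order_experts_by_weight(full$gates)
relabel <- match(clusters$hard, ord$order)
rates <- cluster_outcome_rates(relabel, cohort$outcome,
                               treatment_groups(cohort))
rates[rates$group == "entire", c("cluster", "n", "display")]
#>  cluster    n          display
#>        A 2069 25.3 (23.4-27.2)
#>        B 2041 32.7 (30.6-34.8)
#>        C 1890 16.3 (14.7-18.1)
#>      All 6000 25.0 (23.9-26.1)
```

The trained model discriminates within 0.03 AUROC of the generator's
exact-risk ceiling, its hard phenotype labels recover the planted
subgroups (ARI 0.91), and the three phenotypes separate into the
intended high / intermediate / low mortality strata, each with an exact
binomial confidence interval. Ternary diagnostics follow the same
objects:

```r
emb <- ternary_project(full$gates)
plot_ternary(emb, colour = classify_threshold(cohort$outcome,
                                              full$final_risk))
grid <- local_metric_grid(emb, cohort$outcome, full$final_risk, "auroc")
plot_local_metrics(grid)
```

A command-line wrapper (`inst/scripts/moephen`) drives the same stages
as subcommands (`simulate`, `train`, `gridsearch`, `select`, `analyze`,
`plot`), each writing a manifest with the seeds and options needed to
reproduce its outputs.

## Learn more

The methods vignette (`vignettes/phenotyping-methods.Rmd`) documents the
model and its assumptions, the loss and regularisation regimes, the
training dynamics and their deliberate options, the model-selection
procedure and its known biases, the calibration metrics, and exactly
what the synthetic generator does and does not emulate.
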