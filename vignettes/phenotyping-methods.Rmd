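---
title: "Outcome-driven mixture-of-experts phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-driven mixture-of-experts phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moephen)
```

## The problem

Observational cohorts of acute myocardial infarction complicated by
cardiogenic shock (AMI-CS) mix patients whose mortality risk is driven by
different factors. A single pooled risk model averages those factors away,
and matching methods that model only treatment propensity can pair
patients whose outcomes respond oppositely to the same therapy. `moephen`
implements a joint approach: learn soft patient phenotypes *and* an
in-hospital mortality model in one network, with the phenotypes defined
only by pre-treatment information so they remain usable at decision time.

## Model

Data come in two tiers. *Presentation* features are available from
arrival to the treatment decision; *treatment* features (procedural
course, device use, post-treatment labs) exist only afterwards.

The **selector network** is a fully connected network over the
presentation features. Its final hidden layer feeds a **gating layer**
whose softmax output \(g \in \Delta^{K-1}\) is a probability vector over
\(K\) experts; \(g\) is read as the patient's soft phenotype membership,
and the hard phenotype is \(\arg\max_k g_k\) (ties to the lowest index).
Optionally the selector also emits a pre-treatment risk estimate through
a logistic head.

Each **expert network** \(k\) receives the selector's final hidden layer
concatenated with the treatment features and produces a risk
\(p_k \in [0,1]\). The model's prediction is the weighted vote
\[
\hat y \;=\; \sum_{k=1}^{K} g_k\, p_k ,
\]
a convex combination of the expert risks. Because the gates depend only
on presentation data, the clustering half of the model can be deployed
before treatment even though it was trained with treatment and outcome
information — the training signal *drives* the selector to separate
patients whose outcome models differ, rather than patients who merely
look different.

Three architecture presets are provided: `large` (three layers of 50
units in selector and experts), `mid` (two layers of 24 units), and
`small` (the mid-sized selector with a single prediction layer per
expert). Tabular registry-style data rarely rewards more capacity, and
the single-layer experts of the `small` preset make each phenotype's
risk model directly interpretable as a linear model on the pass-through
plus treatments. Two alternative wirings are available for comparison:
`later_hidden` injects an early selector layer into each expert's final
layer, and `no_hidden` gives experts only raw features. These mirror
ablations whose published descriptions are incomplete; our definitions
are documented in `?moe_config` and flagged as approximations.

The number of experts is capped at 10: beyond interpretability, gating
splits every minibatch across experts, so large \(K\) starves each
expert of examples (the shrinking-batch problem).

## Loss and regularisation

Training minimises binary cross-entropy of \(\hat y\) plus an L2 penalty
on the gate output,
\[
\mathcal{L} \;=\; \mathrm{BCE}(y, \hat y)
\;+\; \lambda \cdot \mathrm{mean}_i \textstyle\sum_k g_{ik}^2
\;+\; 0.1\,\mathrm{BCE}(y, r_0) \; \text{(if the initial-risk head is on)} .
\]
On the simplex, \(\sum_k g_k^2\) is minimised (\(1/K\)) by uniform gates
and maximised (\(1\)) by one-hot gates, so \(\lambda\) is a dial on
expert utilisation. Under-regularised mixtures are free to concentrate on
few experts; over-regularised ones use all experts evenly but stop
grouping patients consistently. The penalty is applied to the
post-softmax gates because that is the quantity whose evenness matters;
penalising the pre-softmax scores instead is available via
`penalty_on = "scores"`. The auxiliary initial-risk weight (0.1) makes
the optional pre-treatment head useful without letting it dominate.

## Training dynamics

Hidden layers use rectified-linear activations; output units are
logistic. Optimisation is minibatch Adam (learning rate `1e-3`, batch
128, up to 400 epochs) with early stopping on the validation loss
(patience 30) and restoration of the best-validation weights. The gate
layer starts at exactly zero weights — uniform gates — so utilisation
structure is learned, not inherited from the initialisation; expert
output layers start near zero so the experts' initial opinions are close
and routing is decided by data rather than initialisation luck. All
randomness (initialisation, shuffling) is governed by the configuration
seed, and two runs with the same seed are bit-identical.

One deliberate option deserves explanation. With Adam everywhere, an
expert that currently receives little gate mass still takes
normalised-size steps, so it catches up and the mixture reliably keeps
several experts alive — good for recovery, but it damps the textbook
collapse of *unregularised* mixtures onto a single expert.
`gate_optimizer = "sgd"` switches the gate to plain momentum SGD and can
be combined with a large `adam_epsilon` (for example `5e-4`), which makes
near-zero-gradient parameters move proportionally to their gradients;
together these preserve classic expert starvation, and unpenalised runs
then can collapse completely. The price is that moderately penalised runs
occasionally get trapped in partially collapsed states, so the default
remains full Adam. The package's own regularisation-regime tests document
what the default dynamics do and do not reproduce: heavy penalties
(\(\lambda = 0.1\)) drive per-expert mean gates to within 0.05 of
\(1/K\), while at \(\lambda = 0\) utilisation becomes markedly uneven but
a dominant expert does not reliably exceed a 90% weight share — with
validation-based weight restoration, the partially specialised state is
simply a better model, and the trainer keeps it.

## Model selection

`make_fold_plan()` builds stratified five-fold cross-validation with a
20% inner validation split of each fold's training remainder.
`run_grid()` trains one model per fold for every combination of
\(\lambda \in \{0.001, 0.002, 0.004, 0.006, 0.008, 0.01, 0.05, 0.1\}\)
and \(K \in \{2,\dots,10\}\) (both overridable), scores AUROC, AUPRC and
the Brier components on held-out folds, and measures clustering
*stability* as the mean pairwise adjusted Rand index (ARI) between the
fold models' hard partitions. Partitions are compared on the full cohort
so every pair shares an item set; partitions that collapse to a single
cluster contribute 0 to the mean, so degenerate runs cannot fake
stability. Optional random restarts per fold keep the best-validation
run. `select_configuration()` applies the two-stage rule: shortlist
penalties whose stability is within one confidence half-width of the
best, fix \(K\) to the modal stability-maximising value among them, then
pick the shortlisted penalty with the best AUROC (ties to the smaller
penalty).

A caveat that our synthetic experiments expose: when the cohort truly
contains \(k\) subgroups, a mixture with \(k+1\) experts typically
recovers the same \(k\) groups plus one near-empty spare expert. Its
partitions are effectively \(k\)-cluster partitions and are at least as
reproducible across folds — often slightly more, because the spare
expert absorbs optimisation accidents. Mean pairwise ARI is therefore a
blunt instrument for choosing the number of phenotypes on its own; the
minimum-size and minimum-weight rules of `cluster_size_check()` (no
cluster below 10% of the largest's population, no weight share at or
below 10%) are the complementary check that flags such spare experts.

## Calibration metrics

`brier_decomposition()` splits the mean squared forecast error into
uncertainty \(\bar y(1-\bar y)\), resolution (between-bin variance of
observed event rates), and reliability (within-bin squared calibration
gap), using ten equal-width probability bins. The identity
`reliability - resolution + uncertainty = Brier` holds exactly when
forecasts are replaced by their bin means and up to a within-bin variance
of order (bin width)\(^2\) otherwise; both statements are verified in the
test suite. Higher resolution and lower reliability indicate better
calibration. Published values of these components exist on scales that
the standard decomposition cannot produce for a binary outcome
(resolution above 1); the scaling there is not recoverable, so this
package reports the standard decomposition only.

Per-phenotype mortality tables use exact Clopper–Pearson 95% intervals
(`clopper_pearson_interval()`), computed from the Beta-quantile form of
binomial tail inversion. A cluster-by-treatment cell is flagged
non-significant when its interval contains the corresponding
whole-population rate — the weakest criterion consistent with "no
significant difference"; `flag = "fisher"` substitutes a two-sided exact
test.

## Latent-space diagnostics

`ternary_project()` embeds each patient's gate vector into the
three-expert simplex. Experts are first ordered by total weight
(`order_experts_by_weight()`: "A" is the heaviest and is drawn bottom
right, "B" top, "C" bottom left); for \(K > 3\) only the three globally
heaviest experts are kept and the retained mass is renormalised, with the
truncated mass recorded per patient (and summarised by
`weight_contribution()`, which is what makes truncation auditable).
Whether to renormalise is genuinely open — the raw projection is
available via `renormalize = FALSE` — and patients with zero mass on all
three plotted experts are returned in an exclusion list rather than
placed arbitrarily.

`local_metric_grid()` subdivides the simplex into \(r^2\) triangular
cells (default \(r = 10\) per edge; half-open cell boundaries with the
top corner closed so membership is deterministic) and computes a local
AUROC or AUPRC in every cell with at least `min_per_cell = 10` patients
of both outcome classes. Unscorable cells take the chance-level fill:
0.5 for AUROC, 0 for AUPRC. With \(r = 1\) the single cell reproduces
the global metric exactly, which the tests assert. Points can be
coloured by `classify_threshold()` confusion classes at a 50% threshold.

## The synthetic cohort generator

Real AMI-CS registry data are restricted, so every stage is exercised on
a synthetic cohort (`default_amics_spec()`, `generate_cohort()`) whose
structure — not its marginal realism — mimics the problem:

* Three equally mixed latent subgroups over 12 presentation + 15
  treatment features (continuous features on a standardised scale,
  binary indicators as Bernoulli draws).
* Subgroups are well separated in presentation space; a group-posterior
  classifier exceeds 98% accuracy, so phenotype recovery is limited by
  the model, not by irreducible overlap.
* Within each subgroup the outcome logit is flat in the presentation
  features; subgroup identity enters through intercepts (mortality
  roughly 0.33 / 0.24 / 0.16, near-equidistant logits) and the
  treatment-tier coefficients flip sign between subgroups in a pairwise
  pattern with zero mixture-weighted means: the balloon-pump and
  microaxial-device indicators separate groups 1 and 2, peak troponin
  separates 2 and 3, ejection fraction separates 1 and 3. A pooled
  linear model consequently loses that signal entirely, and no 2-way
  merge of subgroups is cheap — recovering the risk surface requires
  three-way routing.
* Treatment intensity differs between subgroups (practice-style
  intercept shifts) but, within a subgroup, is independent of
  presentation. We found that any within-group presentation-addressable
  risk — including risk leaked through presentation-dependent treatment
  propensity — hands a spare expert a stable split and distorts
  stability-based selection of \(K\); keeping within-group risk flat in
  presentation makes the intended three-group structure the only
  presentation signal.
* The overall outcome prevalence is calibrated near 0.25, and
  `bayes_risk()` exposes the exact per-patient event probability as a
  discrimination ceiling: ranking by it attains the maximum possible
  AUROC on generated data.

What passing tests show: on data with this planted structure, the small
three-expert model at \(\lambda = 0.01\) recovers the subgroups (ARI
against the latent labels at least 0.6 at \(n = 20{,}000\); in practice
far higher), discriminates within 0.03 AUROC of the exact-risk ceiling,
and beats the pooled ridge-logistic baseline by at least 0.03 AUROC.
What they do not show: performance on real registry data, robustness to
unmeasured confounding, time-varying risk, or informative missingness —
none of which the generator emulates. An MCAR missingness injector
(`inject_missing()`) exists only to exercise the imputation rules
(binary missing to "no", continuous missing to the training-split mean).

## Study sizes used by the test suite

Recovery and baseline comparisons run at \(n = 20{,}000\) with a
stratified 64/16/20 train/validation/test split; regularisation-regime
checks at \(n = 10{,}000\) over five seeds; stability-based selection of
\(K\) at \(n = 5{,}000\) with three folds and five replicates; generator
calibration checks at \(n = 50{,}000\). These sizes keep the full suite
to a few minutes on a single core while leaving the conclusions stable
across seeds.

## Known limitations

* Gates can only express phenotype structure visible in presentation
  data; risk heterogeneity that is orthogonal to presentation is
  unreachable by construction.
* Stability-maximising choice of \(K\) is biased toward spare-expert
  solutions (see above); pair it with the cluster-size/weight rules.
* Full single-expert collapse of unregularised mixtures is a
  training-dynamics phenomenon, not an inevitability: under
  validation-based early stopping with adaptive updates the partially
  specialised state usually survives instead. The non-adaptive gate
  option reproduces the sharper pathology when that regime itself is the
  object of study.
* The exact decomposition scale used by some published calibration
  tables is not reproducible; only the standard Brier decomposition is
  provided.
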