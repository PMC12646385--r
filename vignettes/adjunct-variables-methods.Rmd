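---
title: "Measuring the impact of adjunct variables on synthetic medical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the impact of adjunct variables on synthetic medical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When a data custodian synthesizes a tabular medical dataset for sharing, the
downstream task often needs only a *core* subset of the variables — the
predictors and the binary outcome of a predefined analysis. The remaining
columns are *adjunct*: present in the source data, irrelevant to the task.
Should the generative model be trained on the core alone, or on the core plus
some or all of the adjuncts? Intuition from classical statistical disclosure
control says more variables mean more disclosure risk; intuition from machine
learning says task-irrelevant inputs can act as noise and degrade the model,
or as correlated signal and help it.

`adjunctsdg` implements the full measurement pipeline for this question:
simulate (or load) a cohort, enumerate or sample *variants* — training
populations that add increasing numbers of adjunct variables to the fixed
core — train generative models per variant, generate an ensemble of synthetic
replicates, evaluate fidelity, downstream utility, and membership-disclosure
vulnerability of the projected core subset, and meta-analyze the effect of
the adjunct count on each metric with mixed-effects models across datasets.

Because the medical datasets this design was developed on are
access-restricted, the package ships a cohort simulator with known ground
truth instead of data. Every pipeline stage is exercised and tested against
the simulator; nothing in the package depends on restricted inputs.

## The cohort simulator

`cohort_spec()` / `simulate_cohort()` generate cross-sectional cohorts with
the structural features the pipeline must cope with:

* **Gaussian-copula dependence.** Core predictors arise from latent standard
  normals with a configurable correlation matrix (default exchangeable,
  `rho = 0.3`). A configurable fraction (default one half) is discretized
  into 2–5 quantile bins, producing mixed categorical/continuous tables.
* **Binary outcome with controlled imbalance.** The outcome follows a
  logistic model on the latent core values. The intercept is calibrated by
  `calibrate_intercept()`, which solves a one-dimensional Gaussian integral
  by root-finding so the marginal prevalence hits the target — the relevant
  range in practice runs from roughly balanced (49%) down to 1%.
* **Adjunct modes.** Each adjunct variable is either `independent` (pure
  noise), `redundant` (a noisy copy of one core latent; noise sd 0.5 by
  default), or `informative` (a noisy linear combination). The default pool
  alternates redundant and independent adjuncts because real adjunct
  variables span exactly this range: sometimes strongly related to the core,
  sometimes not at all. `pairwise_nmi()` quantifies this as normalized mutual
  information, grouped core-to-core versus core-to-adjunct.
* **MCAR missingness** (default 5%) on all non-outcome columns. Real
  missingness mechanisms are usually not missing-completely-at-random; MCAR
  is the testable default and the mechanism is deliberately simple — results
  on simulated data bound what the pipeline can do, not what any specific
  real dataset will show.
* **Quasi-identifiers.** The first `qi_count` non-outcome variables are
  flagged; they drive the membership attack.

The simulator is deterministic in its spec (including the seed). Ground
truth (coefficients, calibrated intercept, the parameter of interest) is
returned alongside the cohort so parameter-recovery tests can close the
loop.

What the simulator does *not* emulate: real marginal shapes, informative
missingness, measurement error, record duplication, and the idiosyncratic
dependence structures of actual clinical data. Passing tests on simulated
cohorts therefore demonstrate correctness of the machinery and of the
statistical operating characteristics, not performance claims about any
particular real dataset.

## Variants

`enumerate_variants()` produces all `2^m` adjunct subsets (including the
core-only empty subset) when the pool is small — a pool of 4 gives 16
variants, a pool of 5 gives 32. For larger pools `sample_variants()` draws
per-size samples: at least 5 distinct subsets per adjunct count `k` (the
floor), exactly one variant at `k = 0` and at `k = m` (no variety exists
there), capped by `choose(m, k)`. The default per-`k` target scales with
`log choose(m, k)` so sizes with a larger combinatorial space get more
variants; the allocation is configurable because any specific schedule is a
design choice, not a law. A Halton low-discrepancy sampler is available as
an alternative (`method = "halton"`) for more uniform coverage of the
subset space.

One decision deserves emphasis: the train/holdout split is a function of the
dataset and the master seed *only*. All variants of one dataset share the
same 50:50 split (defaults 10 000/10 000), so varying the variable set never
changes which records the generator sees.

## Generators

Two reference generative models are implemented from scratch; two baselines
and a plugin contract complete the set.

**Sequential decision trees** (`fit_sequential_trees()`) synthesize one
variable at a time conditional on its predecessors: the first variable by
its empirical marginal, each later one by a CART tree (classification or
regression) whose leaves store donor values of the training rows reaching
them. Synthesis routes a partial synthetic record to a leaf and samples a
donor — continuous values therefore stay in the observed support rather
than being generated from a parametric residual model. Default controls:
minimum leaf 5, split tolerance `mindev = 0.002`, visit order = metadata
order with the outcome last. These are package defaults, surfaced as
arguments.

**Chow–Liu Bayesian network** (`fit_bayesian_network()`) discretizes
continuous variables into equal-frequency bins (default at most 10), learns
the maximum spanning tree on pairwise mutual information, roots it at the
first variable to obtain a DAG, smooths the conditional tables with
add-`alpha` (default 0.5) over the categories *observed in training* —
never inventing unseen values — and samples ancestrally. Sampled bins are
re-materialized by a uniform draw within the bin's observed training range.

**Missing values** are handled identically for both fitted models:
categorical missingness becomes an explicit category; each continuous
variable with training missingness gets a companion missing/observed flag
modeled jointly (placed immediately before it in the sequence), with the
value median-imputed for modeling and re-blanked on synthesis. Synthetic
output thus reproduces training missingness rates.

**Baselines.** `fit_independent_marginals()` bootstraps each column
independently, deliberately destroying the joint distribution — a
low-fidelity, low-disclosure contrast. `fit_copy_generator()` bootstraps
whole training rows; it is a test harness, not a synthesizer: it is the
membership-disclosure worst case every real generator must beat, and its
train-on-synthetic performance matches train-on-real by construction.

**Deep tabular models** (GANs, VAEs, normalizing flows, adversarial random
forests) are exposed only through `plugin_generator()` — a
`fit(train, seed)` / `sample(state, n, seed)` contract with enforced schema
guarantees. Reimplementing or tuning them is out of scope here.

Each fitted generator emits a `generate()` ensemble — by default 10
replicates of training size, one derived child seed per replicate —
following the practice of generating several synthetic datasets per trained
model to account for synthesis stochasticity.

## Evaluation metrics

All evaluation happens on the *projected core* subset of the synthetic
table (projection, never retraining), except privacy, which is also
computed on the full core+adjunct table.

**Cluster fidelity** (`cluster_fidelity()`). Real and synthetic records are
pooled, encoded (one-hot categoricals, standardized continuous, mean-filled
missing with indicator columns), and clustered by k-means (`G = 20` by
default, 10 restarts, fixed seed). With `c` the real fraction of the pool
and `p_j` the real fraction of cluster `j`, the size-weighted statistic
`U = sum_j (n_j/n) (p_j - c)^2` is 0 under perfect mixing; its maximum over
all assignments is exactly `c(1-c)` (attained at full purity), which makes
`score = 1 - U / (c(1-c))` a clean `[0, 1]` scale with 1 = maximum
fidelity. The size weighting is what makes the normalization exact; the
default `G` follows common practice for this statistic and is exposed, not
hidden.

**TSTR** (`tstr_auroc()`). Train a probabilistic classifier on each
synthetic replicate's core columns, score the real holdout, compute AUROC
by the tie-corrected rank statistic, and average over replicates. Two
classifier specs ship (`default_classifiers()`): gradient-boosted trees
with a small hyperparameter grid tuned by 5-fold cross-validation
optimizing AUROC on the synthetic training replicate, and a
single-hidden-layer network with fixed architecture and weight decay as the
overfitting control (no grid search). Trees receive integer-coded
categoricals and handle missing values natively; the network receives
one-hot encoding with training-only median/mode imputation, so the holdout
never leaks into training.

**Replicability** (`ensemble_replicability()`). The inferential task is a
logistic regression; the flagged parameter of interest is estimated on the
real data and on each synthetic replicate, the replicate estimates are
pooled by multiple-imputation-style combining rules
(`combine_estimates()`): pooled estimate = mean, total variance
`T = w_bar + b/m` (within + between/m, the partial-synthesis form, never
negative), t interval with `nu = (m-1)(1 + w_bar/(b/m))^2` degrees of
freedom. The fully-synthetic rule `(1+1/m)b - w_bar` is available behind a
switch. Four agreement metrics compare combined-synthetic against real:
decision agreement (same sign and significance status), estimate agreement
(synthetic point estimate inside the real interval), standardized
difference (difference consistent with zero at the normal quantile), and
CI overlap (proportion of overlap averaged over both interval widths,
truncated at 0 because a proportion is nonnegative). Replicates whose
logistic fit fails — constant outcome, complete separation,
non-convergence — are recorded as missing, not silently pooled.

**Membership disclosure** (`membership_attack()`,
`vulnerability_pair()`). The adversary holds an attack sample of `a`
records (default `min(1000, n/10)`), an expected fraction `p = 0.5` of them
drawn from the training data, and predicts "member" whenever some synthetic
record matches on the compared variables — quasi-identifiers only
(realistic background knowledge) or the entire record (an overfitting
probe) — with at most `h = 0` mismatches; categorical matching treats
missing as its own category, continuous matching uses a tolerance of 0.1
pooled standard deviations. F1 against true membership is referenced to the
naive predict-everyone baseline `f1_naive = 2p/(1+p)` (= 2/3 at `p = 0.5`),
giving `relative_f1 = max(0, f1 - f1_naive)`; 0.2 is the conventional
literature threshold for acceptable residual risk, and `summarize_run()`
flags it. Matching uses a hash join when all compared variables are
categorical and `h = 0`, and a vectorized per-record scan otherwise; both
paths are verified against a brute-force all-pairs oracle in the tests.
The difference-from-naive form of the relative F1 and the balanced default
`p` are reconstructions of the published convention that accompanies the
0.2 threshold; both are config-exposed.

Attribute and identity disclosure are deliberately out of scope: identity
disclosure is protected by the synthesis design itself (no record linkage
survives), and no meaningful attribute-disclosure metric is currently
established.

## Meta-analysis

`fit_metric_effect()` models one metric across datasets:

```
value ~ 1 + k_adjunct + (1 + k_adjunct | dataset_id)
```

The dataset is a random intercept *and* a random slope, since a dataset can
shift a metric's level and modulate the adjunct effect. Continuous metrics
(fidelity, AUROC, CI overlap) use a linear mixed model with Satterthwaite
degrees of freedom for the fixed-effect p-value; the binary agreement
metrics use a binomial-logit GLMM reporting the odds ratio `exp(coef)` with
a Wald z p-value. Confidence intervals are computed by likelihood profiling
with a Wald fallback on non-convergence; the method actually used is
recorded in the output, as is a singular-fit refit with uncorrelated
intercept and slope. Replicate-level continuous metrics are averaged to
variant level before modeling; agreement metrics are already one value per
variant. At least two datasets are required — with a single dataset the
random effects are unidentifiable and the function says so rather than
degrading silently.

Two simulation checks characterize the estimator at the scale used in the
tests (12 simulated datasets, 40–60 variants each, adjunct counts 0–120):
a fixed slope of −0.001 with dataset intercept sd 0.05 and residual sd 0.01
is covered by the 95% Wald CI in well over 90 of 100 seeded replications;
under a zero fixed slope with dataset-level random intercepts *and* random
slopes (sd 2×10⁻⁴, i.e. generating from the model class the meta-analysis
assumes), the fixed-effect test rejects at close to the nominal 5% rate.
With intercept-only null data the Satterthwaite test is mildly conservative
— a known property of testing a fixed effect alongside a superfluous
random-slope variance component, not a defect.

## Orchestration and reproducibility

`run_config()` + `run_experiment()` run the whole design: per cohort —
simulate, split once, build variants, fit each generator per variant,
generate the ensemble, evaluate all configured metrics; then the
mixed-effects meta-analysis per generator × metric. Failures are logged
with (dataset, variant, generator) coordinates and the run continues.
The long-format metric table (`write_metric_table()`) is the single
interchange format between evaluation and modeling.

Every random draw in the package flows through `derive_seed(master, tags...)`,
a deterministic hash of the master seed and a tag path (module, dataset,
variant, replicate). Identical config and master seed reproduce the metric
table byte for byte; distinct stages have decoupled streams, so adding a
metric never perturbs another stage's draws. Single-threaded model fits
keep the boosted-tree classifier deterministic as well.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are desk
scale by design — populations of 2 000 with 1 000/1 000 splits, 3–5
replicates, 2 cohorts × 16 enumerated variants × 2 generators in the
end-to-end run — chosen so the full suite characterizes every stage in
minutes while the function defaults remain at the reference design
(10 000/10 000, 10 replicates).

## Known limitations

* The simulator's MCAR missingness and copula dependence are idealizations;
  conclusions about real datasets require real data.
* The exact per-`k` variant-sampling schedule, the clustering configuration
  of the fidelity statistic, the attack construction, and the combining-rule
  degrees of freedom are reconstructions of published conventions; each is
  config-exposed and documented where it appears.
* The Chow–Liu network captures at most tree-structured dependence;
  higher-order interactions are smoothed away. The sequential-tree model's
  quality depends on the visit order, which is fixed by default for
  reproducibility.
* No GAN/VAE/flow training, no hyperparameter search for generators, no
  longitudinal or repeated-measures layouts, no multi-class tasks.
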