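---
title: "Methods: proteomic recurrence-risk modelling for pediatric papillary thyroid carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic recurrence-risk modelling for pediatric papillary thyroid carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrisk)
```

# The problem

Pediatric papillary thyroid carcinoma (PPTC) lacks established recurrence
risk stratification criteria. The workflow implemented here builds an
individualized recurrence-risk predictor from a tandem-mass-tag (TMT)
quantitative proteome of thyroid nodules (pediatric malignant, PM; pediatric
benign, PB; adult malignant, AM), combined with right-censored
recurrence-free survival of the PM patients. The pipeline has five
analytical stages — matrix preprocessing, differential expression, clinical
Cox survival screening, prognostic model building with stability-based
feature selection, and Crank-based risk stratification — plus a synthetic
cohort generator that makes every stage testable without patient-level data.

# The synthetic cohort generator

`sim_config()` / `generate_cohort()` emulate the structure of the cohort the
method was designed for: 85 PM + 83 PB + 66 AM biological samples, six
technical replicate pairs (240 tissue channels from 234 samples), sixteen
TMT batches of 15 tissues plus one pooled reference channel each, ~9,154
quantified proteins, follow-up uniform on [42, 100] months (median 71), and
a ~14% recurrence fraction.

On the log2 scale an entry is

\[
x_{ps} = b_p + \beta^{grp}_{p}\,[s \in PM] + \lambda_p^\top u_s +
  s_p\,\sigma_{mod}\,v_s + b_{p,batch(s)} + \varepsilon_{ps},
\]

with protein baselines \(b_p \sim N(20, 2^2)\), global latent factors
\(u_s\) (three factors, loading SD 0.5) emulating proteome co-regulation,
additive per-batch per-protein offsets (SD `batch_sd`, default 0.5) and
residual noise (SD `noise_sd`, default 0.5). Technical replicates re-noise
the same biological signal at SD `noise_sd / 2`; pooled channels are the
per-batch mean re-noised at the same technical SD.

Two kinds of structure are planted and recorded in the returned ground
truth:

* **Differential proteins** (`n_dep`, default 300) receive a signed shift of
  `dep_log2fc` (default 1.0) in the PM group.
* **Prognostic signal proteins** (`n_signal`, default 10) form a signed
  co-regulated *risk-program module*: each loads with its sign on a shared
  per-sample latent risk factor \(v_s\) (loading `signal_module_sd`, default
  1.33 against residual SD 0.5, i.e. each module protein reads out the
  latent risk with correlation ≈ 0.9). This choice is deliberate: coherent
  prognostic programs in tumor proteomes are modules of co-expressed
  proteins, not ten mutually independent markers, and with ~85% censoring a
  dozen events cannot identify ten independent weak covariates no matter
  what selector is used. The module design makes every planted protein
  marginally informative, which is the regime in which a stability-selected
  panel is a meaningful target. Signal proteins also carry the `dep_log2fc`
  group shift so that they fall inside the differential pool that feeds the
  prognostic models.

Recurrence follows a proportional-hazards model with linear predictor
\(\sum_j \beta_j z_{ij}\) over the standardized signal-protein abundances,
\(\beta_j = \pm\) `signal_loghr` (default 0.25 per SD; given the module
correlation the realized linear predictor has SD ≈ 2.3). Event times are
exponential; censoring is uniform on the configured window. The baseline
hazard is calibrated analytically — for exponential times and uniform
censoring on \([a,b]\) the event probability has the closed form
\(1 - (e^{-ra} - e^{-rb})/(r(b-a))\), and `calibrate_baseline_hazard()`
root-finds the hazard whose cohort mean matches `target_event_fraction`.
The calibration is unbiased; a single cohort of 85 patients still
fluctuates binomially (SD ≈ 0.03), which the tests account for by bounding
the across-seed mean tightly and individual seeds loosely.

Missingness is abundance-dependent: an entry is hidden with probability
`mcar_rate` plus a logistic term in the negated overall abundance rank,
\(p_{MNAR} = \mathrm{logit}^{-1}(\mathrm{logit}(0.08) + s\,(0.5 - r))\)
with steepness `mnar_slope` (default 8), so low-abundance proteins are
preferentially lost, as in real TMT data where low-signal peptides fall
below the identification limit. `mnar_slope = 0` disables the mechanism
exactly. Every masked position and its pre-mask value are recorded.

What the generator does **not** emulate: peptide-to-protein rollup,
reporter-ion interference, ratio compression, sample-loading differences, or
immune-cell composition. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative model, not performance
on real spectra.

## The synthetic reference clinical table

The per-patient clinical table of the original cohort is not
redistributable. `reference_clinical_synthetic()` (also shipped as
`inst/extdata/clinical_synthetic.csv`) is a deterministic, openly synthetic
stand-in calibrated **only to printed cohort summaries**: 85 patients, 12
recurrences, mean tumor size exactly 2.4 cm, 69 node-positive, median
follow-up exactly 71 months, median age 16, 23 males, 38 total
thyroidectomies, 16 multifocal and 43 lateral-node-positive cases, with two
late recurrences (104 and 116 months) and recurrence enriched below age 16.
Fitted hazard ratios on this table are properties of the synthetic data:
they reproduce the *directions* reported for the real cohort (age
protective, nodal burden hazardous, the categorical age coding winning all
three model-selection criteria) but their exact values cannot and should
not match the published ones, which depend on the unpublished joint
patient-level data.

# Preprocessing

The chain runs in a fixed order, enforced by `preprocess_cohort()`:
missingness filter → sequential imputation → ComBat batch correction (all
on log2) → conversion to the linear scale with half-minimum replacement →
technical replicate merging (pooled channels dropped). Scale conversions
are explicit (`as_linear()` / `as_log2()`); the imputation and batch steps
are defined on log2 abundances while the half-minimum rule is defined on
positive linear abundances.

* **Filter**: proteins with NA rate *strictly above* the threshold (default
  0.85) are removed — the boundary protein is kept. The threshold is
  configurable.
* **CVs**: quality control computes per-protein CVs (sample SD / mean of
  non-missing log2 abundances; the \(n-1\) SD, stated here because either
  convention is defensible) across pooled channels and within replicate
  pairs.
* **Sequential imputation** (`impute_sequential()`): proteins are processed
  in order of increasing missingness; each incomplete protein is regressed
  on its `k` (default 10) most-correlated already-complete proteins over the
  samples where it is observed, with a deterministic trimmed least-squares
  fit (iterated OLS on the 75% of observations with smallest residuals).
  No random subsampling is used, so the result is a pure function of the
  matrix. Proteins observed fewer than four times fall back to the protein
  median. The robust sequential-regression scheme follows the cited
  imputation family by construction (ordering, regression on completed
  variables, robust loss); it is validated by oracle comparison against
  median imputation on synthetic masks, not by bit-equality with any other
  implementation.
* **Batch correction** (`correct_batch()`) delegates to the parametric
  empirical-Bayes location/scale adjustment in `sva::ComBat`, the same
  implementation family the study used. No covariates are protected by
  default (the original analysis does not state whether group labels were);
  covariate protection is available. A single batch returns the input
  unchanged; a batch with fewer than two samples is an error.
* **Replicate merging** averages each replicate pair element-wise on the
  linear scale and drops pooled channels; it is idempotent.

# Differential expression

`call_deps()` computes the fold change as the **ratio of linear-scale group
means** (the fold-change scale is not defined in the source analysis; this
choice is configurable) oriented `group_a / group_b`, tests on log2
abundances with a two-sided Welch t test (Satterthwaite degrees of
freedom), adjusts with Benjamini–Hochberg across all proteins tested in the
comparison (the BH family is the post-filter protein set), and calls
`up`/`down` at `fc > threshold` / `fc < 1/threshold` with adjusted
`p < alpha`. The study's two operating points are FC > 1.5 (enrichment
work) and FC > 1.2 (the prognostic feature pool). Constant proteins give an
undefined test and are called `ns`. Swapping the groups inverts the fold
change and preserves p-values exactly.

Small companion operations: direction-aware DEP overlap
(`overlap_deps()`), Tukey's-fences outlier trimming with
linear-interpolation quartiles (R type 7, fixed for reproducibility), and
pairwise-complete Pearson feature–fraction correlations with t-based
p-values.

# Clinical survival analysis

`fit_cox()` wraps `survival::coxph` with Efron tie handling by default
(configurable to Breslow — the original report does not state its choice),
Wald intervals, Harrell's C on the fitted linear predictor, partial-
likelihood AIC and the global score (log-rank) p. Character covariates use
treatment coding with the alphabetically first level as reference (the
original encodings are unstated). Age is dichotomized as 0 below the
cutoff, 1 at or above it (cutoff default: cohort median, 16 years in this
population); median splits send the boundary value to the upper group.
`compare_age_codings()` fits the multivariate model under both codings and
reports log-rank p, AIC and C-index with per-criterion winners. With 11
covariates and ~12 events the multivariate fit is intentionally fragile —
near-separation is flagged (`flagged` in `glance()`) rather than hidden.

# Prognostic models

Five models are specified (`model_spec()`): CliCox, CliRsf, ProtCox,
ProtRsf, CliProtRsf — Cox or log-rank-split random survival forest learners
(forests via `ranger`) over clinical features, a protein pool (differential
proteins at FC > 1.2), or both. The PM cohort is split ~60/40
(`split_train_test()`, event-stratified by default; the study's printed
50/35 split of 85 patients is reproduced with `n_train = 50`). Forest
hyperparameters are tuned by exhaustive grid search with 3-fold
cross-validated Harrell C (grid defaults: 250/500/1000 trees, mtry √p or
p/3, node size 3/6/15; the study's final values are in an unavailable
supplement, so the grid is package-defined and configurable). Ties prefer
the simpler model. Folds are seeded and guaranteed an event, refolding with
a warning when necessary.

By default the protein pool is computed on **training samples only**
(leak-free); the original analysis computed its 1,548-protein pool on the
full cohort, and that paper-faithful mode is available via
`pool_scope = "all"`.

**Feature selection.** ProtCox uses LASSO-Cox (`glmnet`) with the penalty
chosen by cross-validated partial-likelihood deviance at `lambda.min` and an
unpenalized refit on the selection. The forest models use the stability
rule: train the forest 100 times with different RNG states, rank the pool
by permutation importance each time, record the top 50, and keep features
recorded at least 50 times.

Three implementation decisions matter here and are worth stating plainly:

1. *Importance source.* Each repeat uses the forest's out-of-bag
   permutation importance (the explicit C-index-drop variant,
   `permutation_importance()`, is available and is used by the tests to
   validate the concept on held-out data). "Different initial states" is
   read as different RNG seeds for bootstrap and mtry draws.
2. *Ties and non-informative features.* Ties at the top-50 boundary are all
   included, but a feature with non-positive (or unmeasurable) permutation
   importance never counts as selected. Without this rule, a repeat with
   few events ranks hundreds of never-used features at importance exactly
   zero, the tie at the boundary sweeps them all in, and the "panel"
   becomes the whole pool.
3. *Per-repeat forest size* (`stability_num_trees`, default 25). This is
   deliberately small. Repeats differ only by RNG on the same training
   data, so with a large per-repeat forest the importance ranking converges
   and the *same* spuriously outcome-correlated noise proteins appear in
   the top 50 every repeat — on pure-noise pools the rule then returns
   panels of 3–11 features at 100–300 trees per repeat. A small forest
   leaves ranking noise between repeats, which is exactly the variability
   the ≥50/100 count threshold needs to filter spurious features — the role
   subsampling plays in classical stability selection. At 25 trees the
   procedure recovers 9–10 of 10 planted module proteins from a
   1,500-protein pool while returning empty panels on all pure-noise pools
   tried. This trade-off is a property of the selection rule itself and is
   the package's calibrated default, not a claim about the original
   study's settings. If the panel still comes back empty, model training
   falls back (with a warning) to the most frequently selected features.

# Risk stratification

`predict_survival_curve()` returns per-patient survival curves — the
ensemble Nelson–Aalen-based survival function on the training event-time
grid for forests, the baseline-hazard curve powered by `exp(lp)` for Cox.
The "expectation of the curve" is implemented as the restricted mean
survival time over a horizon (default: the maximum of the curve grid),
integrated by the trapezoid rule with the last value carried forward; an
unrestricted mean is undefined when curves do not reach zero. The Crank
score is `horizon − RMST` — the expected event exposure — so higher Crank
means higher risk.

The stratification threshold is the midpoint of the mean Cranks of the
recurrence and non-recurrence groups, computed on the **training set only**
(a shuffle of test outcomes provably changes nothing; this is asserted in
the tests). The figure-level description of the boundary as a Fisher
decision boundary conflicts with the methods-level "average of the mean
Cranks"; the methods text wins, and a pooled-variance Fisher/LDA boundary is
available via `threshold_method = "lda"` (the two coincide for balanced
groups with equal variances). Patients exactly at the threshold are
classified high-risk — conservative toward closer follow-up.
`evaluate_stratification()` treats high-risk as predicted recurrence and
reports the confusion matrix, accuracy, and per-partition Kaplan–Meier
curves with log-rank p.

# The pipeline and reproducibility

`run_pipeline()` executes simulate (or load) → preprocess → differential
expression → clinical Cox screen → train → stratify, writes every stage's
outputs as TSV/CSV/JSON, and emits a manifest with the configuration hash,
derived stage seeds, package versions and per-file MD5 checksums. One
master seed derives all stage seeds by fixed integer arithmetic, so a rerun
with the same configuration is byte-identical (timings go to a separate
JSON-lines log, never into the manifest). Unknown configuration keys are
rejected before any computation. A thin command-line wrapper lives at
`inst/cli/protrisk.R`; the R functions are the primary interface.

# Problem sizes used by the tests

The test-suite and the acceptance script use desk-scale versions of the
study design, chosen once as simulation sizes adequate for each property:
null false-discovery control over 100 seeds at 1,000 proteins and 40 + 40
samples; differential power at 80 + 80 samples (planted log2 fold change
1.0, residual SD 0.3); batch correction at 500 proteins, 85 + 83 samples,
8 batches; imputation over 10 MCAR masks at 150 proteins; hazard-ratio
recovery at n = 2,000 over 100 seeds; stability selection on a
1,500-protein pool with 200 PM patients (training n = 120, ~17 events at
the 14% event rate — a power-adequate recovery design; at the study's 85
patients the same procedure recovers 9/10) and pure-noise pools of the same
size over 30 seeds; stratification over 20 seeds at 300 proteins and 200 PM
patients; determinism on a 250-protein, 120-sample end-to-end run executed
twice. The full default pipeline configuration (2,000 proteins, 200 PM +
150 PB) completes in a few minutes on one core.

# Known limitations

* The generator's clinical covariates match printed marginal summaries, not
  the real joint distribution; fitted clinical hazard ratios on synthetic
  tables are not comparable to the published values beyond sign and rough
  magnitude.
* Stability selection over same-data repeats cannot distinguish a true
  signal from a noise feature that is strongly associated with outcome *in
  this dataset*; the small-forest default mitigates but does not remove
  this, and with very few events the selected panel should be read with
  corresponding caution.
* `lambda.min` LASSO-Cox over-selects under the null in a sizable minority
  of datasets; the tests assert median sparsity rather than a per-dataset
  guarantee.
* Proportional-hazards diagnostics, competing risks, calibration of
  absolute recurrence probabilities, and all enrichment/deconvolution
  analyses are out of scope.
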