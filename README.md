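# protrisk

Proteomic recurrence-risk modelling for pediatric papillary thyroid
carcinoma (PPTC).

Pediatric papillary thyroid carcinoma has high inter-tumor heterogeneity
and no widely adopted recurrence risk stratification criteria. This package
implements, as a tested and fully reproducible pipeline, a proteome-driven
prognostic workflow for that problem:

1. **Preprocessing** of a TMT protein abundance matrix (proteins × samples,
   16-plex batches with pooled reference channels and technical
   replicates): CV-based quality control, removal of proteins with a
   missing-value rate above 85%, robust sequential imputation,
   empirical-Bayes (ComBat) batch correction, half-minimum replacement of
   non-positive abundances, replicate merging.
2. **Differential expression** between groups (pediatric malignant PM,
   pediatric benign PB, adult malignant AM) by two-sided Welch's *t* test
   on log2 abundances with Benjamini–Hochberg adjustment and fold-change
   thresholds (FC > 1.5 for biology, FC > 1.2 to build the prognostic
   feature pool), plus direction-aware overlap, Tukey's-fences outlier
   trimming and Pearson feature–fraction correlations.
3. **Clinical survival screening** with Cox proportional-hazards models
   over 11 clinical features (univariate and multivariate, Efron ties,
   AIC / C-index / log-rank comparison of continuous vs categorical age),
   median splits and Kaplan–Meier log-rank tests.
4. **Prognostic models** — CliCox, CliRsf, ProtCox, ProtRsf and CliProtRsf:
   Cox or log-rank random-survival-forest learners over clinical and/or
   protein features, with a ~60/40 train/test split, grid-search tuning by
   3-fold cross-validated Harrell C-index, LASSO-Cox selection for ProtCox,
   and the stability rule for the forests: 100 training repeats with
   different RNG states, top-50 features by permutation importance per
   repeat, keep features selected at least 50 times.
5. **Risk stratification**: per-patient predicted survival curves; the
   Crank score (continuous risk ranking) `horizon − RMST`, the restricted
   mean survival time of the curve, so higher = riskier; a threshold at the
   midpoint of the mean training Cranks of the recurrence and
   non-recurrence groups; high/low classification with confusion matrix,
   accuracy, and per-partition Kaplan–Meier separation.

A **synthetic cohort generator** reproduces the statistical structure this
design assumes — the 85 PM / 83 PB / 66 AM layout in 16 batches of 15
tissues + 1 pooled channel, a co-regulated planted prognostic protein
module driving an exponential proportional-hazards recurrence process with
~85% censoring, planted differential proteins, batch effects, and
abundance-dependent missingness — with full ground truth for recovery
testing. A deterministic synthetic 85-patient clinical table calibrated to
the printed cohort summaries (mean tumor size 2.4 cm, 69 node-positive, 12
recurrences, median follow-up 71 months, median age 16) ships as
`inst/extdata/clinical_synthetic.csv`.

## Worked example

```r
library(protrisk)

cfg <- sim_config(n_pb = 60, n_pm = 100, n_am = 0, n_proteins = 400,
                  n_batches = 8, n_replicate_pairs = 4, n_dep = 30,
                  n_signal = 10, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <protrisk_cohort>
#> <abundance_matrix> 400 proteins x 172 samples (log2 scale, 23.3% missing)
#>   samples: PB=62, PM=102, POOL=8
#>   clinical: 100 PM patients, 14 recurrences (14.0%)
#>   truth: 30 planted DEPs, 10 signal proteins, 16058 masked entries

prep <- preprocess_cohort(cohort$abundance)
prep
#> <preprocessed>
#> <abundance_matrix> 400 proteins x 160 samples (linear scale, 0.0% missing)
#>   samples: PB=60, PM=100
#>   stages applied: filter -> impute -> correct_batch -> replace_nonpositive -> merge_replicates
#>   median pooled CV (pre-filter): 0.0270
```

The pooled-channel CV (~0.03) plays the role of the instrument-stability
check; preprocessing has filtered, imputed, batch-corrected and merged the
technical replicates down to the 160 biological samples.

```r
deps <- call_deps(prep$abundance, "PM", "PB", fc_threshold = 1.2)
pool <- deps$protein_id[deps$call != "ns"]   # 40 proteins at FC > 1.2

split <- split_train_test(cohort$clinical, seed = 3)   # 60/40, event-stratified
md    <- assemble_model_data(prep$abundance, cohort$clinical)
spec  <- model_spec("ProtRsf",
                    hyper_grid = default_rsf_grid(num_trees = c(100, 250),
                                                  mtry_frac = "sqrt",
                                                  min_node_size = c(3, 6)),
                    n_repeats = 100, top_k = 20, min_count = 50, seed = 11)
model <- train_model(spec, md, split, protein_pool = pool)
model
#> <risk_model> ProtRsf (rsf learner, 9 features)
#>   C-index: train 0.978 / cv 0.850 / test 0.918
```

The stability rule kept a 9-protein panel; 9 of the 10 planted prognostic
proteins are in it. The held-out C-index (0.918) is the concordance between
the forest's risk score and the observed recurrence order on the 40% of
patients never touched during training.

```r
strat <- risk_stratify(model, md)
strat
#> <risk_stratification> threshold 13.267 (horizon 64.4 months)
#> <stratification> accuracy 0.9100 (91/100 correct)
#>   TP=11 FP=6 TN=80 FN=3
#>   test: log-rank p = 0.0003611
#>   train: log-rank p = 9.42e-15
```

The threshold (13.3 months of expected event exposure within the 64-month
horizon) is computed from training patients only; classifying all 100
patients against it recovers 91% of outcomes, and the predicted high/low
groups have clearly separated recurrence-free survival on the held-out
partition (log-rank p = 3.6 × 10⁻⁴).

The whole chain is also available as one call — `run_pipeline()` executes
simulate → preprocess → differential expression → clinical Cox → train →
stratify from a single seeded configuration and writes a manifest of MD5
checksums that is byte-identical across reruns. Clinical-table analyses are
available directly:

```r
ref <- read_clinical_table(system.file("extdata", "clinical_synthetic.csv",
                                       package = "protrisk"))
describe_clinical(ref)       # n=85, 12 events, mean size 2.4, median follow-up 71
univariate_cox(ref, c("age", "TLNN", "LLNN"))
compare_age_codings(ref)     # categorical age wins log-rank p, AIC and C-index
```

## Package layout

| Area | Functions |
| --- | --- |
| synthetic cohorts | `sim_config()`, `generate_cohort()`, `simulate_survival()`, `inject_missingness()`, `write_cohort()` |
| preprocessing | `preprocess_cohort()`, `compute_cv()`, `qc_report()`, `filter_by_missingness()`, `impute_sequential()`, `correct_batch()`, `replace_nonpositive()`, `merge_replicates()` |
| differential | `call_deps()`, `welch_test()`, `bh_adjust()`, `overlap_deps()`, `tukey_fences_filter()`, `correlate_features()` |
| clinical survival | `fit_cox()`, `univariate_cox()`, `compare_age_codings()`, `categorize_age()`, `median_split()`, `km_logrank()`, `describe_clinical()` |
| prognostic models | `model_spec()`, `split_train_test()`, `tune_hyperparameters()`, `stability_select()`, `lasso_cox_select()`, `permutation_importance()`, `train_model()`, `evaluate_cindex()` |
| stratification | `predict_survival_curve()`, `compute_crank()`, `compute_threshold()`, `stratify_patients()`, `evaluate_stratification()`, `risk_stratify()` |
| workflow | `pipeline_config()`, `load_pipeline_config()`, `run_pipeline()` |

Result objects follow broom conventions (`tidy()`, `glance()`) and ship
`autoplot()` methods (volcano plot, Kaplan–Meier curves, stability counts,
Crank densities). The methods vignette
(`vignettes/protrisk-methods.Rmd`) documents the model, every tunable
parameter, the generator's assumptions, and the package's design decisions.
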