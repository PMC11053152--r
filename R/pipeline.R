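#' Pipeline configuration
#'
#' A validated, nested configuration covering every stage of the workflow:
#' cohort simulation (or input paths to an existing matrix + clinical
#' table), preprocessing, differential expression, clinical survival
#' analysis, prognostic modelling and risk stratification. A single master
#' seed deterministically derives every stage seed. Unknown keys are
#' rejected.
#'
#' The default configuration runs a desk-scale synthetic cohort (2,000
#' proteins, 200 PM + 150 PB samples) rather than the full study-scale
#' layout, so a complete run stays light; pass a custom `sim` config for
#' other sizes.
#'
#' @param sim A [sim_config()] (or `NULL` when `input` paths are given).
#' @param input Optional list: `abundance`, `samples`, `clinical` paths.
#' @param na_threshold Missingness filter threshold.
#' @param dep_fc,dep_alpha DEP thresholds for the reported comparison.
#' @param pool_fc Fold-change threshold building the prognostic feature
#'   pool (the study uses 1.2).
#' @param pool_scope `"train"` computes the feature-pool DEPs on training
#'   samples only (leak-free, default); `"all"` reproduces the study's
#'   whole-cohort pool.
#' @param model_name Which of the five models to train.
#' @param split_ratio,stratify_split Train/test split controls.
#' @param n_repeats,top_k,min_count,stability_num_trees Stability rule.
#' @param hyper_grid Forest tuning grid.
#' @param crank_horizon Optional Crank horizon (months).
#' @param threshold_method `"midpoint"` or `"lda"`.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(n_proteins = 2000, n_pm = 200,
                                             n_pb = 150, n_am = 0,
                                             n_replicate_pairs = 4,
                                             n_batches = 10),
                            input = NULL,
                            na_threshold = 0.85,
                            dep_fc = 1.5, dep_alpha = 0.05,
                            pool_fc = 1.2, pool_scope = c("train", "all"),
                            model_name = "ProtRsf",
                            split_ratio = 0.6, stratify_split = TRUE,
                            n_repeats = 100, top_k = 50, min_count = 50,
                            stability_num_trees = 25,
                            hyper_grid = default_rsf_grid(),
                            crank_horizon = NULL,
                            threshold_method = "midpoint",
                            seed = 1L) {
  pool_scope <- match.arg(pool_scope)
  cfg <- list(sim = sim, input = input, na_threshold = na_threshold,
              dep_fc = dep_fc, dep_alpha = dep_alpha, pool_fc = pool_fc,
              pool_scope = pool_scope, model_name = model_name,
              split_ratio = split_ratio, stratify_split = stratify_split,
              n_repeats = n_repeats, top_k = top_k, min_count = min_count,
              stability_num_trees = stability_num_trees,
              hyper_grid = hyper_grid, crank_horizon = crank_horizon,
              threshold_method = threshold_method, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("sim", "input", "na_threshold", "dep_fc", "dep_alpha", "pool_fc",
             "pool_scope", "model_name", "split_ratio", "stratify_split",
             "n_repeats", "top_k", "min_count", "stability_num_trees",
             "hyper_grid", "crank_horizon", "threshold_method", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop_input("unknown config keys: %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$sim) && is.null(cfg$input)) {
    stop_input("either a sim config or input paths must be given")
  }
  if (!is.null(cfg$input)) {
    need <- c("abundance", "samples", "clinical")
    missing <- setdiff(need, names(cfg$input))
    if (length(missing)) stop_input("input paths missing: %s", paste(missing, collapse = ", "))
    absent <- unlist(cfg$input[need])[!file.exists(unlist(cfg$input[need]))]
    if (length(absent)) stop_input("input files not found: %s", paste(absent, collapse = ", "))
  }
  if (!cfg$model_name %in% c("CliCox", "CliRsf", "ProtCox", "ProtRsf", "CliProtRsf")) {
    stop_input("unknown model '%s'", cfg$model_name)
  }
  if (cfg$split_ratio <= 0 || cfg$split_ratio >= 1) stop_input("split_ratio must be in (0,1)")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()]; the `sim`
#' section overrides [sim_config()] defaults field by field.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim <- do.call(sim_config, raw$sim)
    raw$sim <- NULL
  }
  args <- raw
  if (!is.null(sim)) args$sim <- sim
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> differential expression ->
#' clinical Cox screen -> model training -> risk stratification, writing
#' every stage's outputs under `out_dir` together with a manifest recording
#' the configuration hash, stage seeds, package versions and per-file MD5
#' checksums. A rerun with the same configuration reproduces an identical
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return A list of class `pipeline_run`: stage results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_stage <- function(stage, t0) {
    line <- jsonlite::toJSON(list(stage = stage,
                                  elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3)),
                             auto_unbox = TRUE)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  seed <- config$seed
  outputs <- character()

  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
    log_stage(stage, t0)
    res
  }

  # -- simulate / load ------------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$input)) {
      list(abundance = read_abundance(config$input$abundance, config$input$samples),
           clinical = read_clinical_table(config$input$clinical),
           truth = NULL)
    } else {
      sim <- config$sim
      sim$seed <- derive_seed(seed, 1)
      generate_cohort(sim)
    }
  })
  if (is.null(config$input)) {
    run_stage("write_cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
    outputs <- c(outputs, file.path("cohort", c("abundance.tsv", "samples.tsv",
                                                "clinical.csv", "truth.json")))
  }

  # -- preprocess -----------------------------------------------------------
  prep <- run_stage("preprocess",
                    preprocess_cohort(cohort$abundance, na_threshold = config$na_threshold))
  write_abundance(prep$abundance, file.path(out_dir, "matrix_preprocessed.tsv"),
                  file.path(out_dir, "samples_preprocessed.tsv"))
  qc <- prep$qc
  jsonlite::write_json(
    list(median_pooled_cv = qc$median_pooled_cv,
         median_replicate_cv = as.list(qc$median_replicate_cv)),
    file.path(out_dir, "qc_summary.json"), auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "matrix_preprocessed.tsv", "samples_preprocessed.tsv",
               "qc_summary.json")

  # -- differential expression ---------------------------------------------
  deps <- run_stage("deps",
                    call_deps(prep$abundance, "PM", "PB",
                              fc_threshold = config$dep_fc, alpha = config$dep_alpha))
  readr::write_csv(dplyr::mutate(tibble::as_tibble(deps),
                                 dplyr::across(dplyr::where(is.double), format_full)),
                   file.path(out_dir, "dep_table.csv"))
  outputs <- c(outputs, "dep_table.csv")

  # -- clinical survival ----------------------------------------------------
  clinical <- cohort$clinical
  clin <- run_stage("clin_cox", {
    uni <- univariate_cox(clinical)
    cmp <- compare_age_codings(clinical)
    list(univariate = uni, age_codings = cmp)
  })
  readr::write_csv(dplyr::mutate(clin$univariate,
                                 dplyr::across(dplyr::where(is.double), format_full)),
                   file.path(out_dir, "cox_univariate.csv"))
  jsonlite::write_json(clin$age_codings$comparison,
                       file.path(out_dir, "age_coding_comparison.json"),
                       dataframe = "columns", digits = NA)
  outputs <- c(outputs, "cox_univariate.csv", "age_coding_comparison.json")

  # -- prognostic model -----------------------------------------------------
  model <- run_stage("train", {
    split <- split_train_test(clinical, ratio = config$split_ratio,
                              seed = derive_seed(seed, 2),
                              stratify = config$stratify_split)
    pool_matrix <- prep$abundance
    if (config$pool_scope == "train") {
      keep <- pool_matrix$samples$group != "PM" |
        pool_matrix$samples$sample_id %in% split$train_ids
      pool_matrix$values <- pool_matrix$values[, keep, drop = FALSE]
      pool_matrix$samples <- pool_matrix$samples[keep, ]
    }
    pool_deps <- call_deps(pool_matrix, "PM", "PB",
                           fc_threshold = config$pool_fc, alpha = config$dep_alpha)
    pool <- pool_deps$protein_id[pool_deps$call != "ns"]
    if (length(pool) < config$top_k) {
      warn_protrisk("DEP pool (%d) smaller than top_k; using the %d proteins with smallest adjusted p",
                    length(pool), config$top_k)
      pool <- pool_deps$protein_id[order(pool_deps$p_adj)][seq_len(config$top_k)]
    }
    spec <- model_spec(config$model_name, hyper_grid = config$hyper_grid,
                       n_repeats = config$n_repeats, top_k = config$top_k,
                       min_count = config$min_count,
                       stability_num_trees = config$stability_num_trees,
                       seed = derive_seed(seed, 3))
    mdata <- assemble_model_data(prep$abundance, clinical)
    train_model(spec, mdata, split, protein_pool = pool)
  })
  readr::write_csv(dplyr::mutate(model$metrics,
                                 dplyr::across(dplyr::where(is.double), format_full)),
                   file.path(out_dir, "model_metrics.csv"))
  if (!is.null(model$selection) && inherits(model$selection, "stability_result")) {
    readr::write_csv(tidy(model$selection), file.path(out_dir, "stability_counts.csv"))
    outputs <- c(outputs, "stability_counts.csv")
  }
  outputs <- c(outputs, "model_metrics.csv")

  # -- stratification -------------------------------------------------------
  strat <- run_stage("stratify", {
    mdata <- assemble_model_data(prep$abundance, clinical)
    risk_stratify(model, mdata, horizon = config$crank_horizon,
                  threshold_method = config$threshold_method)
  })
  readr::write_csv(dplyr::mutate(strat$cranks,
                                 dplyr::across(dplyr::where(is.double), format_full)),
                   file.path(out_dir, "cranks.csv"))
  readr::write_csv(dplyr::mutate(strat$curves,
                                 dplyr::across(dplyr::where(is.double), format_full)),
                   file.path(out_dir, "survival_curves.csv"))
  jsonlite::write_json(
    list(threshold = strat$threshold, horizon = strat$horizon,
         accuracy = strat$evaluation$accuracy,
         confusion = as.list(strat$evaluation$confusion),
         logrank_p = lapply(strat$evaluation$km, function(k) if (is.null(k)) NULL else k$p)),
    file.path(out_dir, "stratification.json"), auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "cranks.csv", "survival_curves.csv", "stratification.json")

  # -- manifest -------------------------------------------------------------
  cfg_serial <- config
  cfg_serial$hyper_grid <- as.list(cfg_serial$hyper_grid)
  cfg_json <- jsonlite::toJSON(unclass(cfg_serial), auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  checks <- tools::md5sum(file.path(out_dir, sort(outputs)))
  names(checks) <- sort(outputs)
  manifest <- list(
    config_md5 = unname(tools::md5sum(write_temp(cfg_json))),
    master_seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1),
                       split = derive_seed(seed, 2),
                       model = derive_seed(seed, 3)),
    versions = list(r = paste(R.version$major, R.version$minor, sep = "."),
                    protrisk = as.character(utils::packageVersion("protrisk")),
                    survival = as.character(utils::packageVersion("survival")),
                    ranger = as.character(utils::packageVersion("ranger"))),
    outputs = as.list(checks)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  structure(list(cohort = cohort, preprocessed = prep, deps = deps,
                 clinical_results = clin, model = model, stratification = strat,
                 manifest_path = manifest_path, out_dir = out_dir),
            class = "pipeline_run")
}

write_temp <- function(text) {
  f <- tempfile(fileext = ".json")
  writeLines(text, f)
  f
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$out_dir, "\n")
  print(x$model)
  print(x$stratification$evaluation)
  invisible(x)
}
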