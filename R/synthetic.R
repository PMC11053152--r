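#' Simulation configuration for synthetic PPTC-like cohorts
#'
#' Defines every knob of the synthetic cohort generator. The defaults
#' reproduce the layout of the study cohort this package models: 85 pediatric
#' malignant (PM), 83 pediatric benign (PB) and 66 adult malignant (AM)
#' nodules, two technical replicates per group (240 tissue channels from 234
#' biological samples), 16 TMT batches of 15 tissues plus one pooled reference
#' channel each, ~9,154 quantified proteins, follow-up with a median near 71
#' months, and a recurrence (event) fraction near 14%.
#'
#' Planted structure, recorded in the returned ground truth:
#' \itemize{
#'   \item `n_dep` differential proteins shifted by `dep_log2fc` (signed) in
#'     the PM group.
#'   \item `n_signal` prognostic proteins forming a signed co-regulated
#'     "risk program" module: each loads (with its sign) on a shared latent
#'     per-sample risk factor with loading `signal_module_sd` on the log2
#'     scale, so the planted panel is mutually correlated, as coherent
#'     prognostic programs in tumor proteomes are. They also receive the
#'     `dep_log2fc` group shift so they fall inside the differential pool
#'     that feeds the prognostic models. Recurrence hazard follows a
#'     proportional-hazards model with linear predictor
#'     `sum_j beta_j * z_ij` over the standardized signal-protein
#'     abundances, `beta_j = +/- signal_loghr`.
#'   \item Additive per-batch, per-protein offsets with SD `batch_sd`.
#'   \item `n_factors` global latent factors (loading SD `factor_sd`)
#'     emulating co-regulation of the bulk proteome.
#'   \item Abundance-dependent (MNAR) missingness with steepness
#'     `mnar_slope`, plus completely-at-random missingness `mcar_rate`.
#' }
#'
#' @param n_pb,n_pm,n_am Biological sample counts per group.
#' @param n_proteins Number of proteins.
#' @param n_batches Number of TMT batches.
#' @param n_pooled_per_batch Pooled reference channels per batch.
#' @param n_replicate_pairs Technical replicate pairs (spread round-robin
#'   across groups).
#' @param n_dep Planted group-differential proteins.
#' @param dep_log2fc Planted effect size on the log2 scale.
#' @param n_signal Planted prognostic proteins.
#' @param signal_loghr Per-SD log hazard ratio of each signal protein.
#' @param signal_module_sd Loading of the shared risk-program factor on each
#'   signal protein (log2 scale).
#' @param baseline_hazard Events/month for a patient at the linear-predictor
#'   mean, or `NULL` to calibrate it so the expected event fraction equals
#'   `target_event_fraction`.
#' @param censor_time_dist `list(min=, max=)`, censoring follow-up drawn
#'   uniformly on this window (months).
#' @param target_event_fraction Desired fraction of patients with observed
#'   recurrence, in (0, 1).
#' @param batch_sd Additive log2-scale batch-effect SD.
#' @param noise_sd Residual log2 SD; technical replicates and pooled channels
#'   are re-noised at `noise_sd / 2`.
#' @param n_factors,factor_sd Global latent factors and their loading SD.
#' @param mnar_slope Steepness of the logistic abundance-dependent
#'   missingness; 0 disables MNAR masking.
#' @param mnar_base Baseline MNAR probability at the median abundance rank.
#' @param mcar_rate Uniform missingness rate in [0, 1).
#' @param seed Integer seed; identical configs give byte-identical cohorts.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pb = 83, n_pm = 85, n_am = 66,
                       n_proteins = 9154,
                       n_batches = 16,
                       n_pooled_per_batch = 1,
                       n_replicate_pairs = 6,
                       n_dep = 300,
                       dep_log2fc = 1.0,
                       n_signal = 10,
                       signal_loghr = 0.25,
                       signal_module_sd = 1.33,
                       baseline_hazard = NULL,
                       censor_time_dist = list(min = 42, max = 100),
                       target_event_fraction = 0.14,
                       batch_sd = 0.5,
                       noise_sd = 0.5,
                       n_factors = 3,
                       factor_sd = 0.5,
                       mnar_slope = 8,
                       mnar_base = 0.08,
                       mcar_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_pb = n_pb, n_pm = n_pm, n_am = n_am, n_proteins = n_proteins,
    n_batches = n_batches, n_pooled_per_batch = n_pooled_per_batch,
    n_replicate_pairs = n_replicate_pairs,
    n_dep = n_dep, dep_log2fc = dep_log2fc,
    n_signal = n_signal, signal_loghr = signal_loghr,
    signal_module_sd = signal_module_sd,
    baseline_hazard = baseline_hazard,
    censor_time_dist = censor_time_dist,
    target_event_fraction = target_event_fraction,
    batch_sd = batch_sd, noise_sd = noise_sd,
    n_factors = n_factors, factor_sd = factor_sd,
    mnar_slope = mnar_slope, mnar_base = mnar_base, mcar_rate = mcar_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_pb", "n_pm", "n_am", "n_proteins", "n_batches",
              "n_pooled_per_batch", "n_replicate_pairs", "n_dep", "n_signal",
              "n_factors")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop_input("%s must be >= 0", nm)
  }
  if (cfg$n_dep + cfg$n_signal > cfg$n_proteins) {
    stop_input("n_dep + n_signal must not exceed n_proteins")
  }
  if (cfg$mcar_rate < 0 || cfg$mcar_rate >= 1) stop_input("mcar_rate must be in [0, 1)")
  if (cfg$target_event_fraction <= 0 || cfg$target_event_fraction >= 1) {
    stop_input("target_event_fraction must be in (0, 1)")
  }
  if (cfg$censor_time_dist$min <= 0 || cfg$censor_time_dist$max < cfg$censor_time_dist$min) {
    stop_input("censor_time_dist must satisfy 0 < min <= max")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d proteins; samples PB=%d PM=%d AM=%d (+%d replicate pairs, %d batches x %d pooled)\n",
    x$n_proteins, x$n_pb, x$n_pm, x$n_am, x$n_replicate_pairs, x$n_batches,
    x$n_pooled_per_batch
  ))
  cat(sprintf(
    "  planted: %d DEPs (log2FC %.2f), %d signal proteins (log-HR %.2f/SD, module SD %.2f)\n",
    x$n_dep, x$dep_log2fc, x$n_signal, x$signal_loghr, x$signal_module_sd
  ))
  cat(sprintf("  events: target fraction %.2f, censoring U(%g, %g) months; seed %d\n",
              x$target_event_fraction, x$censor_time_dist$min,
              x$censor_time_dist$max, x$seed))
  invisible(x)
}

#' Simulate right-censored exponential survival outcomes
#'
#' Standard proportional-hazards generator: event times are exponential with
#' rate `baseline_hazard * exp(lp_i)`, observed time is the minimum of event
#' and censoring time, and the event indicator is 1 iff the event precedes
#' censoring.
#'
#' @param linear_predictors Numeric vector of per-patient log relative
#'   hazards.
#' @param baseline_hazard Positive rate (events/month) at `lp = 0`.
#' @param censor_times Per-patient censoring times in months (> 0).
#' @param seed Optional integer seed.
#' @return A tibble with `time` (months) and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictors, baseline_hazard, censor_times,
                              seed = NULL) {
  if (!all(is.finite(linear_predictors))) stop_input("linear predictors must be finite")
  if (baseline_hazard <= 0) stop_input("baseline_hazard must be positive")
  if (any(censor_times <= 0)) stop_input("censor times must be positive")
  n <- length(linear_predictors)
  if (length(censor_times) == 1) censor_times <- rep(censor_times, n)
  if (length(censor_times) != n) stop_input("censor_times must have length 1 or n")
  draw <- function() rexp(n, rate = baseline_hazard * exp(linear_predictors))
  t_event <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(
    time = pmin(t_event, censor_times),
    event = as.integer(t_event <= censor_times)
  )
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' For exponential event times and uniform censoring on `[cmin, cmax]`, the
#' probability of an observed event for a patient with rate `r` is
#' `1 - (exp(-r cmin) - exp(-r cmax)) / (r (cmax - cmin))`. The baseline
#' hazard is found by root-finding on the cohort mean of this expression.
#'
#' @param linear_predictors Realized per-patient log relative hazards.
#' @param censor_min,censor_max Censoring window (months).
#' @param target Target event fraction in (0, 1).
#' @return The calibrated baseline hazard (events/month).
#' @export
calibrate_baseline_hazard <- function(linear_predictors, censor_min, censor_max,
                                      target) {
  expect_events <- function(h) {
    r <- h * exp(linear_predictors)
    if (censor_max > censor_min) {
      p <- 1 - (exp(-r * censor_min) - exp(-r * censor_max)) / (r * (censor_max - censor_min))
    } else {
      p <- 1 - exp(-r * censor_min)
    }
    mean(p)
  }
  f <- function(h) expect_events(h) - target
  lo <- 1e-12; hi <- 1e4
  if (f(hi) < 0) {
    warn_protrisk("target event fraction %.3f unreachable; achieved at most %.3f",
                  target, expect_events(hi))
    return(hi)
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Hide matrix entries by an MNAR + MCAR mechanism
#'
#' Each entry is masked with probability
#' `mcar_rate + (1 - mcar_rate) * p_mnar`, where `p_mnar` is logistic in the
#' negated abundance rank: low-abundance entries are preferentially lost, as
#' in real TMT proteomes where low-signal proteins drop below the
#' identification limit. `p_mnar = plogis(qlogis(mnar_base) +
#' mnar_slope * (0.5 - rank))` with `rank` the overall abundance rank scaled
#' to (0, 1); `mnar_slope = 0` disables the MNAR component entirely.
#'
#' @param x A numeric matrix or [abundance_matrix()] with no missing entries.
#' @param mnar_slope,mnar_base MNAR steepness and baseline rate.
#' @param mcar_rate Uniform masking rate in [0, 1).
#' @param seed Integer seed.
#' @return A list: `matrix` (same type as `x`, with `NA`s) and
#'   `masked_entries`, a tibble of `protein_id`, `sample_id`, `value`
#'   (the hidden pre-mask values).
#' @export
inject_missingness <- function(x, mnar_slope, mcar_rate, seed,
                               mnar_base = 0.08) {
  is_am <- inherits(x, "abundance_matrix")
  values <- if (is_am) x$values else as.matrix(x)
  if (anyNA(values)) stop_input("inject_missingness requires a complete matrix")
  if (mcar_rate < 0 || mcar_rate >= 1) stop_input("mcar_rate must be in [0, 1)")
  if (mnar_base <= 0 || mnar_base >= 1) stop_input("mnar_base must be in (0, 1)")
  if (mnar_slope < 0) stop_input("mnar_slope must be >= 0")
  n <- length(values)
  p_mnar <- if (mnar_slope > 0) {
    r <- rank(values, ties.method = "average") / (n + 1)
    plogis(qlogis(mnar_base) + mnar_slope * (0.5 - r))
  } else {
    rep(0, n)
  }
  p_miss <- mcar_rate + (1 - mcar_rate) * p_mnar
  mask <- withr::with_seed(seed, runif(n) < p_miss)
  mask <- matrix(mask, nrow = nrow(values))
  idx <- which(mask, arr.ind = TRUE)
  masked <- tibble::tibble(
    protein_id = rownames(values)[idx[, 1]] %||% as.character(idx[, 1]),
    sample_id = colnames(values)[idx[, 2]] %||% as.character(idx[, 2]),
    value = values[mask]
  )
  values[mask] <- NA_real_
  if (is_am) {
    out <- x
    out$values <- values
    attr(out, "stages") <- attr(x, "stages")
  } else {
    out <- values
  }
  list(matrix = out, masked_entries = masked)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces an abundance matrix with the full study layout (biological
#' samples, technical replicate pairs, pooled reference channels, batch
#' structure, abundance-dependent missingness), a clinical table for the PM
#' patients with 11 covariates and right-censored recurrence outcomes driven
#' by the planted signal proteins, and a ground-truth record for recovery
#' tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `protrisk_cohort`: `abundance`
#'   ([abundance_matrix()], log2 scale), `clinical` (tibble), `truth` (list:
#'   `dep` tibble with signed planted log2 fold changes, `signal` tibble with
#'   true log-HR coefficients, `batch_offsets` matrix, `masked_entries`
#'   tibble, `baseline_hazard`, `linear_predictors`).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  p <- cfg$n_proteins
  protein_ids <- sprintf("P%05d", seq_len(p))

  groups <- c(rep("PB", cfg$n_pb), rep("PM", cfg$n_pm), rep("AM", cfg$n_am))
  n_bio <- length(groups)
  idx_within <- stats::ave(seq_len(n_bio), groups, FUN = seq_along)
  sample_ids <- sprintf("%s%03d", groups, idx_within)

  # planted protein sets: disjoint; signal proteins double as group-shifted
  # so they land in the differential pool used by the prognostic models
  chosen <- sample(p, cfg$n_dep + cfg$n_signal)
  dep_idx <- chosen[seq_len(cfg$n_dep)]
  sig_idx <- chosen[cfg$n_dep + seq_len(cfg$n_signal)]
  dep_sign <- sample(c(1, -1), cfg$n_dep, replace = TRUE)
  sig_sign <- if (cfg$n_signal > 0) rep_len(c(1, -1), cfg$n_signal) else integer()

  baseline <- rnorm(p, mean = 20, sd = 2)

  # biological signal per patient: baseline + group effect + global latent
  # factors + risk-program module + residual biological noise
  signal <- matrix(baseline, nrow = p, ncol = n_bio)
  is_pm <- groups == "PM"
  if (cfg$n_dep > 0) {
    signal[dep_idx, is_pm] <- signal[dep_idx, is_pm] + dep_sign * cfg$dep_log2fc
  }
  if (cfg$n_signal > 0) {
    signal[sig_idx, is_pm] <- signal[sig_idx, is_pm] + sig_sign * cfg$dep_log2fc
  }
  loadings <- matrix(rnorm(p * cfg$n_factors, 0, cfg$factor_sd), nrow = p)
  if (cfg$n_signal > 0) loadings[sig_idx, ] <- 0
  if (cfg$n_factors > 0) {
    scores <- matrix(rnorm(cfg$n_factors * n_bio), nrow = cfg$n_factors)
    signal <- signal + loadings %*% scores
  }
  risk_factor <- rnorm(n_bio)
  if (cfg$n_signal > 0) {
    signal[sig_idx, ] <- signal[sig_idx, ] +
      outer(sig_sign * cfg$signal_module_sd, risk_factor)
  }
  signal <- signal + matrix(rnorm(p * n_bio, 0, cfg$noise_sd), nrow = p)

  # technical replicate columns: same biological signal, re-noised
  rep_src <- integer(0)
  if (cfg$n_replicate_pairs > 0) {
    grp_levels <- unique(groups)
    src_by_grp <- split(seq_len(n_bio), groups)[grp_levels]
    rep_src <- unlist(lapply(seq_len(cfg$n_replicate_pairs), function(k) {
      g <- grp_levels[(k - 1) %% length(grp_levels) + 1]
      src_by_grp[[g]][ (k - 1) %/% length(grp_levels) + 1 ]
    }), use.names = FALSE)
  }
  tech_sd <- cfg$noise_sd / 2
  rep_cols <- if (length(rep_src)) {
    signal[, rep_src, drop = FALSE] + matrix(rnorm(p * length(rep_src), 0, tech_sd), nrow = p)
  } else {
    matrix(numeric(0), nrow = p)
  }
  rep_ids <- if (length(rep_src)) paste0(sample_ids[rep_src], "_rep") else character(0)

  tissue_vals <- cbind(signal, rep_cols)
  tissue_samples <- tibble::tibble(
    sample_id = c(sample_ids, rep_ids),
    group = c(groups, groups[rep_src]),
    replicate_of = c(rep(NA_character_, n_bio), sample_ids[rep_src])
  )

  # randomized allocation of tissue columns to batches
  n_tissue <- nrow(tissue_samples)
  batch_of <- sample(rep_len(seq_len(cfg$n_batches), n_tissue))
  tissue_samples$batch <- batch_of

  batch_offsets <- matrix(rnorm(p * cfg$n_batches, 0, cfg$batch_sd), nrow = p,
                          dimnames = list(protein_ids, paste0("batch", seq_len(cfg$n_batches))))

  # pooled reference channels: per-batch mean of the batch's tissue signal,
  # re-noised at the technical SD
  pooled_vals <- NULL
  pooled_samples <- NULL
  if (cfg$n_pooled_per_batch > 0) {
    pooled_list <- lapply(seq_len(cfg$n_batches), function(b) {
      m <- rowMeans(tissue_vals[, batch_of == b, drop = FALSE])
      vapply(seq_len(cfg$n_pooled_per_batch), function(j) {
        m + rnorm(p, 0, tech_sd)
      }, numeric(p))
    })
    pooled_vals <- do.call(cbind, pooled_list)
    pooled_ids <- paste0("POOL_B",
                         rep(sprintf("%02d", seq_len(cfg$n_batches)),
                             each = cfg$n_pooled_per_batch))
    if (cfg$n_pooled_per_batch > 1) {
      pooled_ids <- paste0(pooled_ids, "_", rep(seq_len(cfg$n_pooled_per_batch),
                                                times = cfg$n_batches))
    }
    pooled_samples <- tibble::tibble(
      sample_id = pooled_ids,
      group = "POOL",
      replicate_of = NA_character_,
      batch = rep(seq_len(cfg$n_batches), each = cfg$n_pooled_per_batch)
    )
  }

  all_vals <- cbind(tissue_vals, pooled_vals)
  all_samples <- dplyr::bind_rows(tissue_samples, pooled_samples)
  all_vals <- all_vals + batch_offsets[, all_samples$batch, drop = FALSE]
  dimnames(all_vals) <- list(protein_ids, all_samples$sample_id)

  abund <- abundance_matrix(all_vals, all_samples, scale = "log2")

  masked <- tibble::tibble(protein_id = character(), sample_id = character(),
                           value = numeric())
  if (cfg$mnar_slope > 0 || cfg$mcar_rate > 0) {
    miss <- inject_missingness(abund, cfg$mnar_slope, cfg$mcar_rate,
                               seed = derive_seed(cfg$seed, 101),
                               mnar_base = cfg$mnar_base)
    abund <- miss$matrix
    masked <- miss$masked_entries
  }

  # ---- clinical table and recurrence outcomes for the PM patients ----
  pm_idx <- which(is_pm)
  n_pm <- length(pm_idx)
  clinical <- NULL
  truth_signal <- tibble::tibble(protein_id = protein_ids[sig_idx],
                                 beta = sig_sign * cfg$signal_loghr)
  lp <- numeric(0)
  h0 <- cfg$baseline_hazard
  if (n_pm > 0) {
    if (cfg$n_signal > 0) {
      z <- scale(t(signal[sig_idx, pm_idx, drop = FALSE]))
      lp <- as.numeric(z %*% truth_signal$beta)
    } else {
      lp <- rep(0, n_pm)
    }
    cmin <- cfg$censor_time_dist$min; cmax <- cfg$censor_time_dist$max
    if (is.null(h0)) h0 <- calibrate_baseline_hazard(lp, cmin, cmax, cfg$target_event_fraction)
    censor <- runif(n_pm, cmin, cmax)
    outcome <- simulate_survival(lp, h0, censor)
    clinical <- simulate_clinical_covariates(n_pm)
    clinical$patient_id <- sample_ids[pm_idx]
    clinical <- dplyr::relocate(clinical, "patient_id")
    clinical$event <- outcome$event
    clinical$time <- outcome$time
  }

  truth <- list(
    dep = tibble::tibble(protein_id = protein_ids[dep_idx],
                         log2fc = dep_sign * cfg$dep_log2fc),
    signal = truth_signal,
    batch_offsets = batch_offsets,
    masked_entries = masked,
    baseline_hazard = h0,
    linear_predictors = lp
  )
  structure(list(abundance = abund, clinical = clinical, truth = truth,
                 config = cfg),
            class = "protrisk_cohort")
}

# Clinical covariates calibrated to the printed cohort summaries: age about
# 15.6 +/- 2.4 years truncated to [8, 18]; ~27% male; nodule size about
# 2.4 +/- 1.3 cm; 19% multifocal; ~81% node-positive (zero-inflated Poisson
# node counts); ~45% total thyroidectomy; generative forms are conventions,
# only the summary statistics are anchored.
simulate_clinical_covariates <- function(n) {
  draw_trunc <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mean, sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  }
  age <- round(draw_trunc(n, 15.6, 2.4, 8, 18))
  gender <- ifelse(runif(n) < 23 / 85, "male", "female")
  size <- round(pmax(draw_trunc(n, 2.4, 1.3, 0.3, 8), 0.3), 1)
  multifocality <- rbinom(n, 1, 16 / 85)
  ete <- rbinom(n, 1, 0.25)
  # zero-inflated Poisson node counts; lateral nodes a subset of total
  tlnn <- ifelse(runif(n) < 69 / 85, rpois(n, 5) + 1L, 0L)
  llnn <- ifelse(tlnn > 0 & runif(n) < 43 / 69, pmin(rpois(n, 3) + 1L, tlnn), 0L)
  dissected <- tlnn + rpois(n, 6) + 1L
  tlnr <- tlnn / dissected
  llnr <- llnn / dissected
  surgery <- ifelse(runif(n) < 38 / 85, "total", "lobectomy")
  ht <- rbinom(n, 1, 0.2)
  tibble::tibble(
    age = age, gender = gender, max_nodule_size = size,
    multifocality = multifocality, ETE = ete,
    TLNR = tlnr, LLNR = llnr, TLNN = tlnn, LLNN = llnn,
    surgery = surgery, HT = ht
  )
}

#' @export
print.protrisk_cohort <- function(x, ...) {
  cat("<protrisk_cohort>\n")
  print(x$abundance)
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical: %d PM patients, %d recurrences (%.1f%%)\n",
                nrow(x$clinical), sum(x$clinical$event),
                100 * mean(x$clinical$event)))
  }
  cat(sprintf("  truth: %d planted DEPs, %d signal proteins, %d masked entries\n",
              nrow(x$truth$dep), nrow(x$truth$signal),
              nrow(x$truth$masked_entries)))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Abundance and sample metadata as TSV, clinical table as CSV, ground truth
#' as JSON.
#'
#' @param cohort A `protrisk_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"),
                  file.path(dir, "samples.tsv"))
  if (!is.null(cohort$clinical)) {
    readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  }
  truth <- cohort$truth
  truth$batch_offsets <- NULL  # large; regenerable from the config seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
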