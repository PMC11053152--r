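#' Per-protein coefficient of variation
#'
#' CV = sample SD / mean of the non-missing log2 abundances of each protein
#' across the given samples. Missing values are omitted; proteins with fewer
#' than two observed values, or mean zero, get an undefined (`NA`) CV.
#' The sample (n-1) standard deviation is used.
#'
#' @param x An [abundance_matrix()] (converted to log2 if on linear scale).
#' @param sample_subset Character vector of sample ids (>= 2).
#' @return A tibble: `protein_id`, `n_obs`, `cv`.
#' @export
compute_cv <- function(x, sample_subset) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (length(sample_subset) == 0) stop_input("sample subset is empty")
  if (length(sample_subset) < 2) stop_input("CV needs at least 2 samples")
  missing_ids <- setdiff(sample_subset, colnames(x$values))
  if (length(missing_ids)) stop_input("unknown sample ids: %s", paste(missing_ids, collapse = ", "))
  v <- as_log2(x)$values[, sample_subset, drop = FALSE]
  n_obs <- unname(rowSums(!is.na(v)))
  m <- unname(rowMeans(v, na.rm = TRUE))
  s <- unname(apply(v, 1, sd, na.rm = TRUE))
  cv <- ifelse(n_obs >= 2 & is.finite(m) & m != 0, s / m, NA_real_)
  tibble::tibble(protein_id = rownames(v), n_obs = n_obs, cv = cv)
}

#' Quality-control report: pooled-sample and replicate CVs, NA rates
#'
#' Mirrors the study's QC: per-protein CVs across the pooled reference
#' channels, per-protein CVs within each technical replicate pair, and the
#' per-protein missing-value rate, with the median CVs summarised.
#'
#' @param x An [abundance_matrix()] containing pooled and/or replicate
#'   columns.
#' @return A list of class `qc_report`: `pooled_cv` (tibble), `replicate_cv`
#'   (tibble with a `pair` column), `na_rate` (tibble), `median_pooled_cv`,
#'   `median_replicate_cv` (named by pair).
#' @export
qc_report <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  pooled <- x$samples$sample_id[x$samples$group == "POOL"]
  pooled_cv <- if (length(pooled) >= 2) compute_cv(x, pooled) else NULL
  reps <- x$samples[!is.na(x$samples$replicate_of), ]
  replicate_cv <- NULL
  if (nrow(reps) > 0) {
    replicate_cv <- dplyr::bind_rows(lapply(seq_len(nrow(reps)), function(i) {
      pair <- c(reps$replicate_of[i], reps$sample_id[i])
      out <- compute_cv(x, pair)
      out$pair <- reps$replicate_of[i]
      out
    }))
  }
  na_rate <- tibble::tibble(
    protein_id = rownames(x$values),
    na_rate = rowMeans(is.na(x$values))
  )
  structure(list(
    pooled_cv = pooled_cv,
    replicate_cv = replicate_cv,
    na_rate = na_rate,
    median_pooled_cv = if (!is.null(pooled_cv)) median(pooled_cv$cv, na.rm = TRUE) else NA_real_,
    median_replicate_cv = if (!is.null(replicate_cv)) {
      tapply(replicate_cv$cv, replicate_cv$pair, median, na.rm = TRUE)
    } else NULL
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  median pooled CV: %.4f\n", x$median_pooled_cv))
  if (!is.null(x$median_replicate_cv)) {
    cat("  median replicate CVs:",
        paste(sprintf("%.4f", x$median_replicate_cv), collapse = ", "), "\n")
  }
  cat(sprintf("  proteins with any NA: %d / %d\n",
              sum(x$na_rate$na_rate > 0), nrow(x$na_rate)))
  invisible(x)
}

#' Remove proteins with a high missing-value rate
#'
#' Retains exactly the proteins whose NA rate is less than or equal to
#' `max_na_rate`; a rate strictly above the threshold removes the protein
#' (the boundary protein at exactly the threshold is kept). Row order is
#' preserved.
#'
#' @param x An [abundance_matrix()].
#' @param max_na_rate Fraction in [0, 1]; default 0.85.
#' @return The filtered [abundance_matrix()].
#' @export
filter_by_missingness <- function(x, max_na_rate = 0.85) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (max_na_rate < 0 || max_na_rate > 1) stop_input("max_na_rate must be in [0, 1]")
  rate <- rowMeans(is.na(x$values))
  keep <- rate <= max_na_rate
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  attr(out, "stages") <- attr(x, "stages")
  mark_stage(out, "filter")
}

#' Robust sequential imputation of missing abundances
#'
#' Fills missing entries by sequential regression in the spirit of robust
#' sequential imputation for omics matrices: proteins are processed in order
#' of increasing missingness, and each incomplete protein is regressed
#' (trimmed least squares) on the `k` most-correlated proteins among those
#' already complete, using the samples where the protein is observed; its
#' missing entries are then predicted. Observed entries are never changed and
#' the procedure is fully deterministic given the matrix.
#'
#' The trimmed fit iteratively refits ordinary least squares on the
#' `trim` fraction of observations with the smallest residuals until the
#' retained set stabilises, giving resistance to outlying abundances without
#' any random subsampling.
#'
#' @param x An [abundance_matrix()] (log2 scale) or plain numeric matrix.
#' @param k Number of correlated predictor proteins (default 10).
#' @param trim Coverage fraction of the trimmed fit (default 0.75).
#' @param max_iter Maximum trimming iterations per protein.
#' @return A complete object of the same type as `x`.
#' @export
impute_sequential <- function(x, k = 10, trim = 0.75, max_iter = 20) {
  is_am <- inherits(x, "abundance_matrix")
  values <- if (is_am) as_log2(x)$values else as.matrix(x)
  all_missing <- rowSums(!is.na(values)) == 0
  if (any(all_missing)) {
    stop_data("protein(s) with no observed values: %s",
              paste(rownames(values)[all_missing] %||% which(all_missing), collapse = ", "))
  }
  filled <- impute_sequential_impl(values, k = k, trim = trim, max_iter = max_iter)
  if (is_am) {
    out <- as_log2(x)
    out$values <- filled
    attr(out, "stages") <- attr(x, "stages")
    mark_stage(out, "impute")
  } else {
    filled
  }
}

impute_sequential_impl <- function(values, k, trim, max_iter) {
  na_count <- rowSums(is.na(values))
  if (all(na_count == 0)) return(values)
  filled <- values
  med <- apply(values, 1, median, na.rm = TRUE)
  completed <- which(na_count == 0)
  order_idx <- order(na_count)
  order_idx <- order_idx[na_count[order_idx] > 0]
  # donor matrix kept samples x proteins so correlations against the
  # completed set are single crossprod calls, not repeated transposes
  donorT <- t(filled)
  for (i in order_idx) {
    obs <- which(!is.na(values[i, ]))
    mis <- which(is.na(values[i, ]))
    yhat <- rep(med[i], length(mis))
    if (length(completed) > 0 && length(obs) >= 4) {
      y <- values[i, obs]
      yc <- y - mean(y)
      Y <- donorT[obs, completed, drop = FALSE]
      m <- length(obs)
      cm <- colMeans(Y)
      num <- as.vector(crossprod(Y, yc))
      den <- sqrt(pmax(colSums(Y^2) - m * cm^2, 0)) * sqrt(sum(yc^2))
      cors <- ifelse(den > 0, num / den, 0)
      cors[!is.finite(cors)] <- 0
      k_eff <- min(k, length(obs) - 2, sum(abs(cors) > 0))
      if (k_eff >= 1) {
        pred <- completed[order(abs(cors), decreasing = TRUE)[seq_len(k_eff)]]
        Xo <- donorT[obs, pred, drop = FALSE]
        Xm <- donorT[mis, pred, drop = FALSE]
        fit <- trimmed_lm(Xo, y, trim = trim, max_iter = max_iter)
        if (!is.null(fit)) yhat <- drop(cbind(1, Xm) %*% fit)
      }
    }
    filled[i, mis] <- yhat
    donorT[mis, i] <- yhat
    completed <- c(completed, i)
  }
  filled
}

# deterministic trimmed least squares: iterate OLS on the h smallest
# absolute residuals until membership stabilises
trimmed_lm <- function(X, y, trim, max_iter) {
  n <- length(y)
  h <- max(ceiling(trim * n), ncol(X) + 2)
  if (h > n) h <- n
  keep <- seq_len(n)
  coefs <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- tryCatch(lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep]),
                    error = function(e) NULL)
    if (is.null(fit)) return(coefs)
    coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    res <- abs(y - drop(cbind(1, X) %*% coefs))
    new_keep <- order(res)[seq_len(h)]
    if (setequal(new_keep, keep)) break
    keep <- sort(new_keep)
  }
  coefs
}

#' Replace non-positive abundances by half the protein minimum
#'
#' On the linear scale, every value less than or equal to zero is replaced by
#' half the minimum positive abundance of the same protein. Idempotent.
#'
#' @param x An [abundance_matrix()] on linear scale, or a numeric matrix.
#' @return Object of the same type with no non-positive values.
#' @export
replace_nonpositive <- function(x) {
  is_am <- inherits(x, "abundance_matrix")
  if (is_am && x$scale != "linear") {
    stop_input("replace_nonpositive is defined on the linear scale; call as_linear() first")
  }
  values <- if (is_am) x$values else as.matrix(x)
  min_pos <- apply(values, 1, function(v) {
    pos <- v[!is.na(v) & v > 0]
    if (length(pos) == 0) NA_real_ else min(pos)
  })
  bad <- rowSums(!is.na(values) & values > 0) == 0 & rowSums(!is.na(values)) > 0
  if (any(bad)) {
    stop_data("protein(s) with no positive abundance: %s",
              paste(rownames(values)[bad] %||% which(bad), collapse = ", "))
  }
  nonpos <- !is.na(values) & values <= 0
  values[nonpos] <- (min_pos / 2)[row(values)[nonpos]]
  if (is_am) {
    out <- x
    out$values <- values
    attr(out, "stages") <- attr(x, "stages")
    if (!"replace_nonpositive" %in% attr(out, "stages")) {
      out <- mark_stage(out, "replace_nonpositive")
    }
    out
  } else {
    values
  }
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Parametric empirical-Bayes location/scale batch adjustment of a complete
#' log2 matrix, delegated to `sva::ComBat`: per-protein standardisation on a
#' design optionally protecting covariates, per-batch means/variances shrunk
#' toward method-of-moments priors, then rescaling. A single batch returns
#' the input unchanged (no adjustment is possible).
#'
#' @param x An [abundance_matrix()] (log2, complete) or numeric matrix.
#' @param batch Batch labels; defaults to the sample metadata for an
#'   [abundance_matrix()].
#' @param parametric Use the parametric prior (default `TRUE`).
#' @param covariates Optional model matrix (or data frame of factors) of
#'   biological covariates to protect.
#' @return Object of the same type, batch-adjusted.
#' @export
correct_batch <- function(x, batch = NULL, parametric = TRUE, covariates = NULL) {
  is_am <- inherits(x, "abundance_matrix")
  values <- if (is_am) as_log2(x)$values else as.matrix(x)
  if (is.null(batch)) {
    if (!is_am) stop_input("batch labels required for a plain matrix")
    batch <- x$samples$batch
  }
  if (anyNA(values)) stop_input("correct_batch requires a complete matrix (impute first)")
  batch <- as.factor(batch)
  if (length(batch) != ncol(values)) stop_input("batch labels must match the number of samples")
  if (nlevels(droplevels(batch)) < 2) {
    out_values <- values
  } else {
    if (any(table(batch) < 2)) {
      stop_data("each batch needs at least 2 samples (smallest has %d)", min(table(batch)))
    }
    mod <- NULL
    if (!is.null(covariates)) {
      mod <- stats::model.matrix(~., data = as.data.frame(covariates))
      if (qr(mod)$rank < ncol(mod)) stop_input("singular covariate design")
    }
    invisible(utils::capture.output(
      out_values <- suppressMessages(
        sva::ComBat(dat = values, batch = batch, mod = mod,
                    par.prior = parametric, prior.plots = FALSE,
                    BPPARAM = BiocParallel::SerialParam()))
    ))
  }
  if (is_am) {
    out <- as_log2(x)
    out$values <- out_values
    attr(out, "stages") <- attr(x, "stages")
    mark_stage(out, "correct_batch")
  } else {
    out_values
  }
}

#' Merge technical replicate pairs and drop pooled channels
#'
#' Each pair of technical replicates is collapsed to a single sample by the
#' element-wise mean on the current scale (the study merges mean protein
#' abundances after conversion to the linear scale); pooled reference
#' channels are removed from the analysis matrix. Idempotent.
#'
#' @param x An [abundance_matrix()].
#' @return The merged [abundance_matrix()] containing only biological samples.
#' @export
merge_replicates <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  samples <- x$samples
  values <- x$values
  reps <- samples[!is.na(samples$replicate_of), ]
  for (i in seq_len(nrow(reps))) {
    src <- reps$replicate_of[i]
    dup <- reps$sample_id[i]
    if (!src %in% colnames(values)) {
      stop_data("dangling replicate link: %s -> %s", dup, src)
    }
    values[, src] <- rowMeans(values[, c(src, dup), drop = FALSE], na.rm = FALSE)
  }
  keep <- is.na(samples$replicate_of) & samples$group != "POOL"
  out <- x
  out$values <- values[, samples$sample_id[keep], drop = FALSE]
  out$samples <- samples[keep, ]
  attr(out, "stages") <- attr(x, "stages")
  if (!"merge_replicates" %in% attr(out, "stages")) {
    out <- mark_stage(out, "merge_replicates")
  }
  out
}

#' Run the full preprocessing chain in the prescribed order
#'
#' Executes missingness filtering, sequential imputation, ComBat batch
#' correction (all on log2), conversion to linear scale with half-minimum
#' replacement of non-positive values, and replicate merging — in exactly
#' that order. Out-of-order invocation through this runner is rejected.
#'
#' @param x An [abundance_matrix()] or a `protrisk_cohort`.
#' @param na_threshold Missingness filter threshold (default 0.85).
#' @param impute_k,impute_trim Sequential-imputation controls.
#' @param combat_parametric Parametric ComBat prior (default `TRUE`).
#' @param covariates Optional covariates protected during batch correction.
#' @return A list of class `preprocessed`: `abundance` (linear scale, merged),
#'   `qc` ([qc_report()] of the input), `log` (per-stage dimensions).
#' @export
preprocess_cohort <- function(x, na_threshold = 0.85, impute_k = 10,
                              impute_trim = 0.75, combat_parametric = TRUE,
                              covariates = NULL) {
  if (inherits(x, "protrisk_cohort")) x <- x$abundance
  stopifnot(inherits(x, "abundance_matrix"))
  if (length(attr(x, "stages")) > 0) {
    stop_input("preprocess_cohort expects an unprocessed matrix; stages already applied: %s",
               paste(attr(x, "stages"), collapse = ", "))
  }
  qc <- qc_report(x)
  log <- list(input = dim(x$values))
  x <- filter_by_missingness(x, na_threshold)
  log$filter <- dim(x$values)
  x <- impute_sequential(x, k = impute_k, trim = impute_trim)
  log$impute <- dim(x$values)
  x <- correct_batch(x, parametric = combat_parametric, covariates = covariates)
  log$correct_batch <- dim(x$values)
  x <- replace_nonpositive(as_linear(x))
  x <- merge_replicates(x)
  log$merged <- dim(x$values)
  structure(list(abundance = x, qc = qc, log = log), class = "preprocessed")
}

#' @export
print.preprocessed <- function(x, ...) {
  cat("<preprocessed>\n")
  print(x$abundance)
  cat(sprintf("  median pooled CV (pre-filter): %.4f\n", x$qc$median_pooled_cv))
  invisible(x)
}
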