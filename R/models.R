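#' Specification of the five prognostic models
#'
#' The model family compared in the study: Cox or random survival forest
#' learners over clinical features, protein features (differential proteins
#' at FC > 1.2), or both. Clinical models use no feature selection; the
#' protein Cox model selects by LASSO; the protein-bearing forests use
#' permutation-importance stability selection.
#'
#' @param name One of `"CliCox"`, `"CliRsf"`, `"ProtCox"`, `"ProtRsf"`,
#'   `"CliProtRsf"`.
#' @param hyper_grid Data frame grid for forest tuning, as produced by
#'   [default_rsf_grid()].
#' @param n_repeats,top_k,min_count Stability-selection rule (default
#'   100 repeats, top 50 per repeat, keep features selected at least 50
#'   times).
#' @param stability_num_trees Forest size used inside the stability repeats.
#'   Deliberately small (default 25): the repeat-to-repeat ranking noise of a
#'   small forest is what lets the count threshold filter out features that
#'   are only spuriously associated with outcome, playing the role that data
#'   subsampling plays in classical stability selection. Large per-repeat
#'   forests rank the same spurious features consistently and inflate the
#'   panel.
#' @param seed Integer seed.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name = c("CliCox", "CliRsf", "ProtCox", "ProtRsf", "CliProtRsf"),
                       hyper_grid = default_rsf_grid(),
                       n_repeats = 100, top_k = 50, min_count = 50,
                       stability_num_trees = 25,
                       seed = 1L) {
  name <- match.arg(name)
  if (min_count > n_repeats) {
    stop_input("min_count (%d) cannot exceed n_repeats (%d)", min_count, n_repeats)
  }
  learner <- if (name %in% c("CliCox", "ProtCox")) "coxph" else "rsf"
  selector <- switch(name,
    CliCox = "none", CliRsf = "none",
    ProtCox = "lasso",
    ProtRsf = "stability", CliProtRsf = "stability"
  )
  pool <- switch(name,
    CliCox = "clinical", CliRsf = "clinical",
    ProtCox = "protein", ProtRsf = "protein",
    CliProtRsf = "both"
  )
  structure(list(name = name, learner = learner, selector = selector,
                 feature_pool = pool, hyper_grid = hyper_grid,
                 n_repeats = n_repeats, top_k = top_k, min_count = min_count,
                 stability_num_trees = stability_num_trees,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Default random-survival-forest tuning grid
#'
#' `num_trees` in {250, 500, 1000}, `mtry` at sqrt(p) or p/3, minimum node
#' size in {3, 6, 15}. `mtry_frac` is resolved against the feature count at
#' fit time.
#'
#' @param num_trees,mtry_frac,min_node_size Grid axes.
#' @return A data frame grid.
#' @export
default_rsf_grid <- function(num_trees = c(250, 500, 1000),
                             mtry_frac = c("sqrt", "third"),
                             min_node_size = c(3, 6, 15)) {
  expand.grid(num_trees = num_trees, mtry_frac = mtry_frac,
              min_node_size = min_node_size, stringsAsFactors = FALSE)
}

resolve_mtry <- function(mtry_frac, p) {
  m <- switch(as.character(mtry_frac),
              sqrt = floor(sqrt(p)),
              third = floor(p / 3),
              as.integer(mtry_frac))
  max(1L, min(as.integer(m), p))
}

#' Random train/test partition of a patient table
#'
#' Random partition at the requested ratio, optionally stratified by the
#' event indicator so both partitions keep the cohort's event fraction
#' (within one patient). Deterministic for a given seed.
#'
#' @param data Data frame with `patient_id` and `event`.
#' @param ratio Training fraction in (0, 1); `n_train = round(ratio * n)`.
#' @param n_train Optional explicit training-set size, overriding `ratio`
#'   (the study uses 50 of 85).
#' @param seed Integer seed.
#' @param stratify Stratify by event (default `TRUE`); requires at least two
#'   events.
#' @return A `split_definition`: `train_ids`, `test_ids`, `seed`,
#'   `stratified`.
#' @export
split_train_test <- function(data, ratio = 0.6, n_train = NULL, seed = 1L,
                             stratify = TRUE) {
  if (is.null(n_train)) {
    if (ratio <= 0 || ratio >= 1) stop_input("ratio must be in (0, 1)")
    n_train <- round(ratio * nrow(data))
  }
  if (n_train < 1 || n_train >= nrow(data)) stop_input("n_train out of range")
  ids <- data$patient_id
  if (stratify) {
    if (sum(data$event) < 2) stop_input("stratified split needs at least 2 events")
    ev_ids <- ids[data$event == 1]
    no_ids <- ids[data$event == 0]
    n_ev_train <- round(n_train * length(ev_ids) / length(ids))
    n_ev_train <- min(max(n_ev_train, 1), length(ev_ids) - 1)
    train_ids <- withr::with_seed(seed, c(
      sample(ev_ids, n_ev_train),
      sample(no_ids, n_train - n_ev_train)
    ))
  } else {
    train_ids <- withr::with_seed(seed, sample(ids, n_train))
  }
  train_ids <- ids[ids %in% train_ids]  # restore table order
  structure(list(train_ids = train_ids,
                 test_ids = setdiff(ids, train_ids),
                 seed = as.integer(seed), stratified = stratify),
            class = "split_definition")
}

#' @export
print.split_definition <- function(x, ...) {
  cat(sprintf("<split_definition> train n = %d, test n = %d (seed %d%s)\n",
              length(x$train_ids), length(x$test_ids), x$seed,
              if (x$stratified) ", event-stratified" else ""))
  invisible(x)
}

# k folds containing at least one event each; refolds with a warning up to
# max_attempts times before giving up
make_event_folds <- function(event, k, seed, max_attempts = 10) {
  n <- length(event)
  if (k < 2) stop_input("k_folds must be >= 2")
  for (attempt in seq_len(max_attempts)) {
    folds <- withr::with_seed(derive_seed(seed, attempt - 1),
                              sample(rep_len(seq_len(k), n)))
    ok <- all(tapply(event, folds, sum) > 0)
    if (ok) {
      if (attempt > 1) warn_protrisk("refolded %d time(s) to place events in every fold", attempt - 1)
      return(folds)
    }
  }
  stop_data("could not build %d folds each containing an event", k)
}

# survival forest wrapper: data must contain time, event and the features
fit_rsf <- function(data, features, num_trees = 500, mtry = NULL,
                    min_node_size = 3, seed = 1L) {
  df <- as.data.frame(data[, c("time", "event", features)])
  df[features] <- lapply(df[features], function(v) if (is.character(v)) factor(v) else v)
  if (is.null(mtry)) mtry <- resolve_mtry("sqrt", length(features))
  ranger::ranger(
    survival::Surv(time, event) ~ ., data = df,
    num.trees = num_trees, mtry = min(mtry, length(features)),
    min.node.size = min_node_size, splitrule = "logrank",
    importance = "permutation", respect.unordered.factors = "order",
    seed = seed, num.threads = 1
  )
}

#' Risk score of a fitted prognostic model
#'
#' For a Cox learner the linear predictor; for a survival forest the total
#' ensemble cumulative hazard (the sum of the Nelson-Aalen CHF over the
#' training event-time grid). Higher = higher recurrence risk.
#'
#' @param model A `risk_model`.
#' @param data Data frame with the model's feature columns.
#' @return Numeric vector of risk scores.
#' @export
risk_score <- function(model, data) {
  UseMethod("risk_score")
}

#' @export
risk_score.risk_model <- function(model, data) {
  missing <- setdiff(model$features, names(data))
  if (length(missing)) stop_input("features absent from data: %s",
                                  paste(missing, collapse = ", "))
  if (model$learner == "coxph") {
    nd <- as.data.frame(data[, model$features, drop = FALSE])
    unname(predict(model$fit, newdata = nd, type = "lp"))
  } else {
    df <- as.data.frame(data[, model$features, drop = FALSE])
    df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
    pr <- predict(model$fit, data = df, num.threads = 1)
    unname(rowSums(pr$chf))
  }
}

#' Harrell's C-index of a model on a dataset
#'
#' Concordance of the model risk score against the right-censored outcome.
#' A risk score constant across all patients gives 0.5 (every comparable
#' pair tied); if no comparable pair exists the result is `NA` with a
#' warning.
#'
#' @param model A `risk_model`, or a numeric risk-score vector.
#' @param data Data frame with `time`, `event` and feature columns.
#' @return C-index in [0, 1], or `NA` if undefined.
#' @export
evaluate_cindex <- function(model, data) {
  score <- if (is.numeric(model)) model else risk_score(model, data)
  cindex_from_scores(score, data$time, data$event)
}

cindex_from_scores <- function(score, time, event) {
  if (sum(event) == 0) {
    warn_protrisk("no events: C-index undefined")
    return(NA_real_)
  }
  cc <- survival::concordance(survival::Surv(time, event) ~ score, reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) {
    warn_protrisk("no comparable pairs: C-index undefined")
    return(NA_real_)
  }
  unname(cc$concordance)
}

#' Grid-search hyperparameter tuning by k-fold cross-validated C-index
#'
#' Exhaustively evaluates a forest tuning grid by the mean held-out Harrell
#' C-index over `k_folds` seeded folds (each fold is guaranteed an event,
#' refolding if necessary). Ties are broken toward the simpler model: fewer
#' trees, then larger minimum node size, then grid order.
#'
#' @param data Training data (`time`, `event`, features).
#' @param features Feature column names.
#' @param grid Data frame from [default_rsf_grid()].
#' @param k_folds Number of folds (default 3).
#' @param seed Integer seed controlling folds and forest fits.
#' @return A list: `best` (one-row data frame with resolved `mtry`),
#'   `cv_cindex` (best mean C), `results` (grid with per-setting mean C).
#' @export
tune_hyperparameters <- function(data, features, grid = default_rsf_grid(),
                                 k_folds = 3, seed = 1L) {
  if (nrow(grid) == 0) stop_input("empty tuning grid")
  folds <- make_event_folds(data$event, k_folds, seed)
  p <- length(features)
  mean_c <- vapply(seq_len(nrow(grid)), function(g) {
    cs <- vapply(seq_len(k_folds), function(f) {
      tr <- data[folds != f, , drop = FALSE]
      te <- data[folds == f, , drop = FALSE]
      fit <- fit_rsf(tr, features,
                     num_trees = grid$num_trees[g],
                     mtry = resolve_mtry(grid$mtry_frac[g], p),
                     min_node_size = grid$min_node_size[g],
                     seed = derive_seed(seed, g * 100 + f))
      m <- list(learner = "rsf", fit = fit, features = features)
      class(m) <- "risk_model"
      evaluate_cindex(m, te)
    }, numeric(1))
    mean(cs, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-mean_c, grid$num_trees, -grid$min_node_size, seq_len(nrow(grid)))
  best_idx <- ord[1]
  best <- grid[best_idx, , drop = FALSE]
  best$mtry <- resolve_mtry(best$mtry_frac, p)
  results <- grid
  results$cv_cindex <- mean_c
  list(best = best, cv_cindex = mean_c[best_idx], results = tibble::as_tibble(results))
}

#' Permutation importance by C-index drop
#'
#' Model-agnostic permutation importance: the drop in Harrell C-index when a
#' feature's column is permuted, averaged over `n_perm` seeded permutations.
#' This is the explicit (in-sample or holdout) variant; the stability
#' selector defaults to the forest's out-of-bag permutation importance,
#' which is the same quantity computed on out-of-bag predictions.
#'
#' @param model A `risk_model`.
#' @param data Data frame with `time`, `event` and the model features.
#' @param n_perm Permutations per feature (default 5).
#' @param seed Integer seed.
#' @return A tibble: `feature`, `importance`, sorted decreasing.
#' @export
permutation_importance <- function(model, data, n_perm = 5, seed = 1L) {
  missing <- setdiff(model$features, names(data))
  if (length(missing)) stop_input("features absent from data: %s",
                                  paste(missing, collapse = ", "))
  c0 <- evaluate_cindex(model, data)
  imp <- vapply(seq_along(model$features), function(j) {
    f <- model$features[j]
    cs <- vapply(seq_len(n_perm), function(r) {
      perm <- withr::with_seed(derive_seed(seed, j * 1000 + r),
                               sample(nrow(data)))
      d2 <- data
      d2[[f]] <- d2[[f]][perm]
      evaluate_cindex(model, d2)
    }, numeric(1))
    c0 - mean(cs)
  }, numeric(1))
  out <- tibble::tibble(feature = model$features, importance = imp)
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Stability selection by repeated permutation importance
#'
#' The feature-selection rule of the protein forest models: the forest is
#' trained `n_repeats` times with different initial states (RNG seeds for
#' bootstrap and mtry draws), each repeat ranks the feature pool by
#' permutation importance and records its `top_k` features (ties at the
#' boundary are all included), and the final panel keeps the features
#' recorded at least `min_count` times.
#'
#' @param data Training data (`time`, `event`, features).
#' @param feature_pool Candidate feature names (>= `top_k`).
#' @param n_repeats,top_k,min_count The selection rule (defaults
#'   100 / 50 / 50).
#' @param num_trees,mtry,min_node_size Forest settings for the repeats.
#' @param seed Master seed; repeat r uses a seed derived from it.
#' @param importance `"oob"` (forest out-of-bag permutation importance,
#'   default) or `"holdout"` (explicit [permutation_importance()] on the
#'   training data).
#' @return A `stability_result`: `counts` (tibble `feature`, `count`),
#'   `panel` (character), plus the rule parameters.
#' @export
stability_select <- function(data, feature_pool, n_repeats = 100, top_k = 50,
                             min_count = 50, num_trees = 25, mtry = NULL,
                             min_node_size = 3, seed = 1L,
                             importance = c("oob", "holdout")) {
  importance <- match.arg(importance)
  if (length(feature_pool) < top_k) {
    stop_input("feature pool (%d) smaller than top_k (%d)", length(feature_pool), top_k)
  }
  no_selection_pressure <- length(feature_pool) == top_k
  if (sum(data$event) == 0) stop_data("stability selection needs events in the training data")
  counts <- setNames(integer(length(feature_pool)), feature_pool)
  for (r in seq_len(n_repeats)) {
    rs <- derive_seed(seed, r)
    fit <- fit_rsf(data, feature_pool, num_trees = num_trees, mtry = mtry,
                   min_node_size = min_node_size, seed = rs)
    imp <- if (importance == "oob") {
      fit$variable.importance
    } else {
      m <- structure(list(learner = "rsf", fit = fit, features = feature_pool),
                     class = "risk_model")
      pi <- permutation_importance(m, data, seed = rs)
      setNames(pi$importance, pi$feature)
    }
    # a feature whose importance is unmeasurable (no usable out-of-bag
    # events) is not demonstrably important
    imp[!is.finite(imp)] <- 0
    imp <- sort(imp, decreasing = TRUE)
    cutoff <- imp[top_k]
    # boundary ties are all included, but under selection pressure only
    # demonstrably important features count: non-positive importance never
    # marks a selection. A pool of exactly top_k features is trivially its
    # own "top_k most important" set.
    top <- if (no_selection_pressure) {
      names(imp)
    } else {
      names(imp)[imp >= cutoff & imp > 0]
    }
    counts[top] <- counts[top] + 1L
  }
  panel <- names(counts)[counts >= min_count]
  if (length(panel) == 0) warn_protrisk("stability selection produced an empty panel")
  structure(list(
    counts = tibble::tibble(feature = names(counts), count = unname(counts)),
    panel = panel, n_repeats = n_repeats, top_k = top_k, min_count = min_count
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d repeats, top %d, keep >= %d: panel of %d features\n",
              x$n_repeats, x$top_k, x$min_count, length(x$panel)))
  if (length(x$panel)) cat(" ", paste(head(x$panel, 20), collapse = ", "),
                           if (length(x$panel) > 20) "..." else "", "\n")
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) {
  dplyr::arrange(x$counts, dplyr::desc(.data$count))
}

#' Selection-count plot for stability selection
#'
#' @param object A `stability_result`.
#' @param n_top Number of features displayed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_result <- function(object, n_top = 30, ...) {
  df <- head(tidy(object), n_top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$count, .data$feature)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::geom_vline(xintercept = object$min_count, linetype = 2, colour = "#c0392b") +
    ggplot2::labs(x = sprintf("times selected (of %d)", object$n_repeats), y = NULL) +
    ggplot2::theme_minimal()
}

#' LASSO-penalized Cox feature selection
#'
#' L1-penalized Cox path over standardized features with the penalty chosen
#' by k-fold cross-validated partial-likelihood deviance (lambda at the
#' minimum); the features with nonzero coefficients are refit in an
#' unpenalized Cox model.
#'
#' @param data Training data (`time`, `event`, features).
#' @param features Candidate feature names (numeric columns).
#' @param k_folds CV folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param lambda Optional fixed penalty, bypassing cross-validation.
#' @return A list: `selected` (character), `fit` (unpenalized `cox_result`
#'   on the selection, `NULL` if empty), `lambda`, `glmnet_fit`.
#' @export
lasso_cox_select <- function(data, features, k_folds = 5, seed = 1L,
                             lambda = NULL) {
  if (sum(data$event) == 0) stop_data("LASSO-Cox needs events")
  xm <- as.matrix(data[, features, drop = FALSE])
  if (!is.numeric(xm)) stop_input("LASSO features must be numeric")
  y <- survival::Surv(data$time, data$event)
  if (is.null(lambda)) {
    foldid <- make_event_folds(data$event, k_folds, seed)
    cvfit <- withr::with_seed(seed,
      glmnet::cv.glmnet(xm, y, family = "cox", foldid = foldid,
                        type.measure = "deviance", standardize = TRUE))
    lambda <- cvfit$lambda.min
    gfit <- cvfit$glmnet.fit
  } else {
    gfit <- glmnet::glmnet(xm, y, family = "cox", lambda = lambda,
                           standardize = TRUE)
  }
  cf <- as.matrix(coef(gfit, s = lambda))
  selected <- rownames(cf)[cf[, 1] != 0]
  refit <- NULL
  if (length(selected) == 0) {
    warn_protrisk("all LASSO coefficients are zero at the chosen penalty")
  } else {
    refit <- fit_cox(data, selected)
  }
  list(selected = selected, fit = refit, lambda = lambda, glmnet_fit = gfit)
}

#' Train one of the five prognostic models
#'
#' Orchestrates the per-model recipe on the training partition only:
#' hyperparameter tuning by 3-fold cross-validated C-index (forest models),
#' feature selection (none / LASSO / stability), final fit, and evaluation
#' on the training, cross-validation and held-out test sets. Test outcomes
#' are touched only in the final evaluation step.
#'
#' @param spec A [model_spec()].
#' @param data Patient table with `patient_id`, `time`, `event`, the 11
#'   clinical covariates if the model uses them, and protein feature columns.
#' @param split A [split_train_test()] result.
#' @param protein_pool Protein feature names forming the candidate pool
#'   (differential proteins at FC > 1.2 in the study design).
#' @param k_folds Cross-validation folds (default 3).
#' @return A `risk_model`: `spec`, `learner`, `fit`, `features`, `tuned`,
#'   `split`, `selection`, and a `metrics` tibble (train / cv / test
#'   C-index).
#' @export
train_model <- function(spec, data, split, protein_pool = character(),
                        k_folds = 3) {
  stopifnot(inherits(spec, "model_spec"), inherits(split, "split_definition"))
  train <- data[data$patient_id %in% split$train_ids, , drop = FALSE]
  pool <- switch(spec$feature_pool,
    clinical = clinical_covariates(),
    protein = protein_pool,
    both = c(clinical_covariates(), protein_pool)
  )
  if (length(pool) == 0) stop_input("empty feature pool for %s", spec$name)
  tuned <- NULL
  cv_c <- NA_real_
  if (spec$learner == "rsf") {
    tuning <- tune_hyperparameters(train, pool, grid = spec$hyper_grid,
                                   k_folds = k_folds, seed = spec$seed)
    tuned <- tuning$best
    cv_c <- tuning$cv_cindex
  }
  selection <- NULL
  features <- pool
  if (spec$selector == "lasso") {
    selection <- lasso_cox_select(train, pool, seed = spec$seed)
    features <- selection$selected
    if (length(features) == 0) stop_data("LASSO selected no features for %s", spec$name)
  } else if (spec$selector == "stability") {
    selection <- stability_select(
      train, pool,
      n_repeats = spec$n_repeats, top_k = spec$top_k, min_count = spec$min_count,
      num_trees = spec$stability_num_trees,
      mtry = if (!is.null(tuned)) min(tuned$mtry, length(pool)) else NULL,
      min_node_size = if (!is.null(tuned)) tuned$min_node_size else 3,
      seed = spec$seed
    )
    features <- selection$panel
    if (length(features) == 0) {
      # an empty panel (too few events for any feature to clear min_count)
      # falls back to the most frequently selected features, so the model
      # can still be fit and evaluated; the warning flags the weak panel
      cnt <- dplyr::arrange(selection$counts, dplyr::desc(.data$count))
      cnt <- cnt[cnt$count > 0, ]
      if (nrow(cnt) == 0) stop_data("stability selection found no informative features for %s", spec$name)
      features <- head(cnt$feature, spec$top_k)
      warn_protrisk("empty stability panel for %s; falling back to the %d most frequently selected features",
                    spec$name, length(features))
    }
  }
  fit <- if (spec$learner == "coxph") {
    fit_cox(train, features)$fit
  } else {
    fit_rsf(train, features,
            num_trees = tuned$num_trees,
            mtry = min(tuned$mtry, length(features)),
            min_node_size = tuned$min_node_size,
            seed = spec$seed)
  }
  model <- structure(list(spec = spec, learner = spec$learner, fit = fit,
                          features = features, tuned = tuned, split = split,
                          selection = selection),
                     class = "risk_model")
  test <- data[data$patient_id %in% split$test_ids, , drop = FALSE]
  model$metrics <- tibble::tibble(
    set = c("train", "cv", "test"),
    cindex = c(evaluate_cindex(model, train), cv_c, evaluate_cindex(model, test))
  )
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%s learner, %d features)\n",
              x$spec$name, x$learner, length(x$features)))
  m <- x$metrics
  cat(sprintf("  C-index: train %.3f / cv %s / test %.3f\n",
              m$cindex[1],
              ifelse(is.na(m$cindex[2]), "-", sprintf("%.3f", m$cindex[2])),
              m$cindex[3]))
  invisible(x)
}

#' @rdname train_model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @export
glance.risk_model <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "set", values_from = "cindex",
                     names_prefix = "cindex_") |>
    dplyr::mutate(model = x$spec$name, n_features = length(x$features),
                  .before = 1)
}

#' Assemble a modelling table from a preprocessed matrix and clinical data
#'
#' Joins the clinical table with log2 protein abundances (samples become
#' rows, proteins become feature columns) for the PM patients.
#'
#' @param abundance A preprocessed [abundance_matrix()] (or `preprocessed`
#'   object) containing the PM samples.
#' @param clinical Clinical tibble with `patient_id`.
#' @param proteins Protein ids to carry as features (default: all).
#' @return A tibble: `patient_id`, clinical columns, one column per protein.
#' @export
assemble_model_data <- function(abundance, clinical, proteins = NULL) {
  if (inherits(abundance, "preprocessed")) abundance <- abundance$abundance
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- as_log2_values(abundance)
  if (is.null(proteins)) proteins <- rownames(v)
  missing <- setdiff(clinical$patient_id, colnames(v))
  if (length(missing)) stop_input("patients absent from the matrix: %s",
                                  paste(head(missing, 5), collapse = ", "))
  pm <- t(v[proteins, clinical$patient_id, drop = FALSE])
  dplyr::bind_cols(clinical, tibble::as_tibble(pm))
}
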