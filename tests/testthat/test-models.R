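# survival data where a co-regulated block of proteins drives the hazard,
# mirroring the generator's risk-program design at unit-test scale
module_signal_data <- function(n, p_noise, n_signal = 5, seed = 1) {
  withr::with_seed(seed, {
    v <- rnorm(n)
    sig <- vapply(seq_len(n_signal), function(j) 1.3 * v + rnorm(n, 0, 0.5),
                  numeric(n))
    colnames(sig) <- sprintf("SIG%02d", seq_len(n_signal))
    noise <- matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, sprintf("N%04d", seq_len(p_noise))))
    cens <- runif(n, 42, 100)
    out <- simulate_survival(1.5 * v, 0.002, cens)
    tibble::tibble(patient_id = sprintf("PT%03d", seq_len(n)),
                   time = out$time, event = out$event) |>
      dplyr::bind_cols(tibble::as_tibble(sig), tibble::as_tibble(noise))
  })
}

test_that("train/test splits have the stated sizes and are deterministic", {
  clin <- reference_clinical_synthetic()
  sp <- split_train_test(clin, n_train = 50, seed = 4)
  expect_length(sp$train_ids, 50)
  expect_length(sp$test_ids, 35)
  expect_setequal(c(sp$train_ids, sp$test_ids), clin$patient_id)
  # proportional event allocation: 12 * 50/85 ~ 7
  n_ev <- sum(clin$event[clin$patient_id %in% sp$train_ids])
  expect_true(abs(n_ev - 7) <= 1)
  expect_identical(split_train_test(clin, n_train = 50, seed = 4)$train_ids,
                   sp$train_ids)
  expect_false(identical(split_train_test(clin, n_train = 50, seed = 5)$train_ids,
                         sp$train_ids))
  expect_error(split_train_test(clin, ratio = 1.2), "ratio")
})

test_that("C-index conventions: constant scores give 0.5, perfect ranking 1", {
  d <- tibble::tibble(time = c(5, 10, 15, 20), event = c(1L, 1L, 1L, 1L))
  expect_equal(evaluate_cindex(rep(1, 4), d), 0.5)
  expect_equal(evaluate_cindex(-d$time, d), 1)
  d0 <- tibble::tibble(time = c(5, 10), event = c(0L, 0L))
  expect_warning(ci <- evaluate_cindex(c(1, 2), d0), "C-index undefined")
  expect_true(is.na(ci))
})

test_that("grid tuning returns the single setting and calibrates on noise vs signal", {
  d_noise <- module_signal_data(120, p_noise = 10, n_signal = 0, seed = 3)
  d_noise$time <- withr::with_seed(4, sample(d_noise$time))  # break any residual link
  g1 <- default_rsf_grid(num_trees = 100, mtry_frac = "sqrt", min_node_size = 6)
  tuned <- tune_hyperparameters(d_noise, grep("^N", names(d_noise), value = TRUE),
                                grid = g1, seed = 5)
  expect_equal(nrow(tuned$results), 1)
  expect_equal(tuned$best$num_trees, 100)
  expect_lt(abs(tuned$cv_cindex - 0.5), 0.07)

  d_sig <- module_signal_data(150, p_noise = 30, n_signal = 5, seed = 6)
  g2 <- default_rsf_grid(num_trees = c(100, 250), mtry_frac = "sqrt",
                         min_node_size = c(3, 6))
  tuned2 <- tune_hyperparameters(d_sig, setdiff(names(d_sig), c("patient_id", "time", "event")),
                                 grid = g2, seed = 7)
  expect_gte(tuned2$cv_cindex, 0.7)
})

test_that("permutation importance separates used, unused and duplicated features", {
  withr::with_seed(11, {
    n <- 400
    a <- rnorm(n)
    b <- rnorm(n)  # carries no signal
    cens <- runif(n, 50, 200)
    out <- simulate_survival(2 * a, 0.005, cens)
    d <- tibble::tibble(time = out$time, event = out$event, a = a, b = b)
  })
  train <- d[1:200, ]
  holdout <- d[201:400, ]  # importance judged away from the fitted trees
  fit <- protrisk:::fit_rsf(train, c("a", "b"), num_trees = 300, mtry = 2,
                            min_node_size = 10, seed = 1)
  m <- structure(list(learner = "rsf", fit = fit, features = c("a", "b")),
                 class = "risk_model")
  imp <- permutation_importance(m, holdout, seed = 2)
  expect_lt(abs(imp$importance[imp$feature == "b"]), 0.02)
  expect_gt(imp$importance[imp$feature == "a"], 0.3)

  # a duplicated copy of the signal shares the credit
  t2 <- train; t2$a2 <- train$a
  h2 <- holdout; h2$a2 <- holdout$a
  fit2 <- protrisk:::fit_rsf(t2, c("a", "a2", "b"), num_trees = 300, mtry = 3,
                             min_node_size = 10, seed = 1)
  m2 <- structure(list(learner = "rsf", fit = fit2, features = c("a", "a2", "b")),
                  class = "risk_model")
  imp2 <- permutation_importance(m2, h2, seed = 2)
  lone <- imp$importance[imp$feature == "a"]
  expect_lt(imp2$importance[imp2$feature == "a"], lone)
  expect_lt(imp2$importance[imp2$feature == "a2"], lone)
  expect_error(permutation_importance(m, holdout[, c("time", "event", "a")]), "absent")
})

test_that("stability selection counts every feature when the pool equals top_k", {
  d <- module_signal_data(80, p_noise = 6, n_signal = 2, seed = 9)
  pool <- setdiff(names(d), c("patient_id", "time", "event"))
  st <- stability_select(d, pool, n_repeats = 5, top_k = length(pool),
                         min_count = 5, num_trees = 50, seed = 1)
  expect_true(all(st$counts$count == 5))
  expect_setequal(st$panel, pool)
})

test_that("stability selection recovers a planted module and stays quiet on noise", {
  d <- module_signal_data(150, p_noise = 120, n_signal = 5, seed = 13)
  pool <- setdiff(names(d), c("patient_id", "time", "event"))
  st <- stability_select(d, pool, n_repeats = 20, top_k = 10, min_count = 10,
                         num_trees = 100, seed = 2)
  expect_gte(sum(sprintf("SIG%02d", 1:5) %in% st$panel), 4)

  # single-tree repeats are too unstable for any noise feature to persist,
  # so the panel comes back empty with a warning
  d0 <- module_signal_data(80, p_noise = 40, n_signal = 0, seed = 14)
  pool0 <- grep("^N", names(d0), value = TRUE)
  expect_warning(
    st0 <- stability_select(d0, pool0, n_repeats = 20, top_k = 5,
                            min_count = 20, num_trees = 1, mtry = 1, seed = 3),
    "empty panel")
  expect_length(st0$panel, 0)
  expect_error(stability_select(d0, pool0[1:5], top_k = 50), "smaller than top_k")
})

test_that("LASSO-Cox selects planted features and shrinks to empty at huge penalty", {
  d <- module_signal_data(150, p_noise = 30, n_signal = 3, seed = 21)
  pool <- setdiff(names(d), c("patient_id", "time", "event"))
  sel <- lasso_cox_select(d, pool, seed = 1)
  expect_gte(sum(grepl("^SIG", sel$selected)), 1)
  expect_lte(length(sel$selected), 15)
  expect_s3_class(sel$fit, "cox_result")

  expect_warning(sel2 <- lasso_cox_select(d, pool, seed = 1, lambda = 1e6),
                 "zero")
  expect_length(sel2$selected, 0)
})

test_that("LASSO-Cox stays sparse on pure-noise pools", {
  sizes <- vapply(1:25, function(s) {
    d <- module_signal_data(150, p_noise = 30, n_signal = 0, seed = 300 + s)
    sel <- suppressWarnings(
      lasso_cox_select(d, grep("^N", names(d), value = TRUE), seed = s))
    length(sel$selected)
  }, numeric(1))
  # lambda.min occasionally over-selects under the null; the typical
  # selection must still be (near-)empty
  expect_lte(median(sizes), 2)
  expect_lte(mean(sizes > 10), 0.2)
})

test_that("training the five model types leaves test outcomes untouched", {
  d <- module_signal_data(120, p_noise = 40, n_signal = 5, seed = 31)
  clin_cov <- clinical_covariates()
  clin <- withr::with_seed(32, protrisk:::simulate_clinical_covariates(nrow(d)))
  d2 <- dplyr::bind_cols(d, clin)
  split <- split_train_test(d2, seed = 1)
  test_before <- d2[d2$patient_id %in% split$test_ids, c("time", "event")]
  pool <- grep("^SIG|^N", names(d2), value = TRUE)
  grid <- default_rsf_grid(num_trees = 100, mtry_frac = "sqrt", min_node_size = 6)

  m_cox <- train_model(model_spec("CliCox"), d2, split)
  expect_equal(m_cox$learner, "coxph")
  expect_setequal(m_cox$features, clin_cov)

  m_prot <- train_model(model_spec("ProtRsf", hyper_grid = grid, n_repeats = 10,
                                   top_k = 10, min_count = 5,
                                   stability_num_trees = 60, seed = 2),
                        d2, split, protein_pool = pool)
  expect_true(all(m_prot$features %in% pool))
  expect_true(all(c("train", "cv", "test") %in% m_prot$metrics$set))
  expect_gt(m_prot$metrics$cindex[m_prot$metrics$set == "train"], 0.6)

  m_lasso <- train_model(model_spec("ProtCox", seed = 3), d2, split,
                         protein_pool = pool)
  expect_equal(m_lasso$learner, "coxph")

  # the test partition was never modified during training
  test_after <- d2[d2$patient_id %in% split$test_ids, c("time", "event")]
  expect_identical(test_before, test_after)

  # protein-driven hazard: the protein forest beats the clinical Cox model
  c_prot <- m_prot$metrics$cindex[m_prot$metrics$set == "test"]
  c_cli <- m_cox$metrics$cindex[m_cox$metrics$set == "test"]
  expect_gt(c_prot, c_cli)
})
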