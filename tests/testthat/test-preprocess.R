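test_that("per-protein CV matches hand computation and handles edge cases", {
  v <- rbind(c(2, 2, 2, 2), c(1, 3, 1, 3), c(NA, NA, NA, NA), c(5, NA, NA, NA))
  x <- make_abundance(v)
  cv <- compute_cv(x, colnames(x$values))
  expect_equal(cv$cv[1], 0)
  expect_equal(cv$cv[2], sd(c(1, 3, 1, 3)) / 2)
  expect_true(is.na(cv$cv[3]))  # all missing
  expect_true(is.na(cv$cv[4]))  # single observation
  # two-point case: sd/mean of {1, 3} = sqrt(2)/2
  cv2 <- compute_cv(make_abundance(matrix(c(1, 3), 1)), c("S001", "S002"))
  expect_equal(cv2$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_error(compute_cv(x, character(0)), "empty")
})

test_that("qc_report summarises pooled and replicate CVs", {
  co <- generate_cohort(small_config(seed = 2))
  qc <- qc_report(co$abundance)
  expect_gt(qc$median_pooled_cv, 0)
  expect_length(qc$median_replicate_cv, 3)
  expect_true(all(qc$na_rate$na_rate >= 0 & qc$na_rate$na_rate <= 1))
})

test_that("missingness filter removes strictly above the threshold", {
  v <- matrix(rnorm(60), 3, 20)
  v[1, 1:18] <- NA  # rate 0.90
  v[2, 1:17] <- NA  # rate 0.85, exactly at the boundary
  v[3, 1:2] <- NA   # rate 0.10
  x <- make_abundance(v)
  kept <- filter_by_missingness(x, 0.85)
  expect_equal(rownames(kept$values), c("P002", "P003"))
  expect_equal(nrow(filter_by_missingness(x, 1)$values), 3)  # identity
})

test_that("sequential imputation is exact on noiseless rank-1 structure", {
  set.seed(1)
  a <- runif(40, 1, 2); b <- runif(30, 5, 10)
  v <- outer(a, b)  # exactly collinear proteins
  dimnames(v) <- list(sprintf("P%03d", 1:40), sprintf("S%03d", 1:30))
  masked <- v
  idx <- withr::with_seed(9, sample(length(v), round(0.05 * length(v))))
  masked[idx] <- NA
  filled <- impute_sequential(masked)
  expect_equal(filled[idx], v[idx], tolerance = 1e-6)
  # complete input is returned unchanged
  expect_identical(impute_sequential(v), v)
})

test_that("sequential imputation beats protein-median imputation under MCAR", {
  cfg <- sim_config(n_pb = 40, n_pm = 40, n_am = 0, n_proteins = 150,
                    n_dep = 10, n_signal = 5, mcar_rate = 0, mnar_slope = 0,
                    n_replicate_pairs = 0, n_batches = 2, seed = 31)
  co <- generate_cohort(cfg)
  v <- co$abundance$values
  miss <- inject_missingness(v, mnar_slope = 0, mcar_rate = 0.1, seed = 77)
  filled <- impute_sequential(miss$matrix)
  med <- apply(miss$matrix, 1, median, na.rm = TRUE)
  idx <- cbind(match(miss$masked_entries$protein_id, rownames(v)),
               match(miss$masked_entries$sample_id, colnames(v)))
  rmse_seq <- sqrt(mean((filled[idx] - v[idx])^2))
  rmse_med <- sqrt(mean((med[idx[, 1]] - v[idx])^2))
  expect_lt(rmse_seq, rmse_med)
})

test_that("imputation refuses an all-missing protein and names it", {
  v <- matrix(rnorm(20), 2, 10)
  v[2, ] <- NA
  expect_error(impute_sequential(make_abundance(v)), "P002")
})

test_that("half-minimum replacement matches hand computation and is idempotent", {
  v <- rbind(c(-1, 4, 8), c(2, 4, 8), c(0, 0.5, 2))
  out <- replace_nonpositive(v)
  expect_equal(out[1, ], c(2, 4, 8))
  expect_equal(out[2, ], c(2, 4, 8))      # all-positive row unchanged
  expect_equal(out[3, ], c(0.25, 0.5, 2))
  expect_identical(replace_nonpositive(out), out)
  bad <- matrix(c(-1, -2, 0, 5), 2)
  expect_error(replace_nonpositive(bad), "no positive")
})

test_that("batch correction removes an additive shift and batch variance", {
  set.seed(4)
  p <- 150; n <- 40
  base <- rnorm(p, 20, 2)
  batch <- rep(1:2, each = n / 2)
  shift <- rnorm(p, 0, 0.6)
  v <- matrix(base, p, n) + outer(shift, as.numeric(batch == 2)) +
    matrix(rnorm(p * n, 0, 1e-5), p, n)
  dimnames(v) <- list(sprintf("P%03d", 1:p), sprintf("S%03d", 1:n))
  corrected <- correct_batch(v, batch = batch)
  bm_diff <- rowMeans(corrected[, batch == 1]) - rowMeans(corrected[, batch == 2])
  expect_lt(max(abs(bm_diff)), 1e-6)
  # the global per-protein mean is preserved by the standardisation
  expect_lt(max(abs(rowMeans(corrected) - rowMeans(v))), 1e-6)

  # batch R^2 collapses on a realistic noisy cohort
  cfg <- sim_config(n_pb = 40, n_pm = 40, n_am = 0, n_proteins = 100,
                    batch_sd = 0.5, n_dep = 10, n_signal = 0, n_factors = 0,
                    mcar_rate = 0, mnar_slope = 0, n_replicate_pairs = 0,
                    n_batches = 4, seed = 6)
  co <- generate_cohort(cfg)
  x <- co$abundance
  r2 <- function(values, batch) {
    mean(vapply(seq_len(nrow(values)), function(i) {
      summary(lm(values[i, ] ~ factor(batch)))$r.squared
    }, numeric(1)))
  }
  before <- r2(x$values, x$samples$batch)
  after <- r2(correct_batch(x)$values, x$samples$batch)
  expect_gt(before, 0.05)
  expect_lt(after, 0.01)
})

test_that("batch correction edge cases behave as specified", {
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(sprintf("P%03d", 1:5), sprintf("S%03d", 1:10)))
  expect_identical(correct_batch(v, batch = rep(1, 10)), v)  # single batch
  expect_error(correct_batch(v, batch = c(rep(1, 9), 2)), "at least 2")
  v[1, 1] <- NA
  expect_error(correct_batch(v, batch = rep(1:2, 5)), "complete")
})

test_that("replicate merging averages pairs and drops pooled channels", {
  v <- cbind(a = c(4, 10), b = c(8, 12), a_rep = c(6, 14), pool = c(1, 1))
  rownames(v) <- c("P001", "P002")
  x <- make_abundance(v, groups = c("PM", "PM", "PM", "POOL"),
                      replicate_of = c(NA, NA, "a", NA))
  merged <- merge_replicates(x)
  expect_equal(colnames(merged$values), c("a", "b"))
  expect_equal(unname(merged$values[, "a"]), c(5, 12))
  expect_identical(merge_replicates(merged)$values, merged$values)  # idempotent
  # no replicates: unchanged
  y <- make_abundance(matrix(1:4, 2))
  expect_equal(merge_replicates(y)$values, y$values)
})

test_that("the preprocessing runner enforces the stage order and preserves ids", {
  co <- generate_cohort(small_config(seed = 8))
  pp <- preprocess_cohort(co$abundance)
  expect_identical(attr(pp$abundance, "stages"),
                   c("filter", "impute", "correct_batch",
                     "replace_nonpositive", "merge_replicates"))
  # protein ids are a subset in original order; sample ids are the biological set
  kept <- rownames(pp$abundance$values)
  expect_identical(kept, intersect(rownames(co$abundance$values), kept))
  expect_setequal(pp$abundance$samples$sample_id,
                  co$abundance$samples$sample_id[is.na(co$abundance$samples$replicate_of) &
                                                 co$abundance$samples$group != "POOL"])
  expect_false(anyNA(pp$abundance$values))
  expect_true(all(pp$abundance$values > 0))
  # feeding an already-processed matrix back is rejected
  expect_error(preprocess_cohort(pp$abundance), "stages already applied")
})
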