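# Small deterministic fixtures shared across the test files.

# minimal abundance matrix built directly from a value matrix
make_abundance <- function(values, groups = NULL, batches = NULL,
                           replicate_of = NULL, scale = "log2") {
  n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%03d", seq_len(n))
  samples <- tibble::tibble(
    sample_id = colnames(values),
    group = groups %||% rep("PM", n),
    batch = batches %||% rep(1L, n),
    replicate_of = replicate_of %||% rep(NA_character_, n)
  )
  abundance_matrix(values, samples, scale = scale)
}

# small cohort configuration used where the full study scale is unnecessary
small_config <- function(...) {
  sim_config(n_pb = 30, n_pm = 40, n_am = 10, n_proteins = 150, n_batches = 4,
             n_replicate_pairs = 3, n_dep = 15, n_signal = 5, ...)
}

# survival data with a single binary covariate of known hazard ratio
binary_cox_data <- function(n, beta, seed, baseline = 0.03,
                            censor = c(20, 80)) {
  x <- withr::with_seed(seed, rbinom(n, 1, 0.5))
  cens <- withr::with_seed(seed + 1, runif(n, censor[1], censor[2]))
  out <- simulate_survival(beta * x, baseline, cens, seed = seed + 2)
  out$x <- x
  out$patient_id <- sprintf("PT%04d", seq_len(n))
  out
}
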