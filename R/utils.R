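# internal helpers shared across modules

# Deterministic derivation of stage seeds from a single master seed, so one
# integer reproduces a whole run. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, offset) {
  master <- as.numeric(master)
  as.integer((master * 48271 + offset * 7919) %% 2147483629 + 1)
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "protrisk_input_error")
}

stop_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "protrisk_data_error")
}

warn_protrisk <- function(msg, ...) {
  rlang::warn(sprintf(msg, ...), class = "protrisk_warning")
}

# Surv object assembled from explicit time/event columns
surv_from <- function(data, time_col = "time", event_col = "event") {
  if (!all(c(time_col, event_col) %in% names(data))) {
    stop_input("data must contain columns '%s' and '%s'", time_col, event_col)
  }
  survival::Surv(data[[time_col]], data[[event_col]])
}

# numeric formatting used by all text writers: full precision, so that a
# deterministic rerun is byte-identical on disk
format_full <- function(x) {
  if (is.double(x)) format(x, digits = 17, trim = TRUE, scientific = FALSE) else x
}
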