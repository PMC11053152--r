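#' Read or write a clinical table
#'
#' The clinical CSV schema carries one row per PM patient: `patient_id`,
#' the 11 modelling covariates (`age`, `gender`, `max_nodule_size`,
#' `multifocality`, `ETE`, `TLNR`, `LLNR`, `TLNN`, `LLNN`, `surgery`, `HT`)
#' and the right-censored recurrence outcome (`event` in {0,1}, `time` in
#' months).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_clinical_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_clinical(tbl)
  tbl
}

#' @rdname read_clinical_table
#' @param table A clinical tibble.
#' @export
write_clinical_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

clinical_covariates <- function() {
  c("age", "gender", "max_nodule_size", "multifocality", "ETE",
    "TLNR", "LLNR", "TLNN", "LLNN", "surgery", "HT")
}

validate_clinical <- function(tbl) {
  need <- c("patient_id", clinical_covariates(), "event", "time")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) stop_input("clinical table lacks columns: %s",
                                  paste(missing, collapse = ", "))
  if (any(tbl$time <= 0)) stop_data("follow-up times must be positive")
  if (!all(tbl$event %in% c(0, 1))) stop_data("event must be 0/1")
  invisible(tbl)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling by default, Wald confidence
#' intervals, Harrell's C on the fitted linear predictor, `AIC = 2k - 2 logPL`
#' and the global score (log-rank) p-value. Character covariates are treated
#' as factors with treatment coding (reference = first level alphabetically).
#'
#' @param data A data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate names.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return A `cox_result`: access per-covariate estimates via [tidy()] and
#'   model-level statistics via [glance()].
#' @export
fit_cox <- function(data, covariates, tie_method = c("efron", "breslow"),
                    conf_level = 0.95) {
  tie_method <- match.arg(tie_method)
  if (sum(data$event) < 1) stop_data("Cox model needs at least one event")
  missing <- setdiff(covariates, names(data))
  if (length(missing)) stop_input("covariates absent: %s", paste(missing, collapse = ", "))
  constant <- covariates[vapply(covariates, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) < 2
  }, logical(1))]
  if (length(constant)) stop_input("constant covariates: %s", paste(constant, collapse = ", "))
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = tie_method, x = TRUE)
  flagged <- !is.null(fit$info) || any(!is.finite(coef(fit))) ||
    any(sqrt(diag(fit$var)) > 100)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- coef(fit)
  se <- sqrt(diag(fit$var))
  tid <- tibble::tibble(
    term = names(est),
    log_hr = unname(est),
    hr = exp(unname(est)),
    conf_low = exp(unname(est) - z * se),
    conf_high = exp(unname(est) + z * se),
    se = unname(se),
    p = 2 * pnorm(-abs(unname(est) / se))
  )
  sc <- summary(fit)
  gl <- tibble::tibble(
    n = fit$n,
    n_events = fit$nevent,
    logrank_p = unname(sc$sctest["pvalue"]),
    aic = AIC(fit),
    concordance = unname(fit$concordance["concordance"]),
    loglik = fit$loglik[2],
    tie_method = tie_method,
    flagged = flagged
  )
  structure(list(fit = fit, terms = tid, model = gl, covariates = covariates),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %d covariates, n = %d, events = %d (%s ties)\n",
              length(x$covariates), x$model$n, x$model$n_events,
              x$model$tie_method))
  print(x$terms)
  cat(sprintf("  global log-rank p = %.4g; AIC = %.2f; C-index = %.4f\n",
              x$model$logrank_p, x$model$aic, x$model$concordance))
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `cox_result`.
#' @param ... Unused.
#' @export
tidy.cox_result <- function(x, ...) x$terms

#' @rdname fit_cox
#' @export
glance.cox_result <- function(x, ...) x$model

#' Univariate Cox screen over a set of covariates
#'
#' Fits one single-covariate Cox model per feature and stacks the tidied
#' results, the screen used to identify clinical recurrence risk factors.
#'
#' @param data A clinical data frame with `time` and `event`.
#' @param covariates Covariate names (default: the 11 clinical features).
#' @param ... Passed to [fit_cox()].
#' @return A tibble with one row per model term plus `covariate`, `aic`,
#'   `concordance`, `logrank_p` columns.
#' @export
univariate_cox <- function(data, covariates = clinical_covariates(), ...) {
  purrr::map_dfr(covariates, function(v) {
    res <- fit_cox(data, v, ...)
    out <- res$terms
    out$covariate <- v
    out$aic <- res$model$aic
    out$concordance <- res$model$concordance
    out$logrank_p <- res$model$logrank_p
    out
  })
}

#' Dichotomize age at a cutoff
#'
#' Returns 0 for ages strictly below the cutoff and 1 otherwise (the boundary
#' age is coded 1). The default cutoff is the cohort median (16 years in the
#' study cohort).
#'
#' @param ages Numeric vector.
#' @param cutoff Numeric cutoff; defaults to `median(ages)`.
#' @return Integer vector of 0/1, same length as `ages`.
#' @export
categorize_age <- function(ages, cutoff = median(ages)) {
  if (length(ages) == 0) return(integer(0))
  as.integer(ages >= cutoff)
}

#' Split values at the sample median
#'
#' Label 0 for values strictly below the median, 1 for values at or above it.
#'
#' @param values Numeric vector (>= 2 values).
#' @return Integer 0/1 labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop_input("median_split needs at least 2 values")
  m <- median(values)
  labels <- as.integer(values >= m)
  if (length(unique(labels)) == 1) {
    warn_protrisk("all values fall in a single median-split group")
  }
  labels
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit estimates per group and the two-group (or k-group) log-rank
#' chi-square and p-value.
#'
#' @param data A data frame with `time` and `event`.
#' @param group_labels Vector of group labels aligned with `data` rows.
#' @return A `km_result`: `curves` (tibble: `group`, `time`, `surv`,
#'   `n_risk`, `n_event`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(data, group_labels) {
  if (length(group_labels) != nrow(data)) stop_input("group labels must align with rows")
  grp <- as.factor(group_labels)
  if (any(table(grp) == 0) || nlevels(droplevels(grp)) < 2) {
    stop_input("log-rank needs two non-empty groups")
  }
  df0 <- data.frame(time = data$time, event = data$event, group = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df0)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = sf$time, surv = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event
  )
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df0)
  p <- stats::pchisq(sd0$chisq, length(sd0$n) - 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd0$chisq),
                 df = length(sd0$n) - 1, p = p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d groups; log-rank chi-square = %.3f (df %d), p = %.4g\n",
              length(unique(x$curves$group)), x$chisq, x$df, x$p))
  invisible(x)
}

#' @export
tidy.km_result <- function(x, ...) x$curves

#' Kaplan-Meier plot
#'
#' @param object A `km_result`.
#' @param ... Unused.
#' @return A ggplot of the step curves.
#' @export
autoplot.km_result <- function(object, ...) {
  start <- dplyr::distinct(object$curves, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start, object$curves[, c("group", "time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "recurrence-free survival",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' Compare continuous vs categorical age codings
#'
#' Fits the full multivariate clinical Cox model twice — once with age as a
#' continuous covariate and once dichotomized at `cutoff` — and reports the
#' global log-rank p, AIC and Harrell C-index for both, with the winner per
#' criterion.
#'
#' @param data Clinical table with the 11 covariates, `time`, `event`.
#' @param cutoff Age cutoff (default: cohort median).
#' @param covariates Covariates of the multivariate model.
#' @param ... Passed to [fit_cox()].
#' @return A list: `continuous` and `categorical` (`cox_result`s),
#'   `comparison` tibble with `criterion`, `continuous`, `categorical`,
#'   `winner`.
#' @export
compare_age_codings <- function(data, cutoff = median(data$age),
                                covariates = clinical_covariates(), ...) {
  data_cat <- data
  data_cat$age <- categorize_age(data$age, cutoff)
  fit_cont <- fit_cox(data, covariates, ...)
  fit_cat <- fit_cox(data_cat, covariates, ...)
  comparison <- tibble::tibble(
    criterion = c("logrank_p", "aic", "concordance"),
    continuous = c(fit_cont$model$logrank_p, fit_cont$model$aic,
                   fit_cont$model$concordance),
    categorical = c(fit_cat$model$logrank_p, fit_cat$model$aic,
                    fit_cat$model$concordance)
  )
  # smaller is better for p and AIC, larger for concordance
  comparison$winner <- ifelse(
    (comparison$criterion == "concordance") == (comparison$categorical > comparison$continuous),
    "categorical", "continuous"
  )
  list(continuous = fit_cont, categorical = fit_cat, comparison = comparison)
}

#' Descriptive statistics of a PM clinical table
#'
#' Recomputes the cohort summaries reported for the study population: mean
#' and SD of tumor size, lymph-node-positive count, median follow-up, event
#' count, median age, and surgery breakdown.
#'
#' @param table A clinical tibble.
#' @return A one-row tibble of summaries.
#' @export
describe_clinical <- function(table) {
  validate_clinical(table)
  tibble::tibble(
    n = nrow(table),
    n_events = sum(table$event),
    mean_tumor_size = mean(table$max_nodule_size),
    sd_tumor_size = sd(table$max_nodule_size),
    n_node_positive = sum(table$TLNN > 0),
    median_followup = median(table$time),
    median_age = median(table$age),
    n_total_thyroidectomy = sum(table$surgery == "total"),
    n_multifocal = sum(table$multifocality == 1)
  )
}
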