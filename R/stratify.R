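#' Predict per-patient survival curves
#'
#' For a survival forest, the ensemble Nelson-Aalen-based survival function
#' on the training event-time grid; for a Cox learner, the baseline-hazard
#' curve raised to `exp(lp)`. A time-zero point with survival 1 is always
#' included, and curves are clipped to [0, 1] and made non-increasing.
#'
#' @param model A `risk_model`.
#' @param data Data frame with `patient_id` and the model's feature columns.
#' @return A tibble of class `survival_curves`: `patient_id`, `time`, `surv`.
#' @export
predict_survival_curve <- function(model, data) {
  missing <- setdiff(model$features, names(data))
  if (length(missing)) stop_input("features absent from data: %s",
                                  paste(missing, collapse = ", "))
  if (model$learner == "rsf") {
    df <- as.data.frame(data[, model$features, drop = FALSE])
    df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
    pr <- predict(model$fit, data = df, num.threads = 1)
    times <- pr$unique.death.times
    surv <- pr$survival
  } else {
    nd <- as.data.frame(data[, model$features, drop = FALSE])
    sf <- survival::survfit(model$fit, newdata = nd)
    times <- sf$time
    surv <- t(if (is.matrix(sf$surv)) sf$surv else matrix(sf$surv, ncol = 1))
  }
  surv <- pmin(pmax(surv, 0), 1)
  # enforce monotone non-increasing curves along the grid
  surv <- t(apply(surv, 1, cummin))
  out <- tibble::tibble(
    patient_id = rep(data$patient_id, each = length(times) + 1),
    time = rep(c(0, times), times = nrow(data)),
    surv = as.vector(t(cbind(1, surv)))
  )
  structure(out, class = c("survival_curves", class(out)))
}

#' Continuous risk ranking (Crank) from predicted survival curves
#'
#' The expectation of each predicted curve is computed as the restricted
#' mean survival time (RMST), the trapezoid-rule integral of S(t) from 0 to
#' the horizon (curves are carried forward at their last value if the grid
#' ends before the horizon). The Crank score is `horizon - RMST` — the
#' expected event exposure — so that higher Crank means higher recurrence
#' risk.
#'
#' @param curves A `survival_curves` tibble (or any tibble with
#'   `patient_id`, `time`, `surv`).
#' @param horizon Integration horizon in months; defaults to the maximum
#'   grid time across the curves.
#' @return A tibble: `patient_id`, `rmst`, `crank`.
#' @export
compute_crank <- function(curves, horizon = NULL) {
  if (nrow(curves) == 0) stop_input("empty curve grid")
  if (is.null(horizon)) horizon <- max(curves$time)
  if (horizon <= 0) stop_input("horizon must be positive")
  out <- curves |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(rmst = rmst_trapezoid(.data$time, .data$surv, horizon),
                     .groups = "drop")
  out$crank <- horizon - out$rmst
  out[match(unique(curves$patient_id), out$patient_id), ]
}

# trapezoid integral of a survival curve up to the horizon, carrying the
# last value forward beyond the grid
rmst_trapezoid <- function(time, surv, horizon) {
  o <- order(time)
  time <- time[o]; surv <- surv[o]
  if (time[1] > 0) { time <- c(0, time); surv <- c(1, surv) }
  keep <- time <= horizon
  t2 <- time[keep]; s2 <- surv[keep]
  if (max(t2) < horizon) {
    # interpolate the curve value at the horizon if inside the grid,
    # otherwise carry the last value forward
    if (any(time > horizon)) {
      i <- which(time > horizon)[1]
      s_h <- surv[i - 1] + (surv[i] - surv[i - 1]) *
        (horizon - time[i - 1]) / (time[i] - time[i - 1])
    } else {
      s_h <- s2[length(s2)]
    }
    t2 <- c(t2, horizon); s2 <- c(s2, s_h)
  }
  sum(diff(t2) * (head(s2, -1) + s2[-1]) / 2)
}

#' Risk stratification threshold from training Cranks
#'
#' The midpoint between the mean Crank of the recurrence group and the mean
#' Crank of the non-recurrence group, computed on the training set only. A
#' pooled-variance Fisher/LDA boundary is available as an alternative: the
#' point where the two equal-variance normal densities (weighted by class
#' priors) cross.
#'
#' @param cranks Numeric Crank scores of the training patients.
#' @param events 0/1 recurrence indicators aligned with `cranks`.
#' @param method `"midpoint"` (default, the study rule) or `"lda"`.
#' @return The threshold (numeric scalar).
#' @export
compute_threshold <- function(cranks, events, method = c("midpoint", "lda")) {
  method <- match.arg(method)
  if (length(cranks) != length(events)) stop_input("cranks and events must align")
  m1 <- mean(cranks[events == 1])
  m0 <- mean(cranks[events == 0])
  if (!is.finite(m1) || !is.finite(m0)) {
    stop_data("both recurrence and non-recurrence groups must be non-empty")
  }
  if (method == "midpoint") {
    (m1 + m0) / 2
  } else {
    n1 <- sum(events == 1); n0 <- sum(events == 0)
    s2 <- (sum((cranks[events == 1] - m1)^2) + sum((cranks[events == 0] - m0)^2)) /
      (n1 + n0 - 2)
    if (m1 == m0) return(m1)
    (m1 + m0) / 2 + s2 * log(n0 / n1) / (m1 - m0)
  }
}

#' Classify patients as high or low recurrence risk
#'
#' High risk iff `crank >= threshold`; the boundary patient is classified
#' high (conservative toward closer follow-up).
#'
#' @param cranks Numeric Crank scores.
#' @param threshold Finite threshold.
#' @return Character vector of `"high"` / `"low"`.
#' @export
stratify_patients <- function(cranks, threshold) {
  if (!is.finite(threshold)) stop_input("threshold must be finite")
  ifelse(cranks >= threshold, "high", "low")
}

#' Evaluate a high/low risk stratification against observed recurrence
#'
#' High risk is treated as predicted recurrence: the confusion matrix,
#' accuracy, and — per partition, when a `set` column is present — the
#' Kaplan-Meier curves and log-rank p-value between predicted groups. If
#' only one risk class is present in a partition the log-rank test is
#' skipped with a warning.
#'
#' @param labels Character `"high"` / `"low"` per patient.
#' @param outcomes Data frame aligned with `labels`: `time`, `event`, and
#'   optionally `patient_id` and `set` (e.g. train/test).
#' @return A `stratification`: `patients` tibble (label, outcome, correct),
#'   `confusion` (TP/FP/TN/FN), `accuracy`, `km` (named list of
#'   [km_logrank()] results per partition or `overall`).
#' @export
evaluate_stratification <- function(labels, outcomes) {
  if (length(labels) != nrow(outcomes)) stop_input("labels and outcomes must align")
  predicted <- as.integer(labels == "high")
  observed <- outcomes$event
  tp <- sum(predicted == 1 & observed == 1)
  fp <- sum(predicted == 1 & observed == 0)
  tn <- sum(predicted == 0 & observed == 0)
  fn <- sum(predicted == 0 & observed == 1)
  patients <- tibble::tibble(
    patient_id = outcomes[["patient_id"]] %||% seq_along(labels),
    set = outcomes[["set"]] %||% "overall",
    label = labels, time = outcomes$time, event = observed,
    correct = predicted == observed
  )
  km <- lapply(split(patients, patients$set), function(d) {
    if (length(unique(d$label)) < 2) {
      warn_protrisk("single risk class in partition '%s': log-rank skipped", d$set[1])
      return(NULL)
    }
    km_logrank(d, d$label)
  })
  structure(list(
    patients = patients,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = (tp + tn) / length(labels),
    km = km
  ), class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<stratification> accuracy %.4f (%d/%d correct)\n",
              x$accuracy, cm["TP"] + cm["TN"], sum(cm)))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  for (nm in names(x$km)) {
    if (!is.null(x$km[[nm]])) {
      cat(sprintf("  %s: log-rank p = %.4g\n", nm, x$km[[nm]]$p))
    }
  }
  invisible(x)
}

#' @export
tidy.stratification <- function(x, ...) x$patients

#' @export
glance.stratification <- function(x, ...) {
  cm <- as.list(x$confusion)
  tibble::tibble(accuracy = x$accuracy, TP = cm$TP, FP = cm$FP, TN = cm$TN,
                 FN = cm$FN)
}

#' Full risk stratification of a cohort with a fitted model
#'
#' Predicts survival curves and Cranks for every patient, computes the
#' stratification threshold on the training partition only, classifies all
#' patients, and evaluates the result per partition.
#'
#' @param model A `risk_model` (its stored split defines train/test).
#' @param data Patient table with `patient_id`, `time`, `event` and the
#'   model's features.
#' @param horizon Crank integration horizon; defaults to the maximum
#'   training event-time grid.
#' @param threshold_method Passed to [compute_threshold()].
#' @return A list of class `risk_stratification`: `cranks` (tibble with
#'   `patient_id`, `set`, `rmst`, `crank`, `label`), `threshold`,
#'   `curves`, `evaluation` (a `stratification`).
#' @export
risk_stratify <- function(model, data, horizon = NULL,
                          threshold_method = "midpoint") {
  split <- model$split
  curves <- predict_survival_curve(model, data)
  if (is.null(horizon)) horizon <- max(curves$time)
  cranks <- compute_crank(curves, horizon)
  cranks$set <- ifelse(data$patient_id[match(cranks$patient_id, data$patient_id)]
                       %in% split$train_ids, "train", "test")
  train_mask <- data$patient_id %in% split$train_ids
  train_cranks <- cranks$crank[match(data$patient_id[train_mask], cranks$patient_id)]
  threshold <- compute_threshold(train_cranks, data$event[train_mask],
                                 method = threshold_method)
  cranks$label <- stratify_patients(cranks$crank, threshold)
  ord <- match(cranks$patient_id, data$patient_id)
  outcomes <- tibble::tibble(patient_id = cranks$patient_id,
                             time = data$time[ord], event = data$event[ord],
                             set = cranks$set)
  evaluation <- evaluate_stratification(cranks$label, outcomes)
  structure(list(cranks = cranks, threshold = threshold, horizon = horizon,
                 curves = curves, evaluation = evaluation),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("<risk_stratification> threshold %.3f (horizon %.1f months)\n",
              x$threshold, x$horizon))
  print(x$evaluation)
  invisible(x)
}

#' Crank density plot by recurrence status
#'
#' The training-set Crank distributions of the recurrence and
#' non-recurrence groups, with the stratification threshold.
#'
#' @param object A `risk_stratification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_stratification <- function(object, ...) {
  df <- dplyr::inner_join(object$cranks,
                          dplyr::distinct(object$evaluation$patients,
                                          .data$patient_id, .data$event),
                          by = "patient_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$crank, fill = factor(.data$event))) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "Crank (expected event exposure, months)",
                  fill = "recurrence") +
    ggplot2::theme_minimal()
}
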