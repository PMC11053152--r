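#' Two-sided Welch's t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom, as
#' used for all protein-level group comparisons (on log2 abundances).
#'
#' @param values_a,values_b Numeric vectors (missing values dropped).
#' @return A tibble: `t`, `df`, `p`. If either group has fewer than two
#'   finite values, or both group variances are zero, the result is `NA`.
#' @export
welch_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  res <- welch_test_matrix(matrix(a, nrow = 1), matrix(b, nrow = 1))
  tibble::tibble(t = res$t, df = res$df, p = res$p)
}

# vectorized Welch test across matrix rows; NA entries are omitted per row
welch_test_matrix <- function(A, B) {
  na_ <- rowSums(!is.na(A))
  nb_ <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  va <- rowSums((A - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((B - mb)^2, na.rm = TRUE) / pmax(nb_ - 1, 1)
  sa <- va / na_
  sb <- vb / nb_
  se2 <- sa + sb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (sa^2 / (na_ - 1) + sb^2 / (nb_ - 1))
  # identical groups with zero variance: define t = 0, p = 1
  zero <- se2 == 0
  t[zero & ma == mb] <- 0
  df[zero] <- na_[zero] + nb_[zero] - 2
  p <- 2 * pt(-abs(t), df)
  p[zero & ma == mb] <- 1
  bad <- na_ < 2 | nb_ < 2 | (zero & ma != mb)
  t[bad] <- NA_real_; df[bad] <- NA_real_; p[bad] <- NA_real_
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, n_a = na_, n_b = nb_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Missing values are excluded from the family and returned
#' missing.
#'
#' @param pvals Numeric vector of p-values in [0, 1], `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop_input("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Call differentially expressed proteins between two groups
#'
#' Fold change is the ratio of linear-scale group means (oriented
#' `group_a / group_b`); the Welch test runs on log2 abundances; p-values are
#' BH-adjusted across all proteins tested in the comparison. A protein is
#' called `up` if `fc > fc_threshold` and `p_adj < alpha`, `down` if
#' `fc < 1 / fc_threshold` and `p_adj < alpha`, otherwise `ns`.
#'
#' @param x An [abundance_matrix()] (either scale; conversions are handled).
#' @param group_a,group_b Group labels present in the sample metadata.
#' @param fc_threshold Linear fold-change threshold (> 1); the study uses 1.5
#'   for enrichment work and 1.2 to build the prognostic feature pool.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A `dep_table` tibble: `protein_id`, `mean_a`, `mean_b` (linear),
#'   `fc`, `log2fc`, `t`, `df`, `p_raw`, `p_adj`, `call`.
#' @export
call_deps <- function(x, group_a = "PM", group_b = "PB", fc_threshold = 1.5,
                      alpha = 0.05) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (fc_threshold <= 1) stop_input("fc_threshold must exceed 1")
  for (g in c(group_a, group_b)) {
    if (!g %in% x$samples$group) stop_input("group '%s' absent from the matrix", g)
  }
  ids_a <- x$samples$sample_id[x$samples$group == group_a]
  ids_b <- x$samples$sample_id[x$samples$group == group_b]
  log2v <- as_log2_values(x)
  linv <- 2^log2v
  test <- welch_test_matrix(log2v[, ids_a, drop = FALSE], log2v[, ids_b, drop = FALSE])
  mean_a <- rowMeans(linv[, ids_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(linv[, ids_b, drop = FALSE], na.rm = TRUE)
  fc <- mean_a / mean_b
  p_adj <- bh_adjust(test$p)
  call <- dplyr::case_when(
    !is.na(p_adj) & p_adj < alpha & fc > fc_threshold ~ "up",
    !is.na(p_adj) & p_adj < alpha & fc < 1 / fc_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    protein_id = rownames(log2v),
    mean_a = mean_a, mean_b = mean_b,
    fc = fc, log2fc = log2(fc),
    t = test$t, df = test$df, p_raw = test$p, p_adj = p_adj,
    call = call
  )
  structure(out,
            class = c("dep_table", class(out)),
            comparison = c(group_a, group_b),
            fc_threshold = fc_threshold, alpha = alpha)
}

# log2 values regardless of stored scale; non-positive linear values become
# NA for testing purposes (they cannot be log-transformed)
as_log2_values <- function(x) {
  if (x$scale == "log2") return(x$values)
  v <- x$values
  v[!is.na(v) & v <= 0] <- NA_real_
  log2(v)
}

#' @export
print.dep_table <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("<dep_table> %s vs %s (FC > %.2f, adjusted p < %.2f)\n",
              cmp[1], cmp[2], attr(x, "fc_threshold"), attr(x, "alpha")))
  cat(sprintf("  %d proteins: %d up, %d down\n", nrow(x),
              sum(x$call == "up"), sum(x$call == "down")))
  NextMethod()
}

#' Overlap of two DEP tables by direction
#'
#' @param dep_a,dep_b `dep_table`s sharing a protein universe.
#' @return A list: `co_up`, `co_down`, `only_a`, `only_b` (character protein
#'   id vectors) and `counts` (named integer vector).
#' @export
overlap_deps <- function(dep_a, dep_b) {
  up_a <- dep_a$protein_id[dep_a$call == "up"]
  up_b <- dep_b$protein_id[dep_b$call == "up"]
  dn_a <- dep_a$protein_id[dep_a$call == "down"]
  dn_b <- dep_b$protein_id[dep_b$call == "down"]
  sig_a <- union(up_a, dn_a); sig_b <- union(up_b, dn_b)
  out <- list(
    co_up = intersect(up_a, up_b),
    co_down = intersect(dn_a, dn_b),
    only_a = setdiff(sig_a, sig_b),
    only_b = setdiff(sig_b, sig_a)
  )
  out$counts <- vapply(out, length, integer(1))
  out
}

#' Tukey's fences outlier filter
#'
#' Retains values within `[Q1 - k IQR, Q3 + k IQR]`; quartiles use linear
#' interpolation (R quantile type 7). Fewer than four finite values are
#' returned unchanged with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return The retained values, in input order.
#' @export
tukey_fences_filter <- function(values, k = 1.5) {
  if (k <= 0) stop_input("k must be positive")
  finite <- values[is.finite(values)]
  if (length(finite) < 4) {
    warn_protrisk("fewer than 4 finite values; returned unchanged")
    return(values)
  }
  q <- quantile(finite, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  values[is.finite(values) & values >= lo & values <= hi]
}

#' Pairwise Pearson correlations between two feature sets
#'
#' Pearson r with a two-sided t-based p-value for each (feature, fraction)
#' pair, using pairwise-complete observations; pairs with fewer than three
#' complete observations get missing results.
#'
#' @param feature_matrix,fraction_matrix Data frames or matrices with matched
#'   rows (samples) and named columns.
#' @return A tibble: `feature`, `fraction`, `n`, `r`, `p`.
#' @export
correlate_features <- function(feature_matrix, fraction_matrix) {
  fm <- as.data.frame(feature_matrix)
  gm <- as.data.frame(fraction_matrix)
  if (nrow(fm) != nrow(gm)) stop_input("feature and fraction matrices must have matched samples")
  grid <- expand.grid(feature = names(fm), fraction = names(gm),
                      stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(grid, function(feature, fraction) {
    xv <- fm[[feature]]; yv <- gm[[fraction]]
    ok <- is.finite(xv) & is.finite(yv)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(feature = feature, fraction = fraction,
                            n = n, r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(xv[ok], yv[ok])
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), n - 2)
    }
    tibble::tibble(feature = feature, fraction = fraction, n = n, r = r, p = p)
  })
  tibble::as_tibble(res)
}

#' Volcano plot of a DEP table
#'
#' @param object A `dep_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dep_table <- function(object, ...) {
  cmp <- attr(object, "comparison")
  df <- dplyr::filter(object, is.finite(.data$log2fc), !is.na(.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_adj),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = sprintf("log2 fold change (%s / %s)", cmp[1], cmp[2]),
                  y = expression(-log[10] ~ "adjusted p"), colour = NULL) +
    ggplot2::theme_minimal()
}
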