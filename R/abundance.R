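#' Protein abundance matrix with sample metadata
#'
#' The central container for quantitative proteome data: a numeric matrix of
#' protein abundances (rows = proteins, columns = samples, `NA` = missing)
#' together with a per-sample metadata tibble carrying the biological group
#' (`PB`, `PM`, `AM`, or `POOL` for pooled reference channels), the TMT batch,
#' and an optional technical-replicate link. A `scale` tag records whether the
#' values are log2-transformed or linear; preprocessing steps that are defined
#' on one scale convert explicitly via [as_log2()] / [as_linear()].
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing values.
#' @param samples A data frame with one row per column of `values`:
#'   `sample_id`, `group`, `batch`, and optionally `replicate_of` (the
#'   `sample_id` this column is a technical replicate of, `NA` otherwise).
#' @param scale `"log2"` or `"linear"`.
#'
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, samples, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  samples <- tibble::as_tibble(samples)
  if (is.null(rownames(values))) stop_input("values must have protein ids as rownames")
  if (is.null(colnames(values))) stop_input("values must have sample ids as colnames")
  if (anyDuplicated(rownames(values))) stop_input("duplicate protein ids")
  if (anyDuplicated(colnames(values))) stop_input("duplicate sample ids")
  if (!all(c("sample_id", "group", "batch") %in% names(samples))) {
    stop_input("samples must have columns sample_id, group, batch")
  }
  if (!"replicate_of" %in% names(samples)) samples$replicate_of <- NA_character_
  if (!identical(colnames(values), samples$sample_id)) {
    stop_input("colnames(values) must equal samples$sample_id, in order")
  }
  if (anyNA(samples$batch)) stop_input("every sample must have a batch")
  bad <- !is.na(samples$replicate_of) & !(samples$replicate_of %in% samples$sample_id)
  if (any(bad)) {
    stop_data("dangling replicate link: %s", paste(samples$sample_id[bad], collapse = ", "))
  }
  structure(
    list(values = values, samples = samples, scale = scale),
    class = "abundance_matrix",
    stages = character()
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  na_frac <- mean(is.na(x$values))
  cat(sprintf(
    "<abundance_matrix> %d proteins x %d samples (%s scale, %.1f%% missing)\n",
    nrow(x$values), ncol(x$values), x$scale, 100 * na_frac
  ))
  grp <- table(x$samples$group)
  cat("  samples:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  stages <- attr(x, "stages")
  if (length(stages)) cat("  stages applied:", paste(stages, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Tidy an abundance matrix into long format
#'
#' @param x An [abundance_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per protein/sample pair: `protein_id`,
#'   `sample_id`, `abundance`, `group`, `batch`.
#' @export
tidy.abundance_matrix <- function(x, ...) {
  long <- tibble::tibble(
    protein_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    abundance = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Convert an abundance matrix between log2 and linear scale
#'
#' The preprocessing chain mixes scales by design: imputation and batch
#' correction operate on log2 abundances, while the half-minimum replacement
#' rule is defined on positive linear abundances. These converters make the
#' bookkeeping explicit.
#'
#' @param x An [abundance_matrix()].
#' @return The same object on the requested scale.
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "linear") return(x)
  out <- x
  out$values <- 2^x$values
  out$scale <- "linear"
  attr(out, "stages") <- attr(x, "stages")
  out
}

#' @rdname as_linear
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "log2") return(x)
  if (any(x$values <= 0, na.rm = TRUE)) {
    stop_data("cannot log2-transform: non-positive values present (run replace_nonpositive first)")
  }
  out <- x
  out$values <- log2(x$values)
  out$scale <- "log2"
  attr(out, "stages") <- attr(x, "stages")
  out
}

# columns holding tissue measurements (excludes pooled reference channels)
tissue_ids <- function(x) x$samples$sample_id[x$samples$group != "POOL"]

mark_stage <- function(x, stage) {
  attr(x, "stages") <- c(attr(x, "stages"), stage)
  x
}

#' Read and write abundance matrices as TSV
#'
#' The on-disk format is a tab-separated table with protein ids in the first
#' column (`protein_id`), one column per sample, and the literal token `NA`
#' for missing values; sample metadata travels in a companion TSV.
#'
#' @param x An [abundance_matrix()].
#' @param path Path for the abundance TSV.
#' @param meta_path Path for the sample-metadata TSV.
#' @return `write_abundance()` returns the paths invisibly;
#'   `read_abundance()` returns an [abundance_matrix()].
#' @export
write_abundance <- function(x, path, meta_path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(protein_id = rownames(x$values),
                   apply(x$values, 2, format_full),
                   check.names = FALSE)
  readr::write_tsv(df, path, na = "NA")
  meta <- x$samples
  meta$scale <- x$scale
  readr::write_tsv(meta, meta_path, na = "NA")
  invisible(c(path, meta_path))
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path, meta_path) {
  df <- readr::read_tsv(path, na = "NA", show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, na = "NA", show_col_types = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$protein_id
  scale <- if ("scale" %in% names(meta)) meta$scale[1] else "log2"
  meta$scale <- NULL
  abundance_matrix(values, meta, scale = scale)
}
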