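#' Metabolite intensity table
#'
#' A samples x metabolites matrix of non-negative intensities with `NA`
#' marking missing measurements (missing is encoded distinctly from zero),
#' plus per-sample metadata (genotype, diet, group, volume) and a block label
#' distinguishing plasma-like from feces-like measurements.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   `NA` for missing.
#' @param metadata optional data frame with one row per sample; a `sample_id`
#'   column must match the matrix row names, and a `volume` column is required
#'   for volume adjustment.
#' @param block `"plasma"` or `"feces"`.
#' @return an object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, metadata = NULL,
                             block = c("plasma", "feces")) {
  block <- match.arg(block)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("met_%03d", seq_len(ncol(values)))
  if (any(values < 0, na.rm = TRUE))
    stop("metabolite intensities must be non-negative", call. = FALSE)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata))
      stop("metadata requires a 'sample_id' column", call. = FALSE)
    if (!all(rownames(values) %in% metadata$sample_id))
      stop("metadata does not cover all samples", call. = FALSE)
    metadata <- metadata[match(rownames(values), metadata$sample_id), ,
                         drop = FALSE]
  }
  structure(list(values = values, metadata = metadata, block = block,
                 qc_log = character(0)),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table (%s): %d samples x %d metabolites, %.1f%% missing\n",
              x$block, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  if (length(x$qc_log)) cat(paste0("  - ", x$qc_log, collapse = "\n"), "\n")
  invisible(x)
}

log_step <- function(t, msg) {
  t$qc_log <- c(t$qc_log, msg)
  t
}

#' Remove metabolites with excessive missingness
#'
#' Metabolites whose missing fraction strictly exceeds `max_missing` are
#' eliminated; a metabolite with exactly `max_missing` missing is retained.
#' Column order is preserved.
#'
#' @param t a [metabolite_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @return the filtered table.
#' @export
filter_missing <- function(t, max_missing = 0.30) {
  stopifnot(inherits(t, "metabolite_table"), ncol(t$values) > 0)
  frac <- colMeans(is.na(t$values))
  keep <- frac <= max_missing
  if (!any(keep))
    warning("all metabolites exceed the missingness threshold", call. = FALSE)
  t$values <- t$values[, keep, drop = FALSE]
  log_step(t, sprintf("filter_missing(>%g): removed %d of %d metabolites",
                      max_missing, sum(!keep), length(keep)))
}

#' Divide each sample by its recorded volume
#'
#' Applied to raw intensities before median scaling; requires a `volume`
#' column in the sample metadata. Intended for the plasma block.
#'
#' @param t a [metabolite_table()].
#' @return the adjusted table.
#' @export
volume_adjust <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  if (is.null(t$metadata) || !"volume" %in% names(t$metadata))
    stop("volume adjustment requires 'volume' in sample metadata", call. = FALSE)
  v <- t$metadata$volume
  if (any(!is.finite(v)) || any(v <= 0))
    stop("sample volumes must be positive", call. = FALSE)
  t$values <- sweep(t$values, 1, v, "/")
  log_step(t, "volume_adjust: intensities divided by sample volume")
}

#' Rescale each metabolite to an observed median of one
#'
#' Per metabolite, observed values are divided by that metabolite's median
#' over observed entries, so after scaling every column's observed median is
#' exactly 1. Missing entries are preserved.
#'
#' @param t a [metabolite_table()].
#' @return the rescaled table.
#' @export
median_scale <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  med <- apply(t$values, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med)))
    stop("metabolite(s) with no observed values: ",
         paste(colnames(t$values)[is.na(med)], collapse = ", "), call. = FALSE)
  if (any(med <= 0))
    stop("non-positive median; intensities must be positive where observed",
         call. = FALSE)
  t$values <- sweep(t$values, 2, med, "/")
  log_step(t, "median_scale: per-metabolite observed median rescaled to 1")
}

#' Impute missing values with half the observed minimum
#'
#' Every missing cell of a metabolite is replaced by 0.5 times the minimum
#' observed value of that metabolite across all samples (and batches) of the
#' median-scaled table; observed values are untouched.
#'
#' @param t a [metabolite_table()].
#' @return the imputed table.
#' @export
impute_half_min <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  for (j in seq_len(ncol(t$values))) {
    x <- t$values[, j]
    if (all(is.na(x)))
      stop("cannot impute metabolite with no observed values: ",
           colnames(t$values)[j], call. = FALSE)
    if (anyNA(x)) t$values[is.na(x), j] <- 0.5 * min(x, na.rm = TRUE)
  }
  log_step(t, "impute_half_min: missing cells set to half the observed minimum")
}

#' Natural-log transform
#'
#' Elementwise natural log of the normalized and imputed intensities. All
#' values must be strictly positive (guaranteed after half-minimum
#' imputation of positive data).
#'
#' @param t a [metabolite_table()].
#' @return the log-transformed table.
#' @export
log_transform <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  bad <- which(t$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value at sample '%s', metabolite '%s'",
                 rownames(t$values)[bad[1, 1]],
                 colnames(t$values)[bad[1, 2]]), call. = FALSE)
  t$values <- log(t$values)
  log_step(t, "log_transform: natural log applied")
}

#' Run the full metabolite QC chain
#'
#' Fixed composition order: missingness filter, optional volume adjustment
#' (plasma block), median scaling, half-minimum imputation, natural log.
#'
#' @param t a [metabolite_table()].
#' @param max_missing missingness threshold for [filter_missing()].
#' @param adjust_volume whether to divide by sample volume before scaling;
#'   defaults to `TRUE` for the plasma block.
#' @return the processed table; its `qc_log` records each step.
#' @export
qc_metabolites <- function(t, max_missing = 0.30,
                           adjust_volume = identical(t$block, "plasma")) {
  t <- filter_missing(t, max_missing)
  if (adjust_volume) t <- volume_adjust(t)
  t <- median_scale(t)
  t <- impute_half_min(t)
  log_transform(t)
}

#' Amplicon sequence variant count table
#'
#' @param counts non-negative integer matrix, samples in rows, taxa in
#'   columns.
#' @param taxonomy optional named character vector, taxon -> lineage string.
#' @return an object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("ASV counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("ASV%03d", seq_len(ncol(counts)))
  structure(list(counts = counts, taxonomy = taxonomy), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d taxa, total %d counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Filter low-prevalence, low-abundance taxa
#'
#' By default a taxon is removed when BOTH its prevalence (fraction of
#' samples with a non-zero count) is below `prevalence_min` AND its median
#' count across samples is at or below `median_max` (0, i.e. median absent).
#' Both thresholds, and whether the two conditions are combined with AND or
#' OR, are configurable.
#'
#' @param a an [asv_table()].
#' @param prevalence_min minimum prevalence (default 0.10).
#' @param median_max taxa with median count <= this value satisfy the
#'   low-abundance condition (default 0).
#' @param combine `"and"` (default) or `"or"`.
#' @return the filtered table.
#' @export
filter_asvs <- function(a, prevalence_min = 0.10, median_max = 0,
                        combine = c("and", "or")) {
  stopifnot(inherits(a, "asv_table"))
  combine <- match.arg(combine)
  prev <- colMeans(a$counts > 0)
  med <- apply(a$counts, 2, stats::median)
  low_prev <- prev < prevalence_min
  low_med <- med <= median_max
  drop <- if (combine == "and") low_prev & low_med else low_prev | low_med
  a$counts <- a$counts[, !drop, drop = FALSE]
  if (!is.null(a$taxonomy)) a$taxonomy <- a$taxonomy[colnames(a$counts)]
  a
}

#' Centered log-ratio transform
#'
#' Per sample, `log(count + pseudocount)` minus the sample mean of
#' `log(count + pseudocount)`, so each output row sums to zero.
#'
#' @param a an [asv_table()] or a non-negative count matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return a numeric matrix of CLR values.
#' @export
clr_transform <- function(a, pseudocount = 1) {
  if (inherits(a, "asv_table")) a <- a$counts
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  lx <- log(as.matrix(a) + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Chi-squared cutoff for the Mahalanobis outlier rule
#'
#' @param quantile chi-squared quantile (default 0.99).
#' @param df degrees of freedom, i.e. the number of principal components
#'   (default 2).
#' @return the squared-distance cutoff.
#' @export
mahalanobis_cutoff <- function(quantile = 0.99, df = 2) {
  stats::qchisq(quantile, df = df)
}

#' Multivariate outlier detection in PCA score space
#'
#' Samples are projected onto the first `n_components` principal components;
#' each sample's squared Mahalanobis distance in that score space is compared
#' with the `quantile` point of a chi-squared distribution with
#' `n_components` degrees of freedom, and samples exceeding it are flagged.
#'
#' @param x numeric matrix (samples in rows) or a [metabolite_table()]
#'   (its processed values are used).
#' @param n_components number of principal components (default 2).
#' @param quantile chi-squared quantile (default 0.99).
#' @param scale. whether to unit-scale features before the PCA.
#' @return character vector of flagged sample ids, with attributes
#'   `distance` (named squared distances) and `cutoff`.
#' @export
detect_outliers <- function(x, n_components = 2, quantile = 0.99,
                            scale. = FALSE) {
  if (inherits(x, "metabolite_table")) x <- x$values
  x <- as.matrix(x)
  if (anyNA(x)) stop("outlier detection requires a complete matrix", call. = FALSE)
  if (nrow(x) < n_components + 2)
    stop("need at least n_components + 2 samples", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  if (ncol(pc$x) < n_components)
    stop("rank too low for ", n_components,
         " components; try fewer components", call. = FALSE)
  sc <- pc$x[, seq_len(n_components), drop = FALSE]
  S <- stats::cov(sc)
  if (any(diag(S) < .Machine$double.eps) ||
      abs(det(S)) < .Machine$double.eps)
    stop("singular covariance in score space; try fewer components",
         call. = FALSE)
  d2 <- stats::mahalanobis(sc, colMeans(sc), S)
  cutoff <- mahalanobis_cutoff(quantile, df = n_components)
  flagged <- rownames(x)[d2 > cutoff]
  structure(flagged, distance = stats::setNames(d2, rownames(x)),
            cutoff = cutoff)
}

#' Read / write feature tables
#'
#' TSV with samples in rows, a leading `sample_id` column, feature ids in the
#' header and `NA` as the missing marker.
#'
#' @param path file path.
#' @param metadata,block passed to [metabolite_table()].
#' @return a [metabolite_table()].
#' @export
read_feature_table <- function(path, metadata = NULL, block = "plasma") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sample_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  metabolite_table(m, metadata = metadata, block = block)
}

#' @rdname read_feature_table
#' @param t a [metabolite_table()] or [asv_table()].
#' @export
write_feature_table <- function(t, path) {
  m <- if (inherits(t, "metabolite_table")) t$values else t$counts
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
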