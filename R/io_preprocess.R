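# Count/metadata I/O, the study's gene & sample filters, median-of-ratios
# normalization, PCA/Mahalanobis outlier removal, housekeeping QC.

#' Read a count matrix and sample metadata
#'
#' Counts may be a TSV (first column gene ids, header row of sample ids) or a
#' MatrixMarket triplet as written by [write_counts()]: `<stem>.mtx` plus
#' `<stem>.genes.txt` and `<stem>.samples.txt` holding row/column ids.
#'
#' @param counts_path Path to the counts TSV or `.mtx` file.
#' @param metadata_path Path to the sample metadata TSV (columns `sample`,
#'   `group`, `region`, `subject`, optional `aligned_reads`).
#' @return A validated [count_experiment()].
#' @export
read_counts <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)

  if (grepl("\\.mtx$", counts_path)) {
    stem <- sub("\\.mtx$", "", counts_path)
    gene_path <- paste0(stem, ".genes.txt")
    sample_path <- paste0(stem, ".samples.txt")
    if (!file.exists(gene_path) || !file.exists(sample_path))
      stop("MatrixMarket counts need companion files ", gene_path, " and ", sample_path)
    m <- as.matrix(Matrix::readMM(counts_path))
    rownames(m) <- readLines(gene_path)
    colnames(m) <- readLines(sample_path)
  } else {
    df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  meta <- utils::read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  count_experiment(m, meta)
}

#' Write counts, metadata (and optionally MatrixMarket) to disk
#'
#' @param exp A `CountExperiment`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param stem File name stem, default `"counts"`.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(exp, dir, format = c("tsv", "mtx"), stem = "counts") {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(exp$sample_table, meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (format == "tsv") {
    cpath <- file.path(dir, paste0(stem, ".tsv"))
    write_matrix_tsv(exp$counts, cpath, id_col = "gene")
    paths <- c(cpath, meta_path)
  } else {
    cpath <- file.path(dir, paste0(stem, ".mtx"))
    Matrix::writeMM(Matrix::Matrix(exp$counts, sparse = TRUE), cpath)
    writeLines(rownames(exp$counts), file.path(dir, paste0(stem, ".genes.txt")))
    writeLines(colnames(exp$counts), file.path(dir, paste0(stem, ".samples.txt")))
    paths <- c(cpath, file.path(dir, paste0(stem, ".genes.txt")),
               file.path(dir, paste0(stem, ".samples.txt")), meta_path)
  }
  invisible(paths)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Drop samples with too few aligned reads
#'
#' Mirrors the study's sequencing-depth filter: samples with fewer than 10
#' million aligned reads are removed before normalization.
#'
#' @param exp A `CountExperiment`.
#' @param min_aligned_reads Threshold; samples with `aligned_reads <`
#'   this value are dropped. `0` disables the filter (useful for synthetic
#'   data, which has no alignment step).
#' @return Filtered `CountExperiment` with a `dropped_samples` attribute.
#' @export
filter_samples <- function(exp, min_aligned_reads = 1e7) {
  if (min_aligned_reads <= 0) {
    attr(exp, "dropped_samples") <- character(0)
    return(exp)
  }
  ar <- exp$sample_table$aligned_reads
  if (is.null(ar))
    stop("sample_table has no aligned_reads column but min_aligned_reads > 0")
  keep <- ar >= min_aligned_reads
  if (!any(keep)) stop("sample filter removed every sample")
  out <- subset_experiment(exp, samples = exp$sample_table$sample[keep])
  attr(out, "dropped_samples") <- exp$sample_table$sample[!keep]
  out
}

#' Drop low-count genes
#'
#' A gene is removed when its count is below `min_count` in more than
#' `max_low_samples` samples (strict inequality on the sample tally), the
#' study's background-noise filter with defaults 50 and 20.
#'
#' @param exp A `CountExperiment`.
#' @param min_count Count threshold (default 50).
#' @param max_low_samples Maximum tolerated number of samples below
#'   `min_count` (default 20).
#' @return Filtered `CountExperiment` with a `dropped_genes` attribute.
#' @export
filter_genes <- function(exp, min_count = 50, max_low_samples = 20) {
  stopifnot(min_count >= 0, max_low_samples >= 0)
  n_low <- rowSums(exp$counts < min_count)
  keep <- n_low <= max_low_samples
  if (!any(keep)) stop("gene filter removed every gene")
  out <- subset_experiment(exp, genes = rownames(exp$counts)[keep])
  attr(out, "dropped_genes") <- rownames(exp$counts)[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' The reference profile is the per-gene geometric mean across samples,
#' restricted to genes with strictly positive counts in every sample; each
#' sample's size factor is the median over those genes of count/reference.
#' No rescaling is applied afterwards.
#'
#' @param exp A `CountExperiment`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(exp) {
  counts <- exp$counts
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos))
    stop("no gene has strictly positive counts in every sample; ",
         "cannot form the median-of-ratios reference (pseudo-reference fallback is disabled)")
  logc <- log(counts[allpos, , drop = FALSE])
  ref <- exp(rowMeans(logc))  # geometric mean per gene
  ratios <- counts[allpos, , drop = FALSE] / ref
  s <- apply(ratios, 2, stats::median)
  names(s) <- colnames(counts)
  s
}

#' Normalize and log-transform counts
#'
#' Produces `log2(count / size_factor + 1)`; a deliberately simple,
#' monotone transform of the median-of-ratios-normalized counts.
#'
#' @param exp A `CountExperiment`.
#' @param s Size factors from [size_factors()] (positive, one per sample).
#' @return A `NormalizedExperiment`: list with `normexpr` (genes x samples),
#'   `size_factors`, `sample_table`, and a `provenance` log.
#' @export
normalize_transform <- function(exp, s = size_factors(exp)) {
  if (length(s) != ncol(exp$counts)) stop("one size factor per sample required")
  if (any(s <= 0)) stop("size factors must be positive")
  normexpr <- log2(sweep(exp$counts, 2, s, "/") + 1)
  structure(list(normexpr = normexpr,
                 size_factors = s,
                 sample_table = exp$sample_table,
                 provenance = list(dropped_samples = attr(exp, "dropped_samples"),
                                   dropped_genes = attr(exp, "dropped_genes"))),
            class = "NormalizedExperiment")
}

#' @export
print.NormalizedExperiment <- function(x, ...) {
  cat("NormalizedExperiment:", nrow(x$normexpr), "genes x", ncol(x$normexpr), "samples\n")
  invisible(x)
}

#' PCA-based Mahalanobis outlier detection
#'
#' Samples are projected on the top principal components of the normalized
#' expression matrix; the squared Mahalanobis distance of each sample in
#' that score space (classical covariance) is compared with a chi-squared
#' quantile cutoff.
#'
#' @param norm A `NormalizedExperiment`.
#' @param n_pcs Number of principal components (default 10, capped at
#'   `n_samples - 2`).
#' @param quantile Chi-squared quantile for the cutoff (default 0.975);
#'   `1.0` disables removal.
#' @return List with `kept`, `removed` (sample ids), `d2` (named squared
#'   distances) and `cutoff`.
#' @export
mahalanobis_outliers <- function(norm, n_pcs = 10, quantile = 0.975) {
  x <- t(norm$normexpr)              # samples x genes
  n <- nrow(x)
  n_pcs <- min(n_pcs, n - 2)
  if (n_pcs < 2) stop("need n_samples > n_pcs >= 2")
  ids <- rownames(x)

  if (all(apply(x, 2, stats::sd) < 1e-12)) {
    d2 <- stats::setNames(rep(0, n), ids)
    return(list(kept = ids, removed = character(0), d2 = d2,
                cutoff = stats::qchisq(quantile, df = n_pcs)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  S <- stats::cov(scores)
  if (rcond_safe(S) < 1e-12)
    stop("singular covariance of PC scores; use fewer PCs")
  d2 <- stats::mahalanobis(scores, colMeans(scores), S)
  names(d2) <- ids
  cutoff <- stats::qchisq(quantile, df = n_pcs)
  removed <- ids[d2 > cutoff]
  list(kept = setdiff(ids, removed), removed = removed, d2 = d2, cutoff = cutoff)
}

rcond_safe <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Housekeeping-gene QC
#'
#' Computes the coefficient of variation of normalized expression across
#' samples for a panel of housekeeping genes (defaults: RTF2, PPIB, YIPF3,
#' PSMB4). Stable housekeeping expression indicates successful
#' normalization.
#'
#' @param norm A `NormalizedExperiment`.
#' @param housekeeping_ids Character vector of gene ids.
#' @param cv_max Pass threshold on the CV (default 0.2).
#' @return List with `table` (gene, mean, sd, cv), `missing` ids, `pass`.
#' @export
qc_housekeeping <- function(norm,
                            housekeeping_ids = c("RTF2", "PPIB", "YIPF3", "PSMB4"),
                            cv_max = 0.2) {
  present <- intersect(housekeeping_ids, rownames(norm$normexpr))
  missing <- setdiff(housekeeping_ids, present)
  if (!length(present)) stop("none of the housekeeping ids are in the matrix")
  if (length(missing))
    warning("housekeeping ids absent from matrix: ", paste(missing, collapse = ", "))
  m <- norm$normexpr[present, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  tab <- data.frame(gene = present, mean = mu, sd = sdv, cv = cv,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, missing = missing, pass = all(is.finite(cv) & cv < cv_max))
}
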