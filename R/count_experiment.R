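#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("sham", "injured_1d", "injured_1wk", "treated_1d")
REGION_LEVELS <- c("FC", "HA")

#' Construct a CountExperiment
#'
#' The root object of the pipeline: a genes x samples matrix of non-negative
#' integer read counts together with a per-sample metadata table.
#'
#' @param counts Genes x samples numeric matrix of non-negative integers.
#'   Row names are gene ids, column names are sample ids.
#' @param sample_table Data frame with one row per sample and columns
#'   `sample` (id, matching `colnames(counts)`), `group` (one of `sham`,
#'   `injured_1d`, `injured_1wk`, `treated_1d`), `region` (`FC` or `HA`),
#'   `subject`, and optionally `aligned_reads` (total aligned read count,
#'   used by [filter_samples()]).
#'
#' @return An object of class `CountExperiment`: a list with elements
#'   `counts` and `sample_table`.
#' @export
count_experiment <- function(counts, sample_table) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numeric values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at gene ", rownames(counts)[bad[1]],
         ", sample ", colnames(counts)[bad[2]])
  }
  storage.mode(counts) <- "double"

  sample_table <- as.data.frame(sample_table, stringsAsFactors = FALSE)
  required <- c("sample", "group", "region", "subject")
  missing_cols <- setdiff(required, names(sample_table))
  if (length(missing_cols))
    stop("sample_table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sample_table$sample))
    stop("duplicate sample ids in sample_table")

  missing_meta <- setdiff(colnames(counts), sample_table$sample)
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(sample_table$sample, colnames(counts))
  if (length(extra_meta))
    stop("metadata rows without a count column: ", paste(extra_meta, collapse = ", "))
  sample_table <- sample_table[match(colnames(counts), sample_table$sample), , drop = FALSE]
  rownames(sample_table) <- NULL

  bad_group <- setdiff(unique(sample_table$group), GROUP_LEVELS)
  if (length(bad_group))
    stop("unknown group(s): ", paste(bad_group, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = ", "), ")")
  bad_region <- setdiff(unique(sample_table$region), REGION_LEVELS)
  if (length(bad_region))
    stop("unknown region(s): ", paste(bad_region, collapse = ", "),
         " (expected ", paste(REGION_LEVELS, collapse = ", "), ")")

  structure(list(counts = counts, sample_table = sample_table),
            class = "CountExperiment")
}

#' @export
print.CountExperiment <- function(x, ...) {
  cat("CountExperiment:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$sample_table$group)),
                               table(x$sample_table$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.CountExperiment <- function(x) dim(x$counts)

subset_experiment <- function(exp, genes = NULL, samples = NULL) {
  counts <- exp$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  st <- exp$sample_table[match(colnames(counts), exp$sample_table$sample), , drop = FALSE]
  rownames(st) <- NULL
  structure(list(counts = counts, sample_table = st), class = "CountExperiment")
}
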