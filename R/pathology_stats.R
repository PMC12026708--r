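# Percent axonal injury and the nonparametric pairwise group comparison
# (exact Wilcoxon rank-sum + Bonferroni) shared with the co-expression
# module's eigengene tests.

#' Percent axonal injury
#'
#' `100 * injured_area / total_area` per subject; both areas must be in the
#' same units (the ratio is unit-free).
#'
#' @param records Data frame with columns `injured_area` (>= 0) and
#'   `total_area` (> 0); extra columns are carried through.
#' @return The input with a `percent_injury` column appended.
#' @export
percent_axonal_injury <- function(records) {
  stopifnot(all(c("injured_area", "total_area") %in% names(records)))
  if (any(records$total_area <= 0)) stop("total_area must be positive")
  if (any(records$injured_area < 0)) stop("injured_area must be non-negative")
  if (any(records$injured_area > records$total_area))
    stop("injured_area exceeds total_area for: ",
         paste(which(records$injured_area > records$total_area), collapse = ", "))
  records$percent_injury <- 100 * records$injured_area / records$total_area
  records
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Two-sided rank-sum test for every pair of groups, exact by default
#' (small-cohort setting); with ties or more than `exact_max` observations
#' per group the midrank normal approximation is used and flagged. The
#' Bonferroni multiplier is the number of pairs tested.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups, >= 3 values each;
#'   smaller groups are skipped with a flag).
#' @param exact_max Largest per-group n for exact enumeration (default 25).
#' @return Data frame: group1, group2, n1, n2, median_diff (group2 -
#'   group1), W, pvalue, p_adjusted, exact, skipped.
#' @export
wilcoxon_bonferroni <- function(values, groups, exact_max = 25) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) stop("need at least two groups")
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- values[groups == g1]; y <- values[groups == g2]
    if (length(x) < 3 || length(y) < 3)
      return(data.frame(group1 = g1, group2 = g2,
                        n1 = length(x), n2 = length(y),
                        median_diff = NA_real_, W = NA_real_,
                        pvalue = NA_real_, exact = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    has_ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- !has_ties && length(x) <= exact_max && length(y) <= exact_max
    wt <- suppressWarnings(stats::wilcox.test(y, x, exact = use_exact,
                                              correct = !use_exact))
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               median_diff = stats::median(y) - stats::median(x),
               W = unname(wt$statistic), pvalue = wt$p.value,
               exact = use_exact, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_pairs <- sum(!out$skipped)
  out$p_adjusted <- pmin(1, out$pvalue * n_pairs)
  out
}
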