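# Two-group negative-binomial Wald test on median-of-ratios-normalized
# counts, with method-of-moments dispersion, BH adjustment, DEG calling at
# p <= 0.05 & |log2FC| >= 1, and top-5 selection by FDR and fold change.

ALPHA_MIN <- 1e-8

#' Method-of-moments NB dispersion
#'
#' Pools normalized counts across the two groups after removing group
#' means; `alpha = max((v - m) / m^2, 1e-8)` where `v` is the pooled
#' residual variance and `m` the overall mean of normalized counts.
#'
#' @param counts_for_gene Numeric vector of raw counts for one gene.
#' @param s Size factors for the same samples.
#' @param group_labels Group label per sample (exactly two levels used).
#' @return Estimated dispersion `alpha` (scalar).
#' @export
estimate_dispersion <- function(counts_for_gene, s, group_labels) {
  y <- counts_for_gene / s
  g <- as.character(group_labels)
  lv <- unique(g)
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  mu <- mean(y)
  if (mu == 0) {
    warning("zero mean; dispersion floored")
    return(ALPHA_MIN)
  }
  res <- y - ave(y, g)
  v <- sum(res^2) / (length(y) - length(lv))
  max((v - mu) / mu^2, ALPHA_MIN)
}

# Vectorized dispersion over a genes x samples normalized matrix.
dispersion_matrix <- function(y, g) {
  lv <- unique(g)
  mu <- rowMeans(y)
  res <- y
  for (l in lv) {
    j <- which(g == l)
    res[, j] <- y[, j, drop = FALSE] - rowMeans(y[, j, drop = FALSE])
  }
  v <- rowSums(res^2) / (ncol(y) - length(lv))
  alpha <- ifelse(mu > 0, (v - mu) / mu^2, ALPHA_MIN)
  pmax(alpha, ALPHA_MIN)
}

#' Negative-binomial Wald test for one two-group comparison
#'
#' Group means of normalized counts are compared on the log2 scale with a
#' 0.5 pseudocount on both means; the standard error comes from the delta
#' method with `Var(count_j / s_j) = q / s_j + alpha * q^2`, the Wald
#' statistic is referred to N(0,1), and p-values are BH-adjusted across all
#' tested genes.
#'
#' @param exp A `CountExperiment`.
#' @param s Size factors (defaults to [size_factors()] of `exp`).
#' @param comparison Character vector `c(groupA, groupB)`; the log2 fold
#'   change is B over A (e.g. `c("sham", "injured_1d")`).
#' @return A `DEResult` data frame: gene, base_mean, log2FC, se, stat,
#'   pvalue, fdr, dispersion; attribute `comparison`.
#' @export
wald_test <- function(exp, s = size_factors(exp), comparison) {
  stopifnot(length(comparison) == 2)
  g <- exp$sample_table$group
  jA <- which(g == comparison[1])
  jB <- which(g == comparison[2])
  if (!length(jA) || !length(jB))
    stop("empty group in comparison ", paste(comparison, collapse = " vs "))
  y <- sweep(exp$counts, 2, s, "/")
  yA <- y[, jA, drop = FALSE]
  yB <- y[, jB, drop = FALSE]
  if (all(yA == 0) || all(yB == 0))
    stop("a comparison group has all-zero counts for every gene")

  alpha <- dispersion_matrix(cbind(yA, yB),
                             c(rep("A", length(jA)), rep("B", length(jB))))
  qA <- rowMeans(yA)
  qB <- rowMeans(yB)
  lfc <- log2((qB + 0.5) / (qA + 0.5))

  varA <- (qA * sum(1 / s[jA])) / length(jA)^2 + alpha * qA^2 / length(jA)
  varB <- (qB * sum(1 / s[jB])) / length(jB)^2 + alpha * qB^2 / length(jB)
  se <- sqrt(varA / (qA + 0.5)^2 + varB / (qB + 0.5)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(stat)), 1)
  res <- data.frame(gene = rownames(exp$counts),
                    base_mean = rowMeans(cbind(yA, yB)),
                    log2FC = lfc, se = se, stat = stat,
                    pvalue = p, fdr = stats::p.adjust(p, method = "BH"),
                    dispersion = alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "comparison") <- comparison
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `p <= p_max` and `|log2FC| >= lfc_min` (defaults
#' 0.05 and 1, the study's main thresholds); with `fdr_mode = TRUE` the BH
#' FDR replaces the unadjusted p (the sensitivity-analysis variant).
#'
#' @param de A `DEResult`.
#' @param p_max Significance threshold (inclusive).
#' @param lfc_min Minimum absolute log2 fold change (inclusive).
#' @param fdr_mode Use `fdr` instead of `pvalue`.
#' @return Data frame of calls: gene, direction (`up`/`down`), log2FC,
#'   pvalue, fdr, comparison.
#' @export
call_degs <- function(de, p_max = 0.05, lfc_min = 1.0, fdr_mode = FALSE) {
  pv <- if (fdr_mode) de$fdr else de$pvalue
  hit <- pv <= p_max & abs(de$log2FC) >= lfc_min
  comp <- attr(de, "comparison")
  comp_str <- if (is.null(comp)) NA_character_ else paste(comp[2], "vs", comp[1])
  data.frame(gene = de$gene[hit],
             direction = ifelse(de$log2FC[hit] >= 0, "up", "down"),
             log2FC = de$log2FC[hit],
             pvalue = de$pvalue[hit], fdr = de$fdr[hit],
             comparison = rep(comp_str, sum(hit)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-k DEGs by fold change within the FDR stratum
#'
#' Among genes with `fdr <= fdr_max`, selects the `k` largest log2FC (up)
#' and the `k` most negative (down); ties break by smaller FDR, then gene
#' id.
#'
#' @param de A `DEResult`.
#' @param k Number per direction (default 5).
#' @param fdr_max FDR stratum (default 0.05).
#' @return List with data frames `up` and `down` (possibly shorter than
#'   `k`).
#' @export
top_degs <- function(de, k = 5, fdr_max = 0.05) {
  strat <- de[de$fdr <= fdr_max, , drop = FALSE]
  ord_up <- order(-strat$log2FC, strat$fdr, strat$gene)
  ord_dn <- order(strat$log2FC, strat$fdr, strat$gene)
  up <- strat[ord_up, , drop = FALSE]
  up <- up[up$log2FC > 0, , drop = FALSE]
  dn <- strat[ord_dn, , drop = FALSE]
  dn <- dn[dn$log2FC < 0, , drop = FALSE]
  list(up = utils::head(up, k), down = utils::head(dn, k))
}

#' Write a DE table to TSV
#'
#' @param de A `DEResult`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
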