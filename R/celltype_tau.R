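# Cell-type specificity via the tau index computed from a reference
# expression matrix (cell types x genes).

#' Tau specificity score
#'
#' For expression `x` over `n >= 2` cell types,
#' `tau = sum(1 - x / max(x)) / (n - 1)`: 1 for expression confined to a
#' single cell type, 0 for perfectly uniform expression.
#'
#' @param expression_row Non-negative numeric vector over cell types.
#' @return Tau in `[0, 1]`, or `NA` (with warning) for an all-zero row.
#' @export
tau_score <- function(expression_row) {
  x <- as.numeric(expression_row)
  if (length(x) < 2) stop("need expression over at least two cell types")
  if (any(x < 0)) stop("negative expression")
  mx <- max(x)
  if (mx == 0) {
    warning("all-zero expression row; tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}

#' Assign genes to cell types by tau
#'
#' Each gene gets its tau score and argmax cell type; tiers follow the
#' study's thresholds: specific at `tau >= 0.8`, enriched at `tau >= 0.6`.
#' Genes whose maximum is tied across cell types are flagged ambiguous and
#' excluded from the specific/enriched tiers.
#'
#' @param ref Cell types x genes non-negative matrix with dimnames.
#' @param tau_specific,tau_enriched Tier thresholds (defaults 0.8, 0.6).
#' @return Data frame: gene, tau, cell_type (argmax, `NA` if all-zero),
#'   tier (`specific`/`enriched`/`none`), ambiguous.
#' @export
assign_celltypes <- function(ref, tau_specific = 0.8, tau_enriched = 0.6) {
  stopifnot(nrow(ref) >= 2, all(ref >= 0))
  genes <- colnames(ref)
  mx <- apply(ref, 2, max)
  n <- nrow(ref)
  tau <- ifelse(mx > 0, colSums(1 - sweep(ref, 2, pmax(mx, .Machine$double.xmin), "/")) / (n - 1),
                NA_real_)
  argmax <- rownames(ref)[apply(ref, 2, which.max)]
  argmax[mx == 0] <- NA_character_
  n_at_max <- colSums(sweep(ref, 2, mx, "==") & mx[col(ref)] > 0)
  ambiguous <- mx > 0 & n_at_max > 1
  tier <- rep("none", length(genes))
  tier[!ambiguous & !is.na(tau) & tau >= tau_enriched] <- "enriched"
  tier[!ambiguous & !is.na(tau) & tau >= tau_specific] <- "specific"
  if (any(mx == 0)) warning(sum(mx == 0), " all-zero gene(s); tau undefined")
  data.frame(gene = genes, tau = tau, cell_type = argmax,
             tier = tier, ambiguous = ambiguous,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pattern x cell-type count table
#'
#' Tabulates cell-type-specific genes (tier `specific`) within each
#' temporal pattern, stratified by direction; the dot-plot summary of how
#' the temporal response distributes over brain cell types.
#'
#' @param calls A `TemporalCall` data frame.
#' @param assignments Output of [assign_celltypes()].
#' @return Long data frame: pattern, cell_type, direction, n.
#' @export
pattern_celltype_table <- function(calls, assignments) {
  spec <- assignments[assignments$tier == "specific", c("gene", "cell_type")]
  merged <- merge(calls[calls$pattern %in% TEMPORAL_PATTERNS,
                        c("gene", "pattern", "direction")],
                  spec, by = "gene")
  cell_levels <- unique(assignments$cell_type[!is.na(assignments$cell_type)])
  tab <- as.data.frame(table(
    pattern = factor(merged$pattern, levels = TEMPORAL_PATTERNS),
    cell_type = factor(merged$cell_type, levels = cell_levels),
    direction = factor(merged$direction, levels = c("up", "down", "discordant"))),
    stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab
}
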