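# Dampened / accelerated classification of DEGs under treatment, from the
# sham-anchored comparisons A (1d vs sham), B (1wk vs sham), T (treated vs
# sham).

#' Classify treatment effects on DEGs
#'
#' * `dampened`: significant at 1 day post-injury but no longer
#'   significant in treated vs sham (the treatment normalized the gene),
#'   regardless of the 1-week status.
#' * `accelerated`: significant at 1 week and in treated vs sham with the
#'   same sign, but not at 1 day (the treated profile reached the 1-week
#'   state within 1 day).
#' * `unaffected`: significant nowhere.
#' * `other`: any remaining flag combination (reported with its triple).
#'
#' Direction comes from the anchoring comparison: A for dampened, B for
#' accelerated.
#'
#' @param de_A,de_B,de_T `DEResult` tables over one gene universe for
#'   1d-vs-sham, 1wk-vs-sham, treated-vs-sham.
#' @param p_max,lfc_min,fdr_mode DEG thresholds (see [call_degs()]).
#' @return A `TreatmentCall` data frame: gene, label, direction, sig_A,
#'   sig_B, sig_T, lfc_A, lfc_B, lfc_T.
#' @export
classify_treatment <- function(de_A, de_B, de_T,
                               p_max = 0.05, lfc_min = 1.0, fdr_mode = FALSE) {
  genes <- de_A$gene
  if (!identical(sort(genes), sort(de_B$gene)) ||
      !identical(sort(genes), sort(de_T$gene)))
    stop("the three DE results must share one gene universe")
  de_B <- de_B[match(genes, de_B$gene), ]
  de_T <- de_T[match(genes, de_T$gene), ]
  sig <- function(de) {
    pv <- if (fdr_mode) de$fdr else de$pvalue
    pv <= p_max & abs(de$log2FC) >= lfc_min
  }
  a <- sig(de_A); b <- sig(de_B); tt <- sig(de_T)
  same_bt <- sign(de_B$log2FC) == sign(de_T$log2FC)

  label <- treatment_truth_table(a, b, tt, same_bt)
  direction <- rep(NA_character_, length(genes))
  damp <- label == "dampened"
  acc <- label == "accelerated"
  direction[damp] <- ifelse(de_A$log2FC[damp] >= 0, "up", "down")
  direction[acc] <- ifelse(de_B$log2FC[acc] >= 0, "up", "down")

  out <- data.frame(gene = genes, label = label, direction = direction,
                    sig_A = a, sig_B = b, sig_T = tt,
                    lfc_A = de_A$log2FC, lfc_B = de_B$log2FC, lfc_T = de_T$log2FC,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("TreatmentCall", "data.frame")
  out
}

treatment_truth_table <- function(a, b, tt, same_bt) {
  label <- rep("other", length(a))
  label[!a & !b & !tt] <- "unaffected"
  label[a & !tt] <- "dampened"
  label[!a & b & tt & same_bt] <- "accelerated"
  label
}

#' Three-set Venn summary with treatment-effect annotation
#'
#' Cardinalities of the 7 regions of the Venn diagram over the DEG sets of
#' comparisons A (1d vs sham), B (1wk vs sham) and T (treated vs sham),
#' computed separately for up- and downregulated genes. Regions containing
#' dampened genes (A without T) and the accelerated region (B and T
#' without A) are annotated.
#'
#' @param deg_A,deg_B,deg_T DEG call tables from [call_degs()] (columns
#'   `gene`, `direction`).
#' @return Data frame: direction, region (e.g. `"A"`, `"A+B"`, `"B+T"`),
#'   n, annotation (`dampened`/`accelerated`/`""`).
#' @export
venn_summary <- function(deg_A, deg_B, deg_T) {
  regions <- c("A", "B", "T", "A+B", "A+T", "B+T", "A+B+T")
  annot <- c(A = "dampened", B = "", T = "", `A+B` = "dampened",
             `A+T` = "", `B+T` = "accelerated", `A+B+T` = "")
  out <- list()
  for (dir in c("up", "down")) {
    sa <- deg_A$gene[deg_A$direction == dir]
    sb <- deg_B$gene[deg_B$direction == dir]
    st <- deg_T$gene[deg_T$direction == dir]
    universe <- unique(c(sa, sb, st))
    key <- paste0(ifelse(universe %in% sa, "A", ""),
                  ifelse(universe %in% sb, "B", ""),
                  ifelse(universe %in% st, "T", ""))
    key <- vapply(strsplit(key, ""), paste, "", collapse = "+")
    n <- vapply(regions, function(r) sum(key == r), integer(1))
    out[[dir]] <- data.frame(direction = dir, region = regions, n = n,
                             annotation = unname(annot[regions]),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
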