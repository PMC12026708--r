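# Six-way temporal classification of DEGs from three two-group comparisons:
# A = 1 day vs sham, B = 1 week vs sham, C = 1 week vs 1 day.

#' Classify genes into temporal DE patterns
#'
#' Each gene's significance triple over the three comparisons maps to one
#' label:
#'
#' | A (1d vs sham) | B (1wk vs sham) | C (1wk vs 1d) | pattern      |
#' |---|---|---|--------------|
#' | T | F | F | Early        |
#' | T | F | T | Transient    |
#' | T | T | F | Persistent   |
#' | T | T | T | Intensified  |
#' | F | T | T | Delayed      |
#' | F | T | F | Late         |
#' | F | F | T | Unclassified |
#' | F | F | F | NotDE        |
#'
#' Direction is the shared sign of the significant sham-anchored
#' comparisons; `discordant` when A and B are both significant with
#' opposite signs.
#'
#' @param de_A,de_B,de_C `DEResult` tables over the same gene universe for
#'   the comparisons 1d-vs-sham, 1wk-vs-sham, 1wk-vs-1d.
#' @param p_max,lfc_min,fdr_mode DEG thresholds passed to [call_degs()].
#' @return A `TemporalCall` data frame: gene, pattern, direction, sig_A,
#'   sig_B, sig_C, lfc_A, lfc_B, lfc_C.
#' @export
classify_temporal <- function(de_A, de_B, de_C,
                              p_max = 0.05, lfc_min = 1.0, fdr_mode = FALSE) {
  genes <- de_A$gene
  if (!identical(sort(genes), sort(de_B$gene)) ||
      !identical(sort(genes), sort(de_C$gene)))
    stop("the three DE results must share one gene universe")
  de_B <- de_B[match(genes, de_B$gene), ]
  de_C <- de_C[match(genes, de_C$gene), ]

  sig <- function(de) {
    pv <- if (fdr_mode) de$fdr else de$pvalue
    pv <= p_max & abs(de$log2FC) >= lfc_min
  }
  a <- sig(de_A); b <- sig(de_B); c <- sig(de_C)

  pattern <- temporal_truth_table(a, b, c)
  direction <- rep(NA_character_, length(genes))
  direction[a & !b] <- ifelse(de_A$log2FC[a & !b] >= 0, "up", "down")
  direction[!a & b] <- ifelse(de_B$log2FC[!a & b] >= 0, "up", "down")
  both <- a & b
  same <- sign(de_A$log2FC) == sign(de_B$log2FC)
  direction[both & same] <- ifelse(de_A$log2FC[both & same] >= 0, "up", "down")
  direction[both & !same] <- "discordant"

  out <- data.frame(gene = genes, pattern = pattern, direction = direction,
                    sig_A = a, sig_B = b, sig_C = c,
                    lfc_A = de_A$log2FC, lfc_B = de_B$log2FC, lfc_C = de_C$log2FC,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("TemporalCall", "data.frame")
  out
}

temporal_truth_table <- function(a, b, c) {
  pattern <- rep("NotDE", length(a))
  pattern[a & !b & !c] <- "Early"
  pattern[a & !b & c] <- "Transient"
  pattern[a & b & !c] <- "Persistent"
  pattern[a & b & c] <- "Intensified"
  pattern[!a & b & c] <- "Delayed"
  pattern[!a & b & !c] <- "Late"
  pattern[!a & !b & c] <- "Unclassified"
  pattern
}

#' Check the temporal-pattern partition invariant
#'
#' The six named patterns must exactly partition the set of genes that are
#' significant in at least one sham-anchored comparison: summing the
#' pattern counts reproduces the total DEG count.
#'
#' @param calls A `TemporalCall` data frame.
#' @return List with `ok` (logical), `table` (pattern x direction counts),
#'   `n_sham_significant`, and `offenders` (gene ids violating the
#'   partition, empty when `ok`).
#' @export
partition_check <- function(calls) {
  sham_sig <- calls$sig_A | calls$sig_B
  named <- calls$pattern %in% TEMPORAL_PATTERNS
  offenders <- calls$gene[xor(sham_sig, named)]
  tab <- table(factor(calls$pattern[named], levels = TEMPORAL_PATTERNS),
               factor(calls$direction[named],
                      levels = c("up", "down", "discordant")))
  list(ok = length(offenders) == 0,
       table = as.matrix(tab),
       n_sham_significant = sum(sham_sig),
       offenders = offenders)
}

#' Intersection structure of DEG sets across strata
#'
#' Computes the exclusive (upset-style) regions of an arbitrary family of
#' DEG sets, e.g. one per (region, timepoint, direction) stratum: each
#' non-empty combination of memberships with its cardinality and members.
#'
#' @param sets Named list (length >= 2) of character vectors of gene ids.
#' @return Data frame: `combo` (`+`-joined stratum names), `degree`, `n`,
#'   and list column `members`; one row per non-empty exclusive region.
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least two strata")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "+"))
  split_members <- split(universe, key)
  out <- data.frame(combo = names(split_members),
                    degree = vapply(strsplit(names(split_members), "\\+"),
                                    length, integer(1)),
                    n = vapply(split_members, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$members <- unname(split_members)
  out[order(-out$degree, out$combo), ]
}
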