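# Gene-set overrepresentation: GMT I/O, one-sided Fisher/hypergeometric
# test against the post-filter universe, BH correction, fold enrichment,
# greedy collapsing of similar terms.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated line per set — name, description,
#' member gene ids. Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @return A `GeneSetCollection`: named list of character vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": need name, description and >= 1 member")
    name <- parts[1]
    if (name %in% names(sets)) stop("duplicate set name at line ", i, ": ", name)
    sets[[name]] <- unique(parts[-(1:2)])
    descriptions[name] <- parts[2]
  }
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#'
#' @param collection Named list of character vectors (descriptions taken
#'   from a `descriptions` attribute when present).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "NA"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher overrepresentation test
#'
#' One-sided (enrichment) hypergeometric tail per set, after intersecting
#' every set with the universe (the post-filter gene list); BH adjustment
#' across sets. Fold enrichment is `(k/m) / (K/N)` for overlap `k`, list
#' size `m`, set size `K`, universe size `N`.
#'
#' @param gene_list Character vector of hits (must lie in `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @return `ORAResult` data frame: set, k, K, m, N, fold_enrichment,
#'   pvalue, fdr, significant (fdr <= 0.05).
#' @export
fisher_ora <- function(gene_list, collection, universe) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("gene list members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  m <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(collection[[nm]], universe)
    K <- length(set_u)
    k <- length(intersect(set_u, gene_list))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    fe <- if (K == 0) NA_real_ else (k / m) / (K / N)
    data.frame(set = nm, k = k, K = K, m = m, N = N,
               fold_enrichment = fe, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
  res$significant <- res$fdr <= 0.05
  class(res) <- c("ORAResult", "data.frame")
  res
}

#' Collapse similar overrepresented terms
#'
#' Significant terms are greedily clustered: seeds are taken in decreasing
#' fold-enrichment order (ties: smaller FDR, then name), and any remaining
#' term whose universe-intersected member set has Jaccard similarity >=
#' `similarity_threshold` with the seed joins its cluster. Each cluster is
#' represented by its seed — the highest-fold-enrichment term.
#'
#' @param results An `ORAResult`.
#' @param collection The gene-set collection used for `results`.
#' @param universe The universe used for `results`.
#' @param similarity_threshold Jaccard threshold (default 0.5).
#' @param only_significant Collapse only `significant` terms (default
#'   `TRUE`).
#' @return The representative rows, with `cluster_members` (list column of
#'   collapsed set names).
#' @export
collapse_terms <- function(results, collection, universe,
                           similarity_threshold = 0.5,
                           only_significant = TRUE) {
  cand <- if (only_significant) results[results$significant, , drop = FALSE] else results
  if (!nrow(cand)) return(cbind(cand, cluster_members = I(list())))
  cand <- cand[order(-cand$fold_enrichment, cand$fdr, cand$set), , drop = FALSE]
  members <- lapply(cand$set, function(nm) intersect(collection[[nm]], universe))
  names(members) <- cand$set
  unassigned <- cand$set
  reps <- character(0)
  clusters <- list()
  while (length(unassigned)) {
    seed <- unassigned[1]
    sims <- vapply(unassigned, function(nm) jaccard(members[[seed]], members[[nm]]),
                   numeric(1))
    grp <- unassigned[sims >= similarity_threshold]
    grp <- union(seed, grp)
    reps <- c(reps, seed)
    clusters[[seed]] <- grp
    unassigned <- setdiff(unassigned, grp)
  }
  out <- cand[match(reps, cand$set), , drop = FALSE]
  out$cluster_members <- unname(clusters[reps])
  rownames(out) <- NULL
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
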