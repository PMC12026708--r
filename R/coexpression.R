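# Signed weighted co-expression network: biweight midcorrelation, soft
# thresholding, mean-denominator topological overlap, module detection by
# average-linkage clustering with fixed-height cuts, eigengene merging, kME
# reassignment, hub ranking, and eigengene group tests.

#' Network parameters
#'
#' Defaults follow the study's network settings: signed network, soft
#' power 12, bicor correlation, mean TOM denominator, minimum module size
#' 10, deepSplit 4, merge cut height 0.15, reassignment threshold 0.05.
#'
#' @param beta Soft-thresholding power (integer >= 1).
#' @param min_module_size Smallest allowed module.
#' @param merge_cut_height Eigengene dissimilarity (1 - cor) below which
#'   modules merge.
#' @param deep_split Detection sensitivity 0-4; mapped to a fixed tree-cut
#'   height of 0.99, 0.95, 0.90, 0.85, 0.80 on the 1 - TOM dendrogram.
#' @param reassign_threshold kME margin for moving a gene to a better
#'   module.
#' @return A `NetworkParams` list.
#' @export
network_params <- function(beta = 12, min_module_size = 10,
                           merge_cut_height = 0.15, deep_split = 4,
                           reassign_threshold = 0.05) {
  stopifnot(beta >= 1, min_module_size >= 1,
            merge_cut_height > 0, merge_cut_height < 1,
            deep_split %in% 0:4, reassign_threshold >= 0)
  structure(list(beta = beta, min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height, deep_split = deep_split,
                 reassign_threshold = reassign_threshold),
            class = "NetworkParams")
}

DEEP_SPLIT_HEIGHTS <- c(0.99, 0.95, 0.90, 0.85, 0.80)

# Biweight transform of each row of x: weighted deviations from the
# median with Tukey biweights at 9 MADs; rows with zero MAD fall back to
# Pearson (centered values) and are flagged via the "pearson_fallback"
# attribute.
bicor_prepare <- function(x) {
  med <- apply(x, 1, stats::median)
  dev <- x - med
  madv <- apply(abs(dev), 1, stats::median)
  fallback <- madv == 0
  u <- dev / (9 * pmax(madv, .Machine$double.eps))
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- dev * w
  if (any(fallback))
    a[fallback, ] <- x[fallback, , drop = FALSE] -
      rowMeans(x[fallback, , drop = FALSE])
  nrm <- sqrt(rowSums(a^2))
  zero <- nrm == 0
  a <- a / pmax(nrm, .Machine$double.eps)
  a[zero, ] <- 0
  attr(a, "pearson_fallback") <- fallback
  attr(a, "degenerate") <- zero
  a
}

#' Biweight midcorrelation matrix
#'
#' Outlier-robust correlation between all gene pairs (rows of `normexpr`),
#' using Tukey biweights with the standard 9-MAD tuning. Genes with zero
#' MAD fall back to Pearson and are flagged; constant genes get zero
#' correlation with everything.
#'
#' @param normexpr Genes x samples numeric matrix (>= 4 samples).
#' @return Symmetric correlation matrix in `[-1, 1]` with unit diagonal
#'   and attribute `pearson_fallback` (logical per gene).
#' @export
bicor_matrix <- function(normexpr) {
  if (ncol(normexpr) < 4) stop("bicor needs at least 4 samples")
  a <- bicor_prepare(as.matrix(normexpr))
  cc <- tcrossprod(a)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(normexpr), rownames(normexpr))
  attr(cc, "pearson_fallback") <- attr(a, "pearson_fallback")
  cc
}

# bicor between rows of x and rows of y (same samples), e.g. genes vs
# module eigengenes.
bicor_cross <- function(x, y) {
  ax <- bicor_prepare(as.matrix(x))
  ay <- bicor_prepare(as.matrix(y))
  cc <- tcrossprod(ax, ay)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  dimnames(cc) <- list(rownames(x), rownames(y))
  cc
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, preserving sign information by
#' mapping perfect anticorrelation to 0; diagonal fixed at 1.
#'
#' @param cor Correlation matrix in `[-1, 1]`.
#' @param beta Soft power (default 12).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor, beta = 12) {
  if (any(cor < -1 - 1e-8) || any(cor > 1 + 1e-8))
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix (mean denominator)
#'
#' `tom_ij = (l_ij + a_ij) / ((k_i + k_j)/2 - a_ij + 1)` with shared
#' neighbourhood `l_ij = sum_u a_iu a_uj` (u != i, j) and connectivity
#' `k_i = sum_u a_iu` (u != i); `tom_ii = 1`. The clustering dissimilarity
#' is `1 - tom`.
#'
#' @param adj Symmetric adjacency with unit diagonal, entries in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(adj < 0) || any(adj > 1 + 1e-12)) stop("adjacency entries must be in [0, 1]")
  A <- unname(adj)
  L <- A %*% A - 2 * A          # removes the u = i and u = j terms (diag = 1)
  k <- rowSums(A) - 1
  denom <- outer(k, k, "+") / 2 - A + 1
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# First principal component of the standardized module expression, sign
# oriented so that it correlates positively with the module's mean
# standardized profile; scaled to unit variance.
module_eigengene <- function(normexpr, genes) {
  x <- normexpr[genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0
  sv <- svd(xs, nu = 0, nv = 1)
  me <- sv$v[, 1]
  profile <- colMeans(xs)
  if (sum(me * profile) < 0) me <- -me
  if (stats::sd(me) > 0) me <- as.numeric(scale(me))
  names(me) <- colnames(normexpr)
  me
}

#' Detect co-expression modules
#'
#' Builds the signed bicor/TOM network, clusters genes by average-linkage
#' hierarchical clustering of `1 - TOM`, cuts the tree at a fixed height
#' determined by `deep_split`, sends branches smaller than
#' `min_module_size` to module 0 (unassigned), computes module eigengenes,
#' iteratively merges modules whose eigengene dissimilarity is below
#' `merge_cut_height`, and finally moves genes whose kME in another module
#' exceeds their own-module kME by at least `reassign_threshold`.
#'
#' @param normexpr Genes x samples matrix (a `NormalizedExperiment`'s
#'   `normexpr`, or any expression matrix).
#' @param params A [network_params()].
#' @return A `ModuleSet`: list with `modules` (named integer vector, 0 =
#'   unassigned), `eigengenes` (modules x samples, unit variance),
#'   `kme` (genes x modules), `hubs` (per-module genes ranked by kME),
#'   `params`.
#' @export
detect_modules <- function(normexpr, params = network_params()) {
  normexpr <- as.matrix(normexpr)
  genes <- rownames(normexpr)
  if (is.null(genes)) stop("normexpr must have gene row names")
  if (nrow(normexpr) < params$min_module_size) {
    warning("fewer genes than min_module_size; empty module set")
    return(empty_module_set(genes, colnames(normexpr), params))
  }
  cc <- bicor_matrix(normexpr)
  adj <- signed_adjacency(cc, params$beta)
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- DEEP_SPLIT_HEIGHTS[params$deep_split + 1]
  cl <- stats::cutree(hc, h = h)

  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  labels <- ifelse(cl %in% as.integer(keep), cl, 0L)
  names(labels) <- genes
  labels <- relabel_by_size(labels)
  if (all(labels == 0)) {
    warning("no branch reached min_module_size; all genes unassigned")
    return(empty_module_set(genes, colnames(normexpr), params))
  }

  labels <- merge_modules(normexpr, labels, params$merge_cut_height)
  labels <- reassign_genes(normexpr, labels, params$reassign_threshold,
                           params$min_module_size)
  labels <- merge_modules(normexpr, labels, params$merge_cut_height)
  labels <- relabel_by_size(labels)

  mes <- eigengene_matrix(normexpr, labels)
  kme <- bicor_cross(normexpr, mes)
  hubs <- hub_table(labels, kme)
  structure(list(modules = labels, eigengenes = mes, kme = kme,
                 hubs = hubs, params = params),
            class = "ModuleSet")
}

empty_module_set <- function(genes, samples, params) {
  labels <- stats::setNames(rep(0L, length(genes)), genes)
  structure(list(modules = labels,
                 eigengenes = matrix(0, 0, length(samples),
                                     dimnames = list(NULL, samples)),
                 kme = matrix(0, length(genes), 0, dimnames = list(genes, NULL)),
                 hubs = data.frame(module = integer(0), gene = character(0),
                                   kme = numeric(0), rank = integer(0)),
                 params = params),
            class = "ModuleSet")
}

relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  new
}

eigengene_matrix <- function(normexpr, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  mes <- t(vapply(mods,
                  function(m) module_eigengene(normexpr, names(labels)[labels == m]),
                  numeric(ncol(normexpr))))
  rownames(mes) <- paste0("ME", mods)
  colnames(mes) <- colnames(normexpr)
  mes
}

# Iteratively merge the closest eigengene pair while 1 - cor(ME_a, ME_b)
# is below the cut height; idempotent once no pair qualifies.
merge_modules <- function(normexpr, labels, merge_cut_height) {
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2) return(labels)
    mes <- eigengene_matrix(normexpr, labels)
    cm <- stats::cor(t(mes))
    diag(cm) <- -Inf
    i <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (1 - cm[i[1], i[2]] >= merge_cut_height) return(labels)
    m_keep <- mods[min(i)]
    m_drop <- mods[max(i)]
    labels[labels == m_drop] <- m_keep
  }
}

reassign_genes <- function(normexpr, labels, threshold, min_module_size) {
  mods <- sort(setdiff(unique(labels), 0L))
  if (length(mods) < 2) return(labels)
  mes <- eigengene_matrix(normexpr, labels)
  kme <- bicor_cross(normexpr, mes)
  assigned <- labels != 0
  own <- kme[cbind(which(assigned), match(paste0("ME", labels[assigned]),
                                          colnames(kme)))]
  best_idx <- apply(kme[assigned, , drop = FALSE], 1, which.max)
  best <- mods[best_idx]
  best_kme <- kme[cbind(which(assigned), best_idx)]
  move <- best != labels[assigned] & (best_kme - own) >= threshold
  labels[which(assigned)[move]] <- best[move]
  # a module emptied below min size by reassignment dissolves to grey
  for (m in mods) if (sum(labels == m) < min_module_size) labels[labels == m] <- 0L
  labels
}

hub_table <- function(labels, kme) {
  mods <- sort(setdiff(unique(labels), 0L))
  rows <- lapply(mods, function(m) {
    g <- names(labels)[labels == m]
    k <- kme[g, paste0("ME", m)]
    ord <- order(-k, g)
    data.frame(module = m, gene = g[ord], kme = k[ord],
               rank = seq_along(g), stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(module = integer(0), gene = character(0),
                      kme = numeric(0), rank = integer(0)))
  do.call(rbind, rows)
}

#' Top hub genes per module
#'
#' @param moduleset A `ModuleSet`.
#' @param k Hubs per module (default 5, the study's reporting choice).
#' @return Data frame: module, gene, kme, rank.
#' @export
hub_genes <- function(moduleset, k = 5) {
  h <- moduleset$hubs
  h[h$rank <= k, , drop = FALSE]
}

#' Pairwise group tests on module eigengene scores
#'
#' For every module, two-sided Wilcoxon rank-sum tests on the eigengene
#' scores for each pair of groups, Bonferroni-adjusted over the pairs
#' within the module (see [wilcoxon_bonferroni()]).
#'
#' @param moduleset A `ModuleSet`.
#' @param sample_table Data frame with `sample` and `group` covering the
#'   eigengene score columns.
#' @return Long data frame: module plus the [wilcoxon_bonferroni()]
#'   columns.
#' @export
module_group_test <- function(moduleset, sample_table) {
  mes <- moduleset$eigengenes
  if (!nrow(mes)) stop("empty module set")
  groups <- sample_table$group[match(colnames(mes), sample_table$sample)]
  if (anyNA(groups)) stop("eigengene samples missing from sample_table")
  rows <- lapply(rownames(mes), function(me) {
    tab <- wilcoxon_bonferroni(mes[me, ], groups)
    cbind(module = as.integer(sub("^ME", "", me)), tab)
  })
  do.call(rbind, rows)
}

#' Classify modules as treatment-dampened or -accelerated
#'
#' Eigengene-level analogue of the gene classification: a module is
#' `accelerated` when the treated group differs from sham (adjusted p <=
#' `p_max`) in the same direction as 1 week differs from sham while 1 day
#' does not differ from sham; `dampened` when 1 day differs from sham but
#' the treated group does not, and the treated group differs from 1 day.
#'
#' @param test_table Output of [module_group_test()] for the four groups.
#' @param p_max Threshold on the Bonferroni-adjusted p (default 0.05).
#' @return Data frame: module, label (`dampened`/`accelerated`/`other`).
#' @export
classify_module_treatment <- function(test_table, p_max = 0.05) {
  need <- c("sham", "injured_1d", "injured_1wk", "treated_1d")
  present <- unique(c(test_table$group1, test_table$group2))
  if (!all(need %in% present))
    stop("missing group(s): ", paste(setdiff(need, present), collapse = ", "))
  lookup <- function(tab, g1, g2) {
    r <- tab[(tab$group1 == g1 & tab$group2 == g2) |
             (tab$group1 == g2 & tab$group2 == g1), ][1, ]
    # orient median_diff as g2 - g1
    d <- if (r$group1 == g1) r$median_diff else -r$median_diff
    list(p = r$p_adjusted, diff = d)
  }
  mods <- unique(test_table$module)
  label <- vapply(mods, function(m) {
    tab <- test_table[test_table$module == m, ]
    d1 <- lookup(tab, "sham", "injured_1d")
    wk <- lookup(tab, "sham", "injured_1wk")
    tr <- lookup(tab, "sham", "treated_1d")
    tr_d1 <- lookup(tab, "injured_1d", "treated_1d")
    if (!anyNA(c(tr$p, wk$p, d1$p)) &&
        tr$p <= p_max && wk$p <= p_max && d1$p > p_max &&
        sign(tr$diff) == sign(wk$diff)) return("accelerated")
    if (!anyNA(c(d1$p, tr$p, tr_d1$p)) &&
        d1$p <= p_max && tr$p > p_max && tr_d1$p <= p_max) return("dampened")
    "other"
  }, character(1))
  data.frame(module = mods, label = label, stringsAsFactors = FALSE)
}
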