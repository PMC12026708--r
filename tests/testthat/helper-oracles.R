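# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Each oracle is written from the definition, not from the
# package's code path.

# Benjamini-Hochberg step-up, from the definition.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper hypergeometric tail P(X >= k) by direct summation with choose().
hyper_tail_oracle <- function(k, K, m, N) {
  hi <- min(K, m)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, m - i)) / choose(N, m)
}

# Exact two-sided rank-sum p by full enumeration of which ranks go to y.
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[(nx + 1):(nx + ny)]) - ny * (ny + 1) / 2
  combos <- utils::combn(nx + ny, ny)
  allranks <- seq_len(nx + ny)
  us <- apply(combos, 2, function(idx) sum(allranks[idx]) - ny * (ny + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Topological overlap (mean denominator) by triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / ((ki + kj) / 2 - a[i, j] + 1)
  }
  tom
}

# Biweight midcorrelation of two vectors from the published formula.
bicor_pair_oracle <- function(x, y) {
  wts <- function(v) {
    med <- median(v)
    u <- (v - med) / (9 * median(abs(v - med)))
    (v - med) * (1 - u^2)^2 * (abs(u) < 1)
  }
  ax <- wts(x); ay <- wts(y)
  sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))
}

# Independently coded temporal truth table (nested conditionals).
temporal_oracle <- function(a, b, c) {
  if (a && !b && !c) "Early"
  else if (a && !b && c) "Transient"
  else if (a && b && !c) "Persistent"
  else if (a && b && c) "Intensified"
  else if (!a && b && c) "Delayed"
  else if (!a && b && !c) "Late"
  else if (!a && !b && c) "Unclassified"
  else "NotDE"
}

# Independently coded treatment labels.
treatment_oracle <- function(a, b, tt, same_bt) {
  if (a && !tt) "dampened"
  else if (!a && b && tt && same_bt) "accelerated"
  else if (!a && !b && !tt) "unaffected"
  else "other"
}

# Minimal DE table with chosen per-gene log2FC and p (fdr = p).
fake_de <- function(genes, lfc, p) {
  structure(data.frame(gene = genes, base_mean = 100, log2FC = lfc,
                       se = 1, stat = lfc, pvalue = p, fdr = p,
                       dispersion = 0.1, stringsAsFactors = FALSE),
            class = c("DEResult", "data.frame"))
}

# A tiny valid CountExperiment.
toy_experiment <- function(counts = NULL, groups = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(2, 4, 8, 4, 8, 16, 3, 6, 12, 5, 10, 20), nrow = 3,
                     dimnames = list(c("g1", "g2", "g3"),
                                     c("s1", "s2", "s3", "s4")))
  }
  if (is.null(groups)) groups <- rep(c("sham", "injured_1d"), each = ncol(counts) / 2)
  st <- data.frame(sample = colnames(counts), group = groups, region = "FC",
                   subject = paste0("p", seq_len(ncol(counts))),
                   stringsAsFactors = FALSE)
  count_experiment(counts, st)
}

# Gaussian expression with planted correlated blocks (for network tests).
planted_block_expr <- function(block_sizes, loading, n_noise, n_samples,
                               shifts_by_block = NULL, groups = NULL) {
  n_blocks <- length(block_sizes)
  z <- matrix(rnorm(n_samples * n_blocks), n_samples, n_blocks)
  if (!is.null(shifts_by_block)) z <- z + shifts_by_block
  rows <- list()
  truth <- integer(0)
  for (b in seq_len(n_blocks)) {
    m <- block_sizes[b]
    rows[[b]] <- t(sapply(seq_len(m), function(i)
      loading * z[, b] + sqrt(1 - loading^2) * rnorm(n_samples)))
    truth <- c(truth, rep(b, m))
  }
  x <- rbind(do.call(rbind, rows), matrix(rnorm(n_noise * n_samples),
                                          n_noise, n_samples))
  truth <- c(truth, rep(0L, n_noise))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(expr = x, truth = truth)
}
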