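test_that("bicor has unit diagonal, handles antithetic vectors, matches the formula", {
  x <- rbind(inc = 1:10, dec = 10:1, rnd = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  colnames(x) <- paste0("s", 1:10)
  cc <- bicor_matrix(x)
  expect_equal(diag(cc), c(inc = 1, dec = 1, rnd = 1))
  expect_equal(cc["inc", "dec"], -1)
  set.seed(80)
  y <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:30)))
  cy <- bicor_matrix(y)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(cy[i, j], bicor_pair_oracle(y[i, ], y[j, ]), tolerance = 1e-8)
  expect_true(isSymmetric(unname(cy)))
  expect_true(all(cy >= -1 & cy <= 1))
  expect_error(bicor_matrix(y[, 1:3]), "4 samples")
})

test_that("zero-MAD genes fall back to Pearson and are flagged", {
  x <- rbind(spiky1 = c(rep(0, 9), 5),    # MAD 0, but not constant
             spiky2 = c(rep(2, 9), 9),
             lin = 1:10)
  colnames(x) <- paste0("s", 1:10)
  cc <- bicor_matrix(x)
  expect_true(attr(cc, "pearson_fallback")["spiky1"])
  expect_true(attr(cc, "pearson_fallback")["spiky2"])
  expect_false(attr(cc, "pearson_fallback")["lin"])
  # between two fallback genes the result is plain Pearson
  expect_equal(cc["spiky1", "spiky2"], cor(x["spiky1", ], x["spiky2", ]),
               tolerance = 1e-8)
})

test_that("signed adjacency has its closed-form values", {
  cc <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  a <- signed_adjacency(cc, beta = 12)
  expect_equal(diag(a), rep(1, 3))
  expect_equal(a[1, 3], 0)                       # cor = -1
  expect_equal(a[1, 2], 2^-12)                   # cor = 0
  expect_equal(a[2, 3], 0.75^12)                 # cor = 0.5
  one <- signed_adjacency(matrix(1, 2, 2), beta = 7)
  expect_equal(one, matrix(1, 2, 2))
})

test_that("TOM matches hand and brute-force computation", {
  # 2-gene network: no shared neighbours, tom = adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.3)
  # binary adjacency, genes 1 and 2 fully connected with identical
  # neighbourhoods: perfect overlap, tom = 1
  a3 <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0), c(1, 1, 1, 0), c(0, 0, 0, 1))
  expect_equal(tom_similarity(a3)[1, 2], 1)
  set.seed(81)
  for (rep in 1:5) {
    r <- matrix(runif(400), 20, 20)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-10)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(diag(tom), rep(1, 20))
  }
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("planted blocks are recovered as modules", {
  set.seed(82)
  pb <- planted_block_expr(c(15, 15, 15), loading = 0.9, n_noise = 30,
                           n_samples = 40)
  ms <- detect_modules(pb$expr, network_params())
  expect_gte(mclust::adjustedRandIndex(pb$truth, ms$modules), 0.8)
  # eigengenes are unit variance and sign-oriented
  expect_equal(unname(apply(ms$eigengenes, 1, sd)),
               rep(1, nrow(ms$eigengenes)))
  for (m in setdiff(unique(ms$modules), 0L)) {
    genes <- names(ms$modules)[ms$modules == m]
    prof <- colMeans(t(scale(t(pb$expr[genes, , drop = FALSE]))))
    expect_gte(cor(ms$eigengenes[paste0("ME", m), ], prof), 0)
  }
  # kME within [-1, 1]; own-module hubs lead the ranking
  expect_true(all(ms$kme >= -1 & ms$kme <= 1))
  hubs <- hub_genes(ms, k = 3)
  expect_true(all(table(hubs$module) <= 3))
})

test_that("duplicated-block halves merge and merging is idempotent", {
  set.seed(83)
  n <- 40
  z <- rnorm(n)
  mk <- function(m) t(sapply(seq_len(m), function(i)
    0.9 * z + sqrt(1 - 0.81) * rnorm(n)))
  x <- rbind(mk(15), mk(15), matrix(rnorm(30 * n), 30, n))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n))
  ms <- detect_modules(x, network_params())
  # the two identical halves share one latent factor -> one module
  expect_equal(length(setdiff(unique(ms$modules[1:30]), 0L)), 1)
  merged <- tempodeg:::merge_modules(x, ms$modules, 0.15)
  expect_identical(merged, ms$modules)
})

test_that("pure noise stays almost entirely unassigned", {
  set.seed(84)
  x <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:40)))
  ms <- suppressWarnings(detect_modules(x, network_params()))
  expect_gte(mean(ms$modules == 0), 0.9)
})

test_that("module labels are invariant to gene order", {
  set.seed(85)
  pb <- planted_block_expr(c(12, 12), loading = 0.9, n_noise = 16,
                           n_samples = 30)
  ms1 <- detect_modules(pb$expr, network_params())
  perm <- sample(nrow(pb$expr))
  ms2 <- detect_modules(pb$expr[perm, ], network_params())
  m2 <- ms2$modules[names(ms1$modules)]
  expect_equal(mclust::adjustedRandIndex(ms1$modules, m2), 1)
})

test_that("eigengene group tests reproduce the exact rank-sum example", {
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  st <- data.frame(sample = paste0("s", 1:12),
                   group = rep(c("sham", "injured_1d", "injured_1wk", "treated_1d"),
                               each = 3))
  ms <- structure(list(eigengenes = matrix(scores, 1, 12,
                                           dimnames = list("ME1", st$sample))),
                  class = "ModuleSet")
  tab <- module_group_test(ms, st)
  r <- tab[tab$group1 == "sham" & tab$group2 == "injured_1d", ]
  expect_equal(r$pvalue, 0.1)            # (1,2,3) vs (4,5,6) exact
  expect_equal(r$p_adjusted, min(1, 0.1 * 6))  # Bonferroni over 6 pairs
})

test_that("module treatment classification follows the eigengene logic", {
  # synthetic tests table: module 1 accelerated, module 2 dampened, 3 null
  mk <- function(mod, p_d1, p_wk, p_tr, p_trd1, d_d1, d_wk, d_tr) {
    data.frame(module = mod,
               group1 = c("sham", "sham", "sham", "injured_1d",
                          "injured_1d", "injured_1wk"),
               group2 = c("injured_1d", "injured_1wk", "treated_1d",
                          "injured_1wk", "treated_1d", "treated_1d"),
               n1 = 8, n2 = 8,
               median_diff = c(d_d1, d_wk, d_tr, 0, 0, 0),
               W = 1, pvalue = 1,
               p_adjusted = c(p_d1, p_wk, p_tr, 1, p_trd1, 1),
               exact = TRUE, skipped = FALSE)
  }
  tab <- rbind(mk(1, 0.9, 0.01, 0.01, 0.01, 0.1, 2, 2),
               mk(2, 0.01, 0.5, 0.9, 0.01, 2, 0.2, 0.1),
               mk(3, 0.9, 0.9, 0.9, 0.9, 0, 0, 0))
  lab <- classify_module_treatment(tab)
  expect_equal(lab$label, c("accelerated", "dampened", "other"))
  # same-direction requirement for accelerated
  tab_flip <- mk(1, 0.9, 0.01, 0.01, 0.01, 0.1, 2, -2)
  expect_equal(classify_module_treatment(tab_flip)$label, "other")
  expect_error(classify_module_treatment(tab[tab$group2 != "treated_1d", ]),
               "missing group")
})
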