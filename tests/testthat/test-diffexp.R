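test_that("dispersion estimates recover Poisson and NB regimes", {
  set.seed(30)
  g <- rep(c("A", "B"), each = 500)
  s <- rep(1, 1000)
  pois <- rpois(1000, 80)
  expect_lt(estimate_dispersion(pois, s, g), 0.01)
  nb <- rnbinom(1000, mu = 80, size = 1 / 0.5)
  a <- estimate_dispersion(nb, s, g)
  expect_gt(a, 0.4); expect_lt(a, 0.6)
  expect_equal(estimate_dispersion(rep(7, 1000), s, g), 1e-8)
  expect_warning(a0 <- estimate_dispersion(rep(0, 1000), s, g), "zero mean")
  expect_equal(a0, 1e-8)
})

test_that("identical groups give zero log2FC and p = 1", {
  counts <- cbind(s1 = c(5, 50), s2 = c(9, 40), s3 = c(5, 50), s4 = c(9, 40))
  rownames(counts) <- c("g1", "g2")
  exp <- toy_experiment(counts, groups = c("sham", "sham", "injured_1d", "injured_1d"))
  de <- wald_test(exp, rep(1, 4), c("sham", "injured_1d"))
  expect_equal(de$log2FC, c(0, 0))
  expect_equal(de$pvalue, c(1, 1))
})

test_that("swapping the comparison negates log2FC and preserves p exactly", {
  set.seed(31)
  counts <- matrix(rnbinom(200, mu = 100, size = 5), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  exp <- toy_experiment(counts)
  s <- size_factors(exp)
  d1 <- wald_test(exp, s, c("sham", "injured_1d"))
  d2 <- wald_test(exp, s, c("injured_1d", "sham"))
  expect_equal(d1$log2FC, -d2$log2FC)
  expect_equal(d1$pvalue, d2$pvalue)
  expect_equal(d1$stat, d1$log2FC / d1$se, tolerance = 1e-10)
})

test_that("planted fold changes are recovered at moderate n", {
  spec <- simulation_spec(
    n_genes = 200, samples_per_group = c(sham = 8, injured_1d = 8),
    dispersion = 0.05,
    planted_temporal = data.frame(pattern = "Persistent", direction = "up",
                                  count = 20, lfc = 2),
    planted_treatment = NULL, celltype_specific_per_type = 0, seed = 32)
  sim <- simulate_counts(spec)
  de <- wald_test(sim$experiment, size_factors(sim$experiment),
                  c("sham", "injured_1d"))
  planted <- de$log2FC[match(sim$truth$gene[sim$truth$pattern == "Persistent"],
                             de$gene)]
  expect_gt(mean(planted > 1.5 & planted < 2.5), 0.9)
})

test_that("DEG calling applies inclusive thresholds exactly", {
  de <- fake_de(paste0("g", 1:6),
                lfc = c(1.0, 0.9, -1.2, 2.0, -3.0, 1.5),
                p = c(0.05, 0.01, 0.04, 0.9, 0.050001, 0.002))
  calls <- call_degs(de)
  # brute-force filter
  expected <- de$gene[de$pvalue <= 0.05 & abs(de$log2FC) >= 1]
  expect_setequal(calls$gene, expected)
  expect_true("g1" %in% calls$gene)        # boundary case p = 0.05, lfc = 1
  expect_false("g2" %in% calls$gene)       # |lfc| below threshold
  expect_false("g5" %in% calls$gene)       # p above threshold
  expect_equal(calls$direction[calls$gene == "g3"], "down")
  # FDR mode switches the significance column
  de$fdr <- rep(1, 6)
  expect_equal(nrow(call_degs(de, fdr_mode = TRUE)), 0)
})

test_that("top_degs ranks by log2FC within the FDR stratum with documented ties", {
  de <- fake_de(paste0("g", 1:10),
                lfc = c(3, 3, 2.5, 1, -4, -4, -2, 0.5, 5, -5),
                p = c(0.001, 0.001, 0.01, 0.2, 0.001, 0.001, 0.01, 0.001, 0.2, 0.2))
  de$fdr <- c(0.01, 0.02, 0.03, 0.2, 0.02, 0.01, 0.03, 0.01, 0.2, 0.2)
  top <- top_degs(de, k = 2)
  # g9 has the largest lfc but fails the FDR stratum; g1/g2 tie on lfc,
  # smaller fdr wins
  expect_equal(top$up$gene, c("g1", "g2"))
  expect_equal(top$down$gene, c("g6", "g5"))
  # short stratum returns fewer than k
  top5 <- top_degs(de, k = 5)
  expect_equal(nrow(top5$up), 4)   # g1 g2 g3 g8 (positive lfc, fdr <= .05)
  # sort-and-slice oracle
  strat <- de[de$fdr <= 0.05 & de$log2FC > 0, ]
  oracle_up <- strat$gene[order(-strat$log2FC, strat$fdr, strat$gene)][1:4]
  expect_equal(top5$up$gene, oracle_up)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(50)^(1 + i %% 3)
    expect_lt(max(abs(p.adjust(p, "BH") - bh_stepup_oracle(p))), 1e-12)
  }
  # fdr column of wald_test output is BH over the tested genes
  exp <- toy_experiment()
  s <- size_factors(exp)
  d <- wald_test(exp, s, c("sham", "injured_1d"))
  expect_equal(d$fdr, bh_stepup_oracle(d$pvalue))
})

test_that("detection power is monotone in the planted effect size", {
  rates <- vapply(c(0.5, 1, 2), function(delta) {
    spec <- simulation_spec(
      n_genes = 300, samples_per_group = c(sham = 8, injured_1d = 8),
      planted_temporal = data.frame(pattern = "Persistent", direction = "up",
                                    count = 60, lfc = delta),
      planted_treatment = NULL, celltype_specific_per_type = 0, seed = 34)
    sim <- simulate_counts(spec)
    de <- wald_test(sim$experiment, size_factors(sim$experiment),
                    c("sham", "injured_1d"))
    planted <- sim$truth$pattern == "Persistent"
    mean(de$pvalue[match(sim$truth$gene[planted], de$gene)] <= 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
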