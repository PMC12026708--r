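test_that("simulation is bit-identical under a fixed seed", {
  spec <- simulation_spec(n_genes = 200, seed = 42,
                          planted_temporal = default_planted_temporal(genes_per_pattern = 2),
                          planted_treatment = NULL,
                          celltype_specific_per_type = 2)
  s1 <- simulate_counts(spec)
  s2 <- simulate_counts(spec)
  expect_identical(s1$experiment$counts, s2$experiment$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$celltype_reference, s2$celltype_reference)
})

test_that("no planted effects gives an all-null truth table", {
  spec <- simulation_spec(n_genes = 100, planted_temporal = NULL,
                          planted_treatment = NULL,
                          celltype_specific_per_type = 0, seed = 1)
  sim <- simulate_counts(spec)
  expect_true(all(sim$truth$pattern == "null"))
  expect_true(all(sim$truth$treatment == "none"))
  expect_true(all(sim$truth$module == 0))
})

test_that("planted bookkeeping: every planted gene appears once with its label", {
  spec <- simulation_spec(
    n_genes = 300,
    planted_temporal = default_planted_temporal(genes_per_pattern = 3),
    planted_treatment = default_planted_treatment(genes_per_label = 4),
    planted_modules = list(list(size = 12, loading = 0.8, shifts = c())),
    celltype_specific_per_type = 5, seed = 3)
  sim <- simulate_counts(spec)
  expect_equal(nrow(sim$truth), 300)
  expect_false(anyDuplicated(sim$truth$gene) > 0)
  # 6 patterns x 2 directions x 3 genes planted directly
  tv <- sim$truth$treatment == "none" & sim$truth$module == 0
  expect_equal(sum(sim$truth$pattern != "null" & tv), 36)
  expect_equal(sum(sim$truth$treatment == "dampened"), 8)
  expect_equal(sum(sim$truth$treatment == "accelerated"), 8)
  expect_equal(sum(sim$truth$module == 1), 12)
  expect_equal(as.integer(table(sim$truth$cell_type)[c("astrocyte", "neuron")]),
               c(5L, 5L))
})

test_that("a planted Persistent gene shows the requested fold change", {
  spec <- simulation_spec(
    n_genes = 50,
    samples_per_group = c(sham = 200, injured_1d = 200),
    planted_temporal = data.frame(pattern = "Persistent", direction = "up",
                                  count = 1, lfc = 2),
    planted_treatment = NULL, celltype_specific_per_type = 0,
    library_size_sigma = 0, seed = 9)
  sim <- simulate_counts(spec)
  g <- sim$truth$gene[sim$truth$pattern == "Persistent"]
  grp <- sim$experiment$sample_table$group
  m_sham <- mean(sim$experiment$counts[g, grp == "sham"])
  m_inj <- mean(sim$experiment$counts[g, grp == "injured_1d"])
  expect_gt(m_inj / m_sham, 3.6)
  expect_lt(m_inj / m_sham, 4.4)
})

test_that("near-Poisson counts with equal depths give near-constant totals", {
  spec <- simulation_spec(n_genes = 5000,
                          samples_per_group = c(sham = 4, injured_1d = 4),
                          planted_temporal = NULL, planted_treatment = NULL,
                          celltype_specific_per_type = 0,
                          dispersion = 1e-6, library_size_sigma = 0, seed = 2)
  sim <- simulate_counts(spec)
  totals <- colSums(sim$experiment$counts)
  expect_lt(max(abs(totals / mean(totals) - 1)), 0.02)
})

test_that("empirical NB moments match the mean-dispersion parameterization", {
  spec <- simulation_spec(n_genes = 30,
                          samples_per_group = c(sham = 1000),
                          planted_temporal = NULL, planted_treatment = NULL,
                          celltype_specific_per_type = 0,
                          baseline_log_mean_sigma = 0.3,
                          dispersion = 0.5, library_size_sigma = 0, seed = 8)
  sim <- simulate_counts(spec)
  mu <- rowMeans(sim$experiment$counts)
  v <- apply(sim$experiment$counts, 1, var)
  expected <- mu + 0.5 * mu^2
  expect_true(all(v / expected > 0.7 & v / expected < 1.4))
})

test_that("overfull or invalid specs are rejected", {
  expect_error(simulation_spec(n_genes = 10), "exceed")
  expect_error(simulation_spec(n_genes = 100, dispersion = 0), "positive")
  expect_error(simulation_spec(
    n_genes = 100, planted_treatment = NULL, celltype_specific_per_type = 0,
    planted_temporal = data.frame(pattern = "Early", direction = "up",
                                  count = 1, lfc = 0)), "nonzero")
  expect_error(simulation_spec(n_genes = 100,
                               samples_per_group = c(foo = 3)), "samples_per_group")
})

test_that("write_simulation round-trips counts and metadata", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(n_genes = 40, planted_temporal = NULL,
                          planted_treatment = NULL,
                          celltype_specific_per_type = 0, seed = 4)
  sim <- simulate_counts(spec)
  write_simulation(sim, dir, mtx = TRUE)
  back <- read_counts(file.path(dir, "counts.tsv"), file.path(dir, "metadata.tsv"))
  expect_equal(back$counts, sim$experiment$counts)
  back_mtx <- read_counts(file.path(dir, "counts.mtx"), file.path(dir, "metadata.tsv"))
  expect_equal(back_mtx$counts, sim$experiment$counts)
  expect_true(file.exists(file.path(dir, "spec.yaml")))
})
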