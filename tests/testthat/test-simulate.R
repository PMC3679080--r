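test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_genes = 10, seed = 101)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$intensities$values, s2$intensities$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(simulation_config(n_genes = 10, seed = 102))
  expect_false(identical(s1$intensities$values, s3$intensities$values))
})

test_that("mapping recovers the generator's own probe assignment", {
  cfg <- simulation_config(n_genes = 15, seed = 33)
  sim <- simulate_experiment(cfg)
  res <- map_probes(sim$probes, sim$models)
  expect_equal(nrow(res$excluded), 0L)  # no border probes by default
  truth <- sim$truth$probes
  got <- res$mapped[match(truth$probe_id, res$mapped$probe_id), ]
  expect_equal(got$gene_id, truth$true_gene)
  expect_equal(got$segment_kind, truth$true_kind)
  expect_equal(got$segment_index, truth$true_index)
})

test_that("planted retention shifts the intron probes by the effect size", {
  ev <- data.frame(gene = 2, intron = 1, type = "retention",
                   condition = "treatment", effect = 3)
  cfg <- simulation_config(n_genes = 5, planted_events = ev,
                           noise_sd = 0.25, seed = 12)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth$probes
  sel <- !is.na(truth$true_gene) & truth$true_gene == "G0002" &
    truth$true_kind == "intron" & truth$true_index == 1L
  v <- log2(sim$intensities$values[truth$probe_id[sel], , drop = FALSE])
  is_t <- sim$intensities$samples$condition == "treatment"
  gap <- mean(v[, is_t]) - mean(v[, !is_t])
  # expectation 3, sd of the estimate ~ 0.25/sqrt(4*n_probes)
  expect_equal(gap, 3, tolerance = 0.2)

  # an unplanted intron stays flat
  sel0 <- !is.na(truth$true_gene) & truth$true_gene == "G0001" &
    truth$true_kind == "intron"
  v0 <- log2(sim$intensities$values[truth$probe_id[sel0], , drop = FALSE])
  expect_equal(mean(v0[, is_t]) - mean(v0[, !is_t]), 0, tolerance = 0.2)
})

test_that("partial events shift only the affected half of the intron", {
  ev <- data.frame(gene = 1, intron = 1, type = "partial_5prime",
                   condition = "treatment", effect = 3)
  cfg <- simulation_config(n_genes = 2, exons_per_gene = c(3, 3),
                           intron_length = c(280, 300), noise_sd = 0.05,
                           planted_events = ev, seed = 9)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth$probes
  sel <- which(!is.na(truth$true_gene) & truth$true_gene == "G0001" &
                 truth$true_kind == "intron" & truth$true_index == 1L)
  v <- log2(sim$intensities$values[truth$probe_id[sel], , drop = FALSE])
  is_t <- sim$intensities$samples$condition == "treatment"
  gaps <- rowMeans(v[, is_t]) - rowMeans(v[, !is_t])
  n_up <- sum(gaps > 1.5)
  expect_equal(n_up, ceiling(length(sel) / 2))
  expect_true(any(gaps < 0.5))  # the other half stays at background
})

test_that("events on single-exon genes are rejected", {
  ev <- data.frame(gene = 1, intron = 1, type = "retention",
                   condition = "treatment", effect = 2)
  cfg <- simulation_config(n_genes = 3, exons_per_gene = c(1, 1),
                           planted_events = ev, seed = 2)
  expect_error(simulate_experiment(cfg), "single-exon")
})

test_that("the exclusion funnel matches the injected probe counts", {
  cfg <- simulation_config(n_genes = 12, border_probe_fraction = 1,
                           n_intergenic_probes = 11, n_control_probes = 6,
                           n_multimap_probes = 4, seed = 77)
  sim <- simulate_experiment(cfg)
  res <- map_probes(sim$probes, sim$models)
  truth <- sim$truth$probes
  rep <- setNames(res$report$n, res$report$category)
  expect_equal(rep[["border"]], sum(truth$true_kind == "border"))
  expect_equal(rep[["intergenic"]], sum(truth$true_kind == "intergenic"))
  expect_equal(rep[["control"]], sum(truth$true_kind == "control"))
  expect_equal(rep[["multi_location"]], sum(truth$true_kind == "multimap"))
  expect_equal(rep[["retained"]],
               sum(truth$true_kind %in% c("exon", "intron")))
  expect_equal(sum(rep), nrow(sim$probes))
})

test_that("a null simulation detects (almost) nothing downstream", {
  cfg <- simulation_config(n_genes = 40, seed = 20130611)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth$events), 0L)
  run <- run_splicing_pipeline(sim$models, sim$probes, sim$intensities)
  expect_lte(sum(run$intron_results$significant), 2)
  expect_lte(sum(run$gene_table$responsive), 1)
})
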