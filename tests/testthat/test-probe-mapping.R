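test_that("probes map to the segment that fully contains them", {
  m <- tiny_models()
  probes <- rbind(
    probe_row("in_exon1", 120),      # inside GA exon 1
    probe_row("in_intron2", 430),    # inside GA intron 2 (401-500)
    probe_row("minus_intron", 1150)  # inside GB intron 1 (1101-1300)
  )
  res <- map_probes(probes, m)
  expect_equal(nrow(res$excluded), 0L)
  got <- res$mapped[match(probes$probe_id, res$mapped$probe_id), ]
  expect_equal(got$gene_id, c("GA", "GA", "GB"))
  expect_equal(got$segment_kind, c("exon", "intron", "intron"))
  expect_equal(got$segment_index, c(1L, 2L, 1L))
})

test_that("exclusion reasons cover every discard rule", {
  m <- tiny_models()
  probes <- rbind(
    probe_row("border", 190),          # spans GA exon1/intron1 boundary
    probe_row("intergenic", 700),      # between the genes
    probe_row("ctrl", 120, control = TRUE),
    probe_row("dup", 120), probe_row("dup", 320),  # one id, two loci
    probe_row("short", 120, len = 20)  # malformed length
  )
  expect_warning(res <- map_probes(probes, m), "malformed")
  reasons <- setNames(res$excluded$reason, res$excluded$probe_id)
  expect_equal(unname(reasons["border"]), "border")
  expect_equal(unname(reasons["intergenic"]), "intergenic")
  expect_equal(unname(reasons["ctrl"]), "control")
  expect_equal(unname(reasons[names(reasons) == "dup"]),
               rep("multi_location", 2))
  expect_equal(unname(reasons["short"]), "malformed")
  expect_equal(nrow(res$mapped), 0L)
})

test_that("a probe inside segments of two overlapping genes is excluded", {
  tab <- rbind(tiny_exon_table(),
               data.frame(gene_id = "GC", transcript_id = "GC.1",
                          chromosome = "chr1", strand = "+",
                          start = c(380, 550), end = c(420, 650),
                          stringsAsFactors = FALSE))
  m <- select_base_transcript(tab)
  # probe at 430-454 sits in GA intron 2 and in GC's intron (421-549)
  res <- map_probes(probe_row("shared", 430), m)
  expect_equal(res$excluded$reason, "multi_location")
  # the brute-force scan agrees that >1 gene contains it
  bf <- brute_force_assignments(probe_row("shared", 430), m)
  expect_gt(bf[1, "n_genes"], 1)
})

test_that("retained + excluded partition the input and match a linear scan", {
  cfg <- simulation_config(n_genes = 12, border_probe_fraction = 0.5,
                           n_intergenic_probes = 9, n_control_probes = 4,
                           seed = 5)
  sim <- simulate_experiment(cfg)
  res <- map_probes(sim$probes, sim$models)
  expect_equal(nrow(res$mapped) + nrow(res$excluded), nrow(sim$probes))
  expect_equal(length(intersect(res$mapped$probe_id,
                                res$excluded$probe_id)), 0L)

  bf <- brute_force_assignments(sim$probes, sim$models)
  is_ctrl <- sim$probes$is_control
  expect_setequal(res$mapped$probe_id,
                  sim$probes$probe_id[bf[, "n_genes"] == 1 & !is_ctrl])
  # every retained probe is fully inside its reported segment
  seg <- sim$models$segments
  for (i in seq_len(nrow(res$mapped))) {
    p <- res$mapped[i, ]
    s <- seg[seg$gene_id == p$gene_id & seg$kind == p$segment_kind &
               seg$index == p$segment_index, ]
    expect_true(s$start <= p$start && s$end >= p$end)
  }
})

test_that("per-gene probe counts equal an independent tally", {
  cfg <- simulation_config(n_genes = 10, seed = 3)
  sim <- simulate_experiment(cfg)
  res <- map_probes(sim$probes, sim$models)
  counts <- probe_counts_per_gene(res, sim$models)
  for (g in counts$gene_id) {
    sel <- res$mapped$gene_id == g
    expect_equal(counts$n_probes[counts$gene_id == g], sum(sel))
    expect_equal(counts$n_intron_probes[counts$gene_id == g],
                 sum(sel & res$mapped$segment_kind == "intron"))
  }
  # a model gene with no probes is reported with zeros
  m2 <- sim$models
  m2$genes <- rbind(m2$genes, within(m2$genes[1, ], {
    gene_id <- "GHOST"; tx_start <- 1e6; tx_end <- 1e6 + 99
  }))
  c2 <- probe_counts_per_gene(res, m2)
  expect_equal(c2[c2$gene_id == "GHOST", c("n_probes", "n_intron_probes")],
               data.frame(n_probes = 0L, n_intron_probes = 0L),
               ignore_attr = TRUE)
})

test_that("stranded mapping restricts probes to same-strand genes", {
  m <- tiny_models()  # GA is +, GB is -
  p <- rbind(probe_row("pa", 120), probe_row("pb", 1150))
  res <- map_probes(p, m, stranded = TRUE)
  expect_equal(res$mapped$probe_id, "pa")
  expect_equal(res$excluded$probe_id, "pb")
})
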