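# One gene, hand-built: 6 exon probes and an intron with `k` probes.
splice_fixture <- function(intron_mu_trt, intron_mu_ctrl = 6,
                           exon_mu = 10, noise_sd = 0.25, n_rep = 4,
                           seed = 20130611, gene = "G1") {
  k <- length(intron_mu_trt)
  map <- data.frame(
    probe_id = paste0(gene, "_p", seq_len(6 + k)),
    chromosome = "chr1", start = seq_len(6 + k) * 100,
    end = seq_len(6 + k) * 100 + 24, strand = "+", gene_id = gene,
    segment_kind = c(rep("exon", 6), rep("intron", k)),
    segment_index = c(1:6, rep(1L, k)), stringsAsFactors = FALSE)
  mu <- mu_matrix(control = c(rep(exon_mu, 6), rep(intron_mu_ctrl, k)),
                  treatment = c(rep(exon_mu, 6), intron_mu_trt),
                  ids = map$probe_id)
  m <- log2_transform(sim_matrix(mu, noise_sd, n_rep, seed))
  list(map = map, m = m)
}

test_that("gating thresholds are the documented medians", {
  fx <- splice_fixture(rep(6, 4))
  thr <- gating_thresholds(fx$m, fx$map)
  rows <- match(fx$map$probe_id, rownames(fx$m$values))
  expect_equal(thr$exon_expression_threshold,
               median(fx$m$values[rows[fx$map$segment_kind == "exon"], ]))
  expect_equal(thr$intron_background_threshold,
               median(fx$m$values[rows, ]))
  expect_true(is.finite(thr$exon_mode))
})

test_that("the gene gate applies all four rules", {
  mk <- function(gene, n_exon, n_intron, exon_mu, intron_mu_c,
                 intron_mu_t = intron_mu_c) {
    n <- n_exon + n_intron
    data.frame(probe_id = paste0(gene, "_p", seq_len(n)),
               chromosome = "chr1", start = seq_len(n), end = seq_len(n) + 24,
               strand = "+", gene_id = gene,
               segment_kind = c(rep("exon", n_exon), rep("intron", n_intron)),
               segment_index = c(seq_len(n_exon), rep(1L, n_intron)),
               mu_c = c(rep(exon_mu, n_exon), rep(intron_mu_c, n_intron)),
               mu_t = c(rep(exon_mu, n_exon), rep(intron_mu_t, n_intron)),
               stringsAsFactors = FALSE)
  }
  map <- rbind(mk("GHI", 7, 2, 10, 5),      # 9 probes, expressed, introns low
               mk("G8", 6, 2, 10, 5),       # only 8 probes -> ineligible
               mk("GLO", 7, 2, 6, 5),       # exons at background -> ineligible
               mk("GIN", 7, 2, 10, 10),     # introns high in both -> ineligible
               mk("GCOND", 7, 2, 10, 5, 10))  # introns low in control only
  mu <- mu_matrix(map$mu_c, map$mu_t, ids = map$probe_id)
  m <- log2_transform(sim_matrix(mu, noise_sd = 0.1, seed = 4))
  map <- map[, 1:8]
  ge <- gene_expression(m, map)
  # fixed thresholds between the planted levels isolate the gate logic
  thr <- structure(list(exon_expression_threshold = 8,
                        intron_background_threshold = 8,
                        exon_mode = NA_real_),
                   class = "gating_thresholds")
  gate <- gate_genes(m, map, ge, thresholds = thr)
  expect_setequal(gate$eligible, c("GHI", "GCOND"))
})

test_that("the gate equals a brute-force re-filter on a synthetic cohort", {
  cfg <- simulation_config(n_genes = 40, exon_level_sd = 1.5, seed = 66)
  sim <- simulate_experiment(cfg)
  map <- map_probes(sim$probes, sim$models)
  m <- preprocess_intensities(sim$intensities)
  ge <- gene_expression(m, map)
  gate <- gate_genes(m, map, ge)
  thr <- gate$thresholds

  counts <- probe_counts_per_gene(map)
  manual <- character(0)
  for (g in intersect(counts$gene_id, rownames(ge$exon))) {
    if (counts$n_probes[counts$gene_id == g] < 9) next
    if (counts$n_intron_probes[counts$gene_id == g] < 1) next
    for (cond in c("control", "treatment")) {
      sel <- m$samples$condition == cond
      if (mean(ge$exon[g, sel]) > thr$exon_expression_threshold &&
            mean(ge$intron[g, sel]) < thr$intron_background_threshold) {
        manual <- union(manual, g)
      }
    }
  }
  expect_setequal(gate$eligible, manual)
})

test_that("probe-level tests obey the complement rule and the t reference", {
  # identical replicate sets: symmetric null
  mu <- mu_matrix(rep(7, 3), rep(7, 3))
  m <- log2_transform(sim_matrix(mu, noise_sd = 0))
  pt0 <- probe_level_tests(m)
  expect_equal(pt0$p_up, rep(0.5, 3))
  expect_equal(pt0$p_down, rep(0.5, 3))

  # strong direction
  mu2 <- mu_matrix(c(2, 8), c(8, 2))
  m2 <- log2_transform(sim_matrix(mu2, noise_sd = 0))
  pt2 <- probe_level_tests(m2)
  expect_lt(pt2$p_up[1], 1e-6)
  expect_gt(pt2$p_down[1], 1 - 1e-6)
  expect_gt(pt2$p_up[2], 1 - 1e-6)

  # random draws match the t CDF computed independently
  set.seed(31)
  mu3 <- mu_matrix(rnorm(20, 8, 1), rnorm(20, 8, 1))
  m3 <- log2_transform(sim_matrix(mu3, noise_sd = 0.5, seed = 32))
  pt3 <- probe_level_tests(m3)
  expect_equal(pt3$p_up + pt3$p_down, rep(1, 20))
  is_c <- m3$samples$condition == "control"
  for (i in c(1, 7, 20)) {
    x <- m3$values[i, is_c]; y <- m3$values[i, !is_c]
    sp2 <- (3 * var(x) + 3 * var(y)) / 6
    tstat <- (mean(y) - mean(x)) / sqrt(sp2 / 2)
    expect_equal(pt3$p_up[i], pt(tstat, 6, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("fisher_combine matches the chi-square oracle", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.2), 0.2)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  expect_warning(p0 <- fisher_combine(c(0.5, 0)), "floored")
  expect_gt(p0, 0)
  expect_error(fisher_combine(c(0.5, 1.2)), "in \\(0, 1\\]")

  oracle <- function(p) {
    x2 <- -2 * sum(log(p))
    # chi-square upper tail by numerical integration, not pchisq
    stats::integrate(function(u) stats::dchisq(u, df = 2 * length(p)),
                     lower = x2, upper = Inf, rel.tol = 1e-12)$value
  }
  set.seed(77)
  for (k in 1:10) {
    p <- runif(k, min = 0.001, max = 1)
    expect_equal(fisher_combine(p), oracle(p), tolerance = 1e-10)
    # appending p = 1 raises the df; the oracle tracks the change
    expect_equal(fisher_combine(c(p, 1)), oracle(c(p, 1)),
                 tolerance = 1e-10)
  }
})

test_that("a planted retained intron is found with the right calls", {
  fx <- splice_fixture(intron_mu_trt = rep(9, 4))  # +3 log2 in treatment
  res <- intron_test(fx$m, fx$map, genes = "G1")
  expect_equal(nrow(res), 1L)
  expect_true(res$significant)
  expect_equal(res$direction, "higher_in_treatment")
  expect_equal(res$presence, "treatment")
  expect_equal(res$splice_type, "retained")
  expect_equal(res$intron_p, min(res$combined_p_up, res$combined_p_down))
})

test_that("a partial event is significant but of unknown type", {
  fx <- splice_fixture(intron_mu_trt = c(9, 9, 6, 6))  # 5' half only
  res <- intron_test(fx$m, fx$map, genes = "G1")
  expect_true(res$significant)
  expect_equal(res$splice_type, "unknown")
})

test_that("splice-type classification follows the all-probes rule", {
  expect_equal(classify_splice_type(c(0.01, 0.02, 0.04, 0.049)), "retained")
  expect_equal(classify_splice_type(c(0.01, 0.02, 0.04, 0.3)), "unknown")
  expect_equal(classify_splice_type(numeric(0)), "unknown")
})

test_that("a null screen yields (almost) no significant introns", {
  set.seed(20130611)
  n_introns <- 500
  maps <- lapply(seq_len(n_introns), function(i) {
    g <- sprintf("N%04d", i)
    data.frame(probe_id = paste0(g, "_p", 1:4), chromosome = "chr1",
               start = 1:4, end = 25:28, strand = "+", gene_id = g,
               segment_kind = "intron", segment_index = 1L,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  mu <- mu_matrix(rep(6, nrow(map)), rep(6, nrow(map)), ids = map$probe_id)
  m <- log2_transform(sim_matrix(mu, noise_sd = 0.25, seed = 20130611))
  res <- intron_test(m, map, genes = unique(map$gene_id))
  expect_equal(nrow(res), n_introns)
  expect_lte(sum(res$significant), 2)
})

test_that("introns with zero probes are skipped silently", {
  fx <- splice_fixture(rep(9, 3))
  # gene G1 has introns 1..5 in principle; only intron 1 carries probes
  res <- intron_test(fx$m, fx$map, genes = "G1")
  expect_equal(res$intron_index, 1L)
})
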