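# Small fixtures built in code, shared across test files.

# A two-gene annotation on one chromosome:
#   GA (+): exons 101-200, 301-400, 501-600  -> introns 201-300, 401-500
#   GB (-): exons 1001-1100, 1301-1400       -> intron  1101-1300
tiny_exon_table <- function() {
  data.frame(
    gene_id = c(rep("GA", 3), rep("GB", 2)),
    transcript_id = c(rep("GA.1", 3), rep("GB.1", 2)),
    chromosome = "chr1",
    strand = c(rep("+", 3), rep("-", 2)),
    start = c(101, 301, 501, 1001, 1301),
    end = c(200, 400, 600, 1100, 1400),
    stringsAsFactors = FALSE
  )
}

tiny_models <- function() select_base_transcript(tiny_exon_table())

# A probe table with one probe per interesting case against tiny_models().
probe_row <- function(id, start, control = FALSE, chrom = "chr1",
                      len = 25L) {
  data.frame(probe_id = id, chromosome = chrom, start = start,
             end = start + len - 1L, strand = "+", is_control = control,
             stringsAsFactors = FALSE)
}

# An intensity matrix with named probes and a 4 vs 4 design; values are
# log2 means + Normal noise, exponentiated to the linear scale.
sim_matrix <- function(mu, noise_sd = 0, n_rep = 4, seed = 1) {
  set.seed(seed)
  conds <- rep(c("control", "treatment"), each = n_rep)
  v <- sapply(seq_along(conds), function(j) {
    2^(mu[, conds[j]] + rnorm(nrow(mu), 0, noise_sd))
  })
  rownames(v) <- rownames(mu)
  colnames(v) <- paste0(conds, "_", rep(seq_len(n_rep), 2))
  intensity_matrix(v, condition = conds)
}

# Two-column mean matrix (control, treatment) with probe ids.
mu_matrix <- function(control, treatment, ids = NULL) {
  m <- cbind(control = control, treatment = treatment)
  rownames(m) <- ids %||% paste0("p", seq_len(nrow(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force containment scan: for each probe, loop over all
# segments and count full containments, ignoring any interval machinery.
brute_force_assignments <- function(probes, models) {
  seg <- models$segments
  t(vapply(seq_len(nrow(probes)), function(i) {
    hits <- which(seg$chromosome == probes$chromosome[i] &
                    seg$start <= probes$start[i] &
                    seg$end >= probes$end[i])
    genes <- unique(seg$gene_id[hits])
    touches <- sum(seg$chromosome == probes$chromosome[i] &
                     seg$start <= probes$end[i] &
                     seg$end >= probes$start[i])
    c(n_within = length(hits), n_genes = length(genes),
      n_touch = touches)
  }, c(n_within = 0, n_genes = 0, n_touch = 0)))
}

# Brute-force Benjamini-Hochberg step-up.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# Explicit sort/average/unsort quantile normalization (no ties expected).
quantile_reference <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[, j] <- ref[rank(x[, j])]
  out
}
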