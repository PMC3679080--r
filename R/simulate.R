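#' Configuration for a synthetic tiling-array experiment
#'
#' Defaults mirror the experimental design the package targets: 25-mer
#' probes tiled at an average 35 bp resolution, four biological replicates
#' per condition, and log-normal intensity noise (Normal on the log2 scale,
#' sd 0.25). Exonic probes sit at a high expression level and intronic
#' probes at background, so that planted events are the only structured
#' differences between conditions.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (lo, hi) of exon counts per gene.
#' @param exon_length,intron_length bp ranges for segment lengths.
#' @param intergenic_length bp gap between consecutive genes.
#' @param probe_spacing tiling step in bp (default 35).
#' @param probe_length probe length in nt (default 25).
#' @param n_replicates replicate arrays per condition (default 4).
#' @param exon_level,intron_level mean log2 intensity of exonic/intronic
#'   probes (defaults 10 and 6).
#' @param exon_level_sd gene-to-gene sd of the baseline exon level
#'   (default 0: all genes share the level).
#' @param noise_sd replicate noise sd on the log2 scale (default 0.25).
#' @param planted_events `NULL` or data frame with columns `gene` (gene id
#'   or 1-based gene index), `intron` (1-based transcript-order index, or
#'   `NA` to pick one at random), `type`
#'   (`"retention"`/`"partial_5prime"`/`"partial_3prime"`), `condition`
#'   (`"treatment"`/`"control"`), `effect` (log2 shift).
#' @param de_genes `NULL` or data frame with columns `gene`, `log2_shift`:
#'   all exon probes of the gene are shifted in the treatment condition.
#' @param border_probe_fraction fraction of boundary-crossing tiling probes
#'   to emit anyway (default 0; raise to exercise the border exclusion).
#' @param n_intergenic_probes,n_control_probes extra probes placed between
#'   genes / flagged as controls (default 0).
#' @param n_multimap_probes probes emitted at two genomic positions under
#'   one id (default 0).
#' @param seed random seed recorded in all outputs (default 20130611).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 60,
                              exons_per_gene = c(3, 8),
                              exon_length = c(100, 300),
                              intron_length = c(150, 300),
                              intergenic_length = 500,
                              probe_spacing = 35,
                              probe_length = 25,
                              n_replicates = 4,
                              exon_level = 10,
                              intron_level = 6,
                              exon_level_sd = 0,
                              noise_sd = 0.25,
                              planted_events = NULL,
                              de_genes = NULL,
                              border_probe_fraction = 0,
                              n_intergenic_probes = 0,
                              n_control_probes = 0,
                              n_multimap_probes = 0,
                              seed = 20130611) {
  stopifnot(probe_spacing > 0, probe_length > 0, n_replicates >= 2,
            noise_sd >= 0, n_genes >= 1,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1)
  if (!is.null(planted_events)) {
    planted_events <- as.data.frame(planted_events)
    stopifnot(all(c("gene", "intron", "type", "condition", "effect") %in%
                    names(planted_events)))
    if (!all(planted_events$type %in%
               c("retention", "partial_5prime", "partial_3prime", "none"))) {
      stop("unknown planted event type")
    }
    if (!all(is.finite(planted_events$effect))) stop("non-finite effect size")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a complete two-condition tiling-array experiment
#'
#' Generates a genome annotation (genes with one transcript each), tiles
#' probes across every gene at the configured spacing, assigns each probe
#' its true segment, and draws raw linear intensities for
#' `2 * n_replicates` arrays. Planted intron-retention events raise all
#' probes of the target intron by the effect size in the target condition;
#' partial (alternative 5'/3') events raise only the probes in the affected
#' half of the intron; differentially expressed genes shift all their exon
#' probes. Probes that would cross a segment boundary are dropped unless
#' `border_probe_fraction > 0`.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `splice_simulation`: `config`, `models`
#'   (a `gene_models`), `exon_table` (the annotation as a data frame),
#'   `probes` (probe coordinate table), `intensities` (raw
#'   `intensity_matrix`), and `truth` with `probes` (true assignment of
#'   every probe), `events` (resolved planted events) and `de_genes`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  # --- gene structures ------------------------------------------------
  n <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  exon_rows <- vector("list", n)
  cursor <- cfg$intergenic_length + 1
  strands <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n)) {
    n_ex <- .sample_range(cfg$exons_per_gene, 1L)
    ex_len <- .sample_range(cfg$exon_length, n_ex)
    in_len <- if (n_ex > 1L) .sample_range(cfg$intron_length, n_ex - 1L)
              else integer(0)
    starts <- ends <- integer(n_ex)
    pos <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
    }
    exon_rows[[i]] <- data.frame(
      gene_id = gene_ids[i],
      transcript_id = paste0(gene_ids[i], ".1"),
      chromosome = "chr1", strand = strands[i],
      start = starts, end = ends, stringsAsFactors = FALSE
    )
    cursor <- ends[n_ex] + cfg$intergenic_length + 1L
  }
  exon_table <- do.call(rbind, exon_rows)
  models <- select_base_transcript(exon_table)

  # --- resolve planted events and DE genes ----------------------------
  events <- .resolve_events(cfg$planted_events, models)
  de <- NULL
  if (!is.null(cfg$de_genes)) {
    de <- as.data.frame(cfg$de_genes)
    de$gene_id <- .resolve_gene(de$gene, models)
    de <- de[, c("gene_id", "log2_shift")]
  }

  # --- tile probes ----------------------------------------------------
  seg <- models$segments
  probe_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- models$genes[i, ]
    pos <- seq(g$tx_start, g$tx_end - cfg$probe_length + 1L,
               by = cfg$probe_spacing)
    if (length(pos) == 0L) next
    s <- seg[seg$gene_id == g$gene_id, , drop = FALSE]
    hit <- vapply(pos, function(p) {
      j <- which(s$start <= p & s$end >= p + cfg$probe_length - 1L)
      if (length(j) == 1L) j else NA_integer_
    }, integer(1))
    keep_border <- is.na(hit) &
      stats::runif(length(pos)) < cfg$border_probe_fraction
    keep <- !is.na(hit) | keep_border
    probe_rows[[i]] <- data.frame(
      chromosome = "chr1",
      start = pos[keep],
      end = pos[keep] + cfg$probe_length - 1L,
      strand = "+",
      is_control = FALSE,
      true_gene = g$gene_id,
      true_kind = ifelse(is.na(hit[keep]), "border", s$kind[hit[keep]]),
      true_index = ifelse(is.na(hit[keep]), NA_integer_, s$index[hit[keep]]),
      stringsAsFactors = FALSE
    )
  }
  probes <- do.call(rbind, probe_rows)

  # --- extra probes exercising the exclusion rules --------------------
  gaps_start <- c(1L, models$genes$tx_end + 1L)
  gaps_end <- c(models$genes$tx_start - 1L,
                models$genes$tx_end[n] + cfg$intergenic_length)
  extra <- function(k, is_control) {
    if (k == 0L) return(NULL)
    gi <- rep(seq_along(gaps_start), length.out = k)
    off <- 2L * (seq_len(k) %% 10L)  # stagger within the gap
    start <- gaps_start[gi] + 10L + off
    data.frame(chromosome = "chr1", start = start,
               end = start + cfg$probe_length - 1L, strand = "+",
               is_control = is_control, true_gene = NA_character_,
               true_kind = if (is_control) "control" else "intergenic",
               true_index = NA_integer_, stringsAsFactors = FALSE)
  }
  probes <- rbind(probes, extra(cfg$n_intergenic_probes, FALSE),
                  extra(cfg$n_control_probes, TRUE))
  probes$probe_id <- sprintf("P%06d", seq_len(nrow(probes)))

  if (cfg$n_multimap_probes > 0L) {
    src <- utils::head(which(probes$true_kind == "exon"),
                       cfg$n_multimap_probes)
    if (length(src) < cfg$n_multimap_probes) {
      stop("not enough exon probes to duplicate as multi-mapping")
    }
    dup <- extra(length(src), FALSE)
    dup$start <- dup$start + 7L  # avoid colliding with injected intergenics
    dup$end <- dup$start + cfg$probe_length - 1L
    dup$probe_id <- probes$probe_id[src]
    dup$true_kind <- "multimap"
    probes$true_kind[src] <- "multimap"
    probes <- rbind(probes, dup)
  }

  # --- intensity means ------------------------------------------------
  base_level <- stats::setNames(
    stats::rnorm(n, cfg$exon_level, cfg$exon_level_sd), gene_ids)
  mu <- matrix(cfg$intron_level, nrow = nrow(probes), ncol = 2,
               dimnames = list(probes$probe_id, c("control", "treatment")))
  is_exonish <- probes$true_kind %in% c("exon", "multimap") &
    !is.na(probes$true_gene)
  mu[is_exonish, ] <- base_level[probes$true_gene[is_exonish]]

  if (!is.null(de)) {
    for (r in seq_len(nrow(de))) {
      sel <- is_exonish & probes$true_gene == de$gene_id[r]
      mu[sel, "treatment"] <- mu[sel, "treatment"] + de$log2_shift[r]
    }
  }
  if (!is.null(events) && nrow(events)) {
    for (r in seq_len(nrow(events))) {
      ev <- events[r, ]
      if (ev$type == "none") next
      sel <- which(!is.na(probes$true_gene) &
                     probes$true_gene == ev$gene_id &
                     probes$true_kind == "intron" &
                     probes$true_index == ev$intron_index)
      if (length(sel) == 0L) next
      strand <- models$genes$strand[models$genes$gene_id == ev$gene_id]
      ord <- order(probes$start[sel])
      if (strand == "-") ord <- rev(ord)  # 5' end of a minus-strand intron
      affected <- switch(ev$type,
        retention = sel,
        partial_5prime = sel[ord][seq_len(ceiling(length(sel) / 2))],
        partial_3prime = sel[rev(ord)][seq_len(ceiling(length(sel) / 2))]
      )
      mu[affected, ev$condition] <- mu[affected, ev$condition] + ev$effect
    }
  }

  # --- draw arrays ----------------------------------------------------
  nr <- cfg$n_replicates
  conds <- rep(c("control", "treatment"), each = nr)
  arr_ids <- paste0(conds, "_", rep(seq_len(nr), 2))
  vals <- matrix(0, nrow = nrow(probes), ncol = 2 * nr,
                 dimnames = list(probes$probe_id, arr_ids))
  for (j in seq_len(2 * nr)) {
    vals[, j] <- 2^(mu[, conds[j]] +
                      stats::rnorm(nrow(probes), 0, cfg$noise_sd))
  }
  m <- intensity_matrix(vals, condition = conds, state = "raw")

  structure(list(
    config = cfg,
    models = models,
    exon_table = exon_table,
    probes = probes[, c("probe_id", "chromosome", "start", "end", "strand",
                        "is_control")],
    intensities = m,
    truth = list(
      probes = probes[, c("probe_id", "true_gene", "true_kind",
                          "true_index")],
      events = events,
      de_genes = de
    )
  ), class = "splice_simulation")
}

# sample() treats a scalar first argument as 1:x; guard degenerate ranges
.sample_range <- function(range, k) {
  if (range[1] == range[2]) rep(as.integer(range[1]), k)
  else sample(seq(range[1], range[2]), k, replace = TRUE)
}

.resolve_gene <- function(gene, models) {
  ids <- models$genes$gene_id
  out <- ifelse(gene %in% ids, as.character(gene),
                ids[suppressWarnings(as.integer(gene))])
  if (anyNA(out)) stop("unknown gene reference in config: ",
                       paste(gene[is.na(out)], collapse = ", "))
  out
}

.resolve_events <- function(ev, models) {
  if (is.null(ev) || nrow(as.data.frame(ev)) == 0L) {
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      type = character(0), condition = character(0),
                      effect = numeric(0)))
  }
  ev <- as.data.frame(ev)
  gene_id <- .resolve_gene(ev$gene, models)
  n_intr <- models$genes$n_introns[match(gene_id, models$genes$gene_id)]
  if (any(n_intr == 0L)) {
    stop("planted event on single-exon gene(s): ",
         paste(unique(gene_id[n_intr == 0L]), collapse = ", "))
  }
  intron <- ev$intron
  pick <- is.na(intron)
  intron[pick] <- vapply(n_intr[pick], function(k) sample.int(k, 1L),
                         integer(1))
  if (any(intron > n_intr | intron < 1L)) {
    stop("planted event references intron index beyond the gene's introns")
  }
  data.frame(gene_id = gene_id, intron_index = as.integer(intron),
             type = ev$type, condition = ev$condition, effect = ev$effect,
             stringsAsFactors = FALSE)
}

#' @export
print.splice_simulation <- function(x, ...) {
  cat("splice_simulation:", nrow(x$models$genes), "genes,",
      nrow(x$probes), "probes,", ncol(x$intensities$values), "arrays,",
      nrow(x$truth$events), "planted events (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits `annotation.gff3`, `probes.tsv`, `intensities.tsv` +
#' `arrays.tsv`, and the truth tables `truth_probes.tsv`,
#' `truth_events.tsv`, `truth_de_genes.tsv`.
#'
#' @param sim a `splice_simulation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "splice_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- sim$exon_table
  g <- sim$models$genes

  mk <- function(type, start, end, strand, id, parent) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                 strand = strand)
    gr$type <- type
    gr$ID <- id
    gr$Parent <- IRanges::CharacterList(
      lapply(parent, function(p) if (is.na(p)) character(0) else p))
    gr
  }
  gff <- c(
    mk("gene", g$tx_start, g$tx_end, g$strand, g$gene_id,
       rep(NA_character_, nrow(g))),
    mk("mRNA", g$tx_start, g$tx_end, g$strand, g$transcript_id, g$gene_id),
    mk("exon", ex$start, ex$end, ex$strand,
       paste0(ex$transcript_id, ".exon", stats::ave(ex$start,
                                                    ex$transcript_id,
                                                    FUN = seq_along)),
       ex$transcript_id)
  )
  rtracklayer::export(gff, file.path(dir, "annotation.gff3"), format = "gff3")

  utils::write.table(sim$probes, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_intensity_matrix(sim$intensities, file.path(dir, "intensities.tsv"),
                         file.path(dir, "arrays.tsv"))
  utils::write.table(sim$truth$probes, file.path(dir, "truth_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$de_genes)) {
    utils::write.table(sim$truth$de_genes,
                       file.path(dir, "truth_de_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
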