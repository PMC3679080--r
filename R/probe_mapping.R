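#' Map tiling probes onto gene-model segments
#'
#' Assigns every probe to exactly one exon or intron of exactly one gene.
#' A probe is retained only when its interval lies fully inside a single
#' segment of a single gene; everything else is excluded with a reason:
#' \describe{
#'   \item{malformed}{interval length differs from `probe_length`.}
#'   \item{control}{flagged as a control probe in the input.}
#'   \item{multi_location}{probe id occurs at more than one genomic
#'     position, or the probe lies inside segments of more than one
#'     (overlapping) gene.}
#'   \item{border}{probe overlaps a segment but crosses an exon/intron
#'     boundary (or a gene edge).}
#'   \item{intergenic}{probe overlaps no gene segment.}
#' }
#'
#' @param probes data frame with columns `probe_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive), `strand`, and optionally `is_control`
#'   (logical).
#' @param models a `gene_models` object.
#' @param probe_length expected probe length in nt (default 25).
#' @param stranded if `TRUE`, probes may only map to genes on the same
#'   strand; default `FALSE` (double-stranded cDNA targets hybridise both
#'   strands).
#' @return a list of class `probe_map`:
#'   `mapped` (probe_id, chromosome, start, end, strand, gene_id,
#'   segment_kind, segment_index), `excluded` (probe_id, reason), and
#'   `report`, a data frame of per-reason counts plus the retained count.
#' @export
map_probes <- function(probes, models, probe_length = 25L, stranded = FALSE) {
  req <- c("probe_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(req, names(probes))
  if (length(miss)) stop("probe table lacks columns: ", paste(miss, collapse = ", "))
  probes <- as.data.frame(probes)
  if (is.null(probes$is_control)) probes$is_control <- FALSE
  n_in <- nrow(probes)

  reason <- rep(NA_character_, n_in)

  malformed <- (probes$end - probes$start + 1L) != probe_length
  if (any(malformed)) {
    warning(sum(malformed), " probe(s) with interval length != ",
            probe_length, " excluded as malformed")
    reason[malformed] <- "malformed"
  }
  reason[is.na(reason) & probes$is_control] <- "control"

  # a probe id seen at more than one distinct position is multi-location
  live <- is.na(reason)
  key <- paste(probes$probe_id, probes$chromosome, probes$start, probes$end)
  pos_per_id <- rowsum((!duplicated(key)) + 0L, probes$probe_id)
  multi_ids <- rownames(pos_per_id)[pos_per_id[, 1L] > 1L]
  reason[live & probes$probe_id %in% multi_ids] <- "multi_location"

  live <- which(is.na(reason))
  if (length(live)) {
    seg <- models$segments
    seg_gr <- GenomicRanges::GRanges(
      seqnames = seg$chromosome,
      ranges = IRanges::IRanges(seg$start, seg$end),
      strand = if (stranded) seg$strand else "*"
    )
    probe_gr <- GenomicRanges::GRanges(
      seqnames = probes$chromosome[live],
      ranges = IRanges::IRanges(probes$start[live], probes$end[live]),
      strand = if (stranded) probes$strand[live] else "*"
    )
    within <- GenomicRanges::findOverlaps(probe_gr, seg_gr, type = "within")
    touches <- GenomicRanges::findOverlaps(probe_gr, seg_gr, type = "any")

    qh <- S4Vectors::queryHits(within)
    sh <- S4Vectors::subjectHits(within)
    n_genes <- integer(length(live))
    if (length(qh)) {
      genes_hit <- rowsum((!duplicated(paste(qh, seg$gene_id[sh]))) + 0L, qh)
      n_genes[as.integer(rownames(genes_hit))] <- genes_hit[, 1L]
    }
    has_touch <- logical(length(live))
    has_touch[unique(S4Vectors::queryHits(touches))] <- TRUE

    reason[live[n_genes > 1L]] <- "multi_location"
    reason[live[n_genes == 0L & has_touch]] <- "border"
    reason[live[n_genes == 0L & !has_touch]] <- "intergenic"

    ok <- n_genes == 1L
    first_hit <- match(which(ok), qh)  # unique segment per retained probe
    mapped <- data.frame(
      probe_id = probes$probe_id[live[ok]],
      chromosome = probes$chromosome[live[ok]],
      start = probes$start[live[ok]],
      end = probes$end[live[ok]],
      strand = probes$strand[live[ok]],
      gene_id = seg$gene_id[sh[first_hit]],
      segment_kind = seg$kind[sh[first_hit]],
      segment_index = seg$index[sh[first_hit]],
      stringsAsFactors = FALSE
    )
  } else {
    mapped <- data.frame(probe_id = character(0), chromosome = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), gene_id = character(0),
                         segment_kind = character(0),
                         segment_index = integer(0))
  }

  excluded <- data.frame(probe_id = probes$probe_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  reasons <- c("multi_location", "border", "intergenic", "control", "malformed")
  report <- data.frame(
    category = c("retained", reasons),
    n = c(nrow(mapped),
          vapply(reasons, function(r) sum(excluded$reason == r), integer(1))),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(mapped) + nrow(excluded) == n_in)
  structure(list(mapped = mapped, excluded = excluded, report = report),
            class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  cat("probe_map:", nrow(x$mapped), "probes retained,",
      nrow(x$excluded), "excluded\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Per-gene probe counts
#'
#' Counts mapped probes per gene, total and intronic; genes of the model set
#' that received no probes are reported with zeros.
#'
#' @param map a `probe_map` (or its `mapped` data frame).
#' @param models a `gene_models` object supplying the gene universe;
#'   if omitted, only genes present in the map are reported.
#' @return data frame `gene_id`, `n_probes`, `n_exon_probes`,
#'   `n_intron_probes`.
#' @export
probe_counts_per_gene <- function(map, models = NULL) {
  mapped <- if (inherits(map, "probe_map")) map$mapped else map
  genes <- if (!is.null(models)) models$genes$gene_id else unique(mapped$gene_id)
  tot <- table(factor(mapped$gene_id, levels = genes))
  intr <- table(factor(mapped$gene_id[mapped$segment_kind == "intron"],
                       levels = genes))
  exon <- table(factor(mapped$gene_id[mapped$segment_kind == "exon"],
                       levels = genes))
  data.frame(gene_id = genes,
             n_probes = as.integer(tot),
             n_exon_probes = as.integer(exon),
             n_intron_probes = as.integer(intr),
             stringsAsFactors = FALSE)
}

#' Read a probe coordinate table
#'
#' BED-like TSV with header: `probe_id`, `chromosome`, `start`, `end`,
#' `strand`, optional `is_control` (0/1 or logical).
#'
#' @param path TSV file.
#' @return data frame of probes.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(p$is_control)) p$is_control <- as.logical(p$is_control)
  p
}

#' Write mapped probes and the exclusion report
#'
#' @param map a `probe_map`.
#' @param mapped_path,report_path output TSV paths (either may be `NULL`).
#' @export
write_probe_map <- function(map, mapped_path = NULL, report_path = NULL) {
  if (!is.null(mapped_path)) {
    utils::write.table(map$mapped, mapped_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report_path)) {
    utils::write.table(map$report, report_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(map)
}
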