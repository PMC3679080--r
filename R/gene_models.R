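#' Gene models: base-transcript selection and exon/intron segmentation
#'
#' A `gene_models` object holds, for each gene, the exon/intron segmentation
#' of its *base transcript* — the annotated isoform with the most exons.
#' Introns are the gaps between consecutive exons of that transcript.
#' Segment numbering follows transcript orientation (5' to 3'), so for
#' minus-strand genes segment indices run against genomic coordinate order.
#'
#' @section Structure:
#' A list with two data frames:
#' \describe{
#'   \item{genes}{`gene_id`, `chromosome`, `strand`, `transcript_id`,
#'     `n_exons`, `n_introns`, `tx_start`, `tx_end`.}
#'   \item{segments}{`gene_id`, `chromosome`, `strand`, `kind`
#'     (`"exon"`/`"intron"`), `index` (1-based, transcript order),
#'     `start`, `end` (1-based inclusive genomic coordinates).}
#' }
#' @name gene_models
NULL

#' Derive introns from a sorted exon interval list
#'
#' Introns are the complement of the exons within the transcript span:
#' the gap between the end of one exon and the start of the next.
#' Abutting exons (zero-length gap) produce no intron.
#'
#' @param exons two-column matrix or data frame of exon `start`, `end`
#'   (1-based inclusive), sorted by start, non-overlapping.
#' @return data frame with columns `start`, `end`; zero rows for a
#'   single-exon input.
#' @examples
#' derive_introns(data.frame(start = c(100, 300), end = c(200, 400)))
#' @export
derive_introns <- function(exons) {
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2L) stop("`exons` needs start and end columns")
  names(exons)[1:2] <- c("start", "end")
  if (nrow(exons) <= 1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons: introns are undefined")
  }
  start <- exons$end[-nrow(exons)] + 1L
  end <- exons$start[-1L] - 1L
  keep <- end >= start  # abutting exons leave no gap
  data.frame(start = start[keep], end = end[keep])
}

#' Select each gene's base transcript and segment it
#'
#' For a gene annotated with several transcripts, the isoform with the most
#' exons is the base transcript; ties are broken by the lexicographically
#' smallest transcript id so the choice is deterministic. The base
#' transcript's exons and derived introns are numbered in transcript
#' orientation.
#'
#' @param exon_table data frame of annotated exons with columns `gene_id`,
#'   `transcript_id`, `chromosome`, `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive).
#' @return a `gene_models` object (see [gene_models]).
#' @export
select_base_transcript <- function(exon_table) {
  req <- c("gene_id", "transcript_id", "chromosome", "strand", "start", "end")
  miss <- setdiff(req, names(exon_table))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(exon_table) == 0L) stop("exon table is empty")

  counts <- stats::aggregate(start ~ gene_id + transcript_id,
                             data = exon_table, FUN = length)
  names(counts)[3] <- "n_exons"
  # max exon count, ties to the lexicographically smallest transcript id
  counts <- counts[order(counts$gene_id, -counts$n_exons, counts$transcript_id), ]
  base <- counts[!duplicated(counts$gene_id), ]

  rows_by_tx <- split(seq_len(nrow(exon_table)),
                      paste(exon_table$gene_id, exon_table$transcript_id,
                            sep = "\r"))
  seg_list <- vector("list", nrow(base))
  gene_rows <- vector("list", nrow(base))
  for (i in seq_len(nrow(base))) {
    gid <- base$gene_id[i]
    tid <- base$transcript_id[i]
    ex <- exon_table[rows_by_tx[[paste(gid, tid, sep = "\r")]], ,
                     drop = FALSE]
    if (nrow(ex) == 0L || any(is.na(ex$start)) || any(is.na(ex$end))) {
      stop("gene ", gid, " has no usable exons")
    }
    chrom <- ex$chromosome[1L]
    strand <- ex$strand[1L]
    if (!strand %in% c("+", "-")) stop("gene ", gid, " has strand ", strand)
    ex <- ex[order(ex$start), , drop = FALSE]
    introns <- derive_introns(ex[, c("start", "end")])
    nex <- nrow(ex)
    nin <- nrow(introns)
    # transcript-order numbering: genomic order on "+", reversed on "-"
    exon_idx <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
    intron_idx <- if (nin == 0L) integer(0) else
      if (strand == "+") seq_len(nin) else rev(seq_len(nin))
    seg_list[[i]] <- data.frame(
      gene_id = gid, chromosome = chrom, strand = strand,
      kind = c(rep("exon", nex), rep("intron", nin)),
      index = c(exon_idx, intron_idx),
      start = c(ex$start, introns$start),
      end = c(ex$end, introns$end),
      stringsAsFactors = FALSE
    )
    gene_rows[[i]] <- data.frame(
      gene_id = gid, chromosome = chrom, strand = strand,
      transcript_id = tid, n_exons = nex, n_introns = nin,
      tx_start = min(ex$start), tx_end = max(ex$end),
      stringsAsFactors = FALSE
    )
  }
  models <- list(genes = do.call(rbind, gene_rows),
                 segments = do.call(rbind, seg_list))
  rownames(models$genes) <- NULL
  rownames(models$segments) <- NULL
  class(models) <- "gene_models"
  models
}

#' Read gene models from a GFF3 annotation
#'
#' Parses gene / mRNA (or transcript) / exon features, resolves `Parent`
#' attributes, and applies [select_base_transcript()] to every gene.
#'
#' @param path GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  tx <- gff[type %in% c("mRNA", "transcript")]
  ex <- gff[type == "exon"]
  if (length(tx) == 0L || length(ex) == 0L) {
    stop("annotation has no transcript/exon features: ", path)
  }
  tx_parent <- vapply(tx$Parent, function(p) p[1L], character(1))
  tx_id <- tx$ID
  gene_of_tx <- stats::setNames(tx_parent, tx_id)
  ex_parent <- vapply(ex$Parent, function(p) p[1L], character(1))
  known <- ex_parent %in% tx_id
  if (!all(known)) {
    warning(sum(!known), " exon(s) with unknown Parent dropped")
    ex <- ex[known]
    ex_parent <- ex_parent[known]
  }
  exon_table <- data.frame(
    gene_id = unname(gene_of_tx[ex_parent]),
    transcript_id = ex_parent,
    chromosome = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  select_base_transcript(exon_table)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      sum(x$segments$kind == "exon"), "exons,",
      sum(x$segments$kind == "intron"), "introns\n")
  invisible(x)
}

#' Write a gene-model summary TSV
#'
#' One row per gene: id, chromosome, strand, exon count and comma-separated
#' exon/intron interval lists.
#'
#' @param models a `gene_models` object.
#' @param path output TSV path.
#' @export
write_gene_models <- function(models, path) {
  fmt <- function(gid, kind) {
    s <- models$segments
    s <- s[s$gene_id == gid & s$kind == kind, , drop = FALSE]
    s <- s[order(s$index), , drop = FALSE]
    paste(sprintf("%d-%d", s$start, s$end), collapse = ",")
  }
  g <- models$genes
  out <- data.frame(
    gene_id = g$gene_id, chromosome = g$chromosome, strand = g$strand,
    n_exons = g$n_exons,
    exons = vapply(g$gene_id, fmt, character(1), kind = "exon"),
    introns = vapply(g$gene_id, fmt, character(1), kind = "intron"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
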