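#' Gene-level expression from mapped probes
#'
#' A gene's expression value on an array is the arithmetic mean of the log2
#' intensities of all probes mapped to its exons; the intronic mean is the
#' analogous average over intron probes (absent when a gene has none).
#' Expression is only computed for genes represented by more than
#' `min_probes - 1` mapped probes (default: more than three).
#'
#' @param m an `intensity_matrix` in state `"normalized_log2"`.
#' @param map a `probe_map` (or its `mapped` data frame).
#' @param min_probes minimum number of mapped probes a gene must have
#'   (strictly more than `min_probes - 1`; default 4, i.e. > 3 probes).
#' @return a `gene_expression` object: list with `exon` and `intron`
#'   (genes x arrays matrices of per-array means, `NA` where undefined),
#'   `samples` (array design), and `counts` (per-gene probe counts for the
#'   genes carrying expression values, plus a `no_exon_probes` flag).
#' @export
gene_expression <- function(m, map, min_probes = 4L) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "normalized_log2") {
    stop("gene expression is computed on normalized log2 intensities")
  }
  mapped <- if (inherits(map, "probe_map")) map$mapped else map
  counts <- probe_counts_per_gene(mapped)
  counts <- counts[counts$n_probes >= min_probes, , drop = FALSE]
  counts$no_exon_probes <- counts$n_exon_probes == 0L
  if (any(counts$no_exon_probes)) {
    warning(sum(counts$no_exon_probes),
            " gene(s) have enough probes but none in exons; ",
            "their expression is undefined (NA)")
  }
  genes <- counts$gene_id

  keep <- mapped$gene_id %in% genes
  probe_rows <- match(mapped$probe_id[keep], rownames(m$values))
  if (anyNA(probe_rows)) stop("mapped probes missing from the intensity matrix")
  gene_f <- factor(mapped$gene_id[keep], levels = genes)
  kind <- mapped$segment_kind[keep]
  vals <- m$values[probe_rows, , drop = FALSE]

  group_means <- function(sel) {
    out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(vals),
                  dimnames = list(genes, colnames(vals)))
    if (any(sel)) {
      f <- droplevels(gene_f[sel])
      sums <- rowsum(vals[sel, , drop = FALSE], f)
      n <- table(f)
      out[rownames(sums), ] <- sums / as.integer(n[rownames(sums)])
    }
    out
  }
  structure(list(
    exon = group_means(kind == "exon"),
    intron = group_means(kind == "intron"),
    samples = m$samples,
    counts = counts
  ), class = "gene_expression")
}

#' @export
print.gene_expression <- function(x, ...) {
  cat("gene_expression:", nrow(x$exon), "genes x", ncol(x$exon), "arrays\n")
  invisible(x)
}

#' Fold changes and the differentially-expressed gene call
#'
#' Per-condition expression is the mean of a gene's per-array expression
#' values over the replicate arrays of that condition. The log2 fold change
#' is treatment minus control, so induced genes are positive. Each gene is
#' tested with a two-sided two-sample t-test on its per-array expression
#' values, p-values are Benjamini-Hochberg adjusted across all tested genes,
#' and a gene is called responsive when the adjusted p-value is at most
#' `fdr` **and** the absolute linear fold change is at least `min_fold`.
#'
#' Degenerate variance (all replicate values identical in both groups) gives
#' p = 1 when the group means agree; otherwise the pooled variance is floored
#' at 1e-8 so the call reflects the mean difference.
#'
#' @param ge a `gene_expression` object.
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @param min_fold minimum absolute linear fold change (default 2, i.e.
#'   |log2 FC| >= 1).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data frame: `gene_id`, `expr_control`, `expr_treatment`,
#'   `log2_fc`, `linear_fc` (signed: negative for repression), `p_value`,
#'   `adj_p`, `responsive`.
#' @export
fold_change_and_test <- function(ge, fdr = 0.05, min_fold = 2,
                                 var_equal = TRUE) {
  stopifnot(inherits(ge, "gene_expression"))
  expr <- ge$exon
  ok <- rowSums(is.na(expr)) == 0L
  expr <- expr[ok, , drop = FALSE]
  is_ctrl <- ge$samples$condition == "control"
  is_trt <- ge$samples$condition == "treatment"
  tt <- row_t_test(expr, is_ctrl, is_trt,
                   alternative = "two.sided", var_equal = var_equal)
  log2_fc <- tt$mean_treatment - tt$mean_control
  adj <- bh_adjust(tt$p_value)
  data.frame(
    gene_id = rownames(expr),
    expr_control = tt$mean_control,
    expr_treatment = tt$mean_treatment,
    log2_fc = log2_fc,
    linear_fc = ifelse(log2_fc >= 0, 2^log2_fc, -2^(-log2_fc)),
    p_value = tt$p_value,
    adj_p = adj,
    responsive = adj <= fdr & abs(log2_fc) >= log2(min_fold),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write the gene-expression result table
#'
#' @param tbl data frame from [fold_change_and_test()].
#' @param path output TSV path.
#' @export
write_gene_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
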