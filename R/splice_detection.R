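#' Gating thresholds for the splicing analysis
#'
#' Two global log2-intensity cutoffs computed from the normalized matrix:
#' the *exon expression threshold* (median over all exon-probe values, all
#' arrays pooled) that a gene's exonic signal must exceed, and the *intron
#' background threshold* (median over all mapped probes' values) that a
#' gene's intronic signal must stay below. The histogram mode of the
#' exon-probe values is reported alongside as a diagnostic.
#'
#' @param m an `intensity_matrix` in state `"normalized_log2"`.
#' @param map a `probe_map` (or its `mapped` data frame).
#' @return list of class `gating_thresholds`: `exon_expression_threshold`,
#'   `intron_background_threshold`, `exon_mode` (diagnostic).
#' @export
gating_thresholds <- function(m, map) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "normalized_log2") stop("thresholds need normalized log2 data")
  mapped <- if (inherits(map, "probe_map")) map$mapped else map
  rows <- match(mapped$probe_id, rownames(m$values))
  if (anyNA(rows)) stop("mapped probes missing from the intensity matrix")
  exon_vals <- m$values[rows[mapped$segment_kind == "exon"], , drop = FALSE]
  all_vals <- m$values[rows, , drop = FALSE]
  structure(list(
    exon_expression_threshold = stats::median(exon_vals),
    intron_background_threshold = stats::median(all_vals),
    exon_mode = histogram_mode(as.vector(exon_vals))
  ), class = "gating_thresholds")
}

#' @export
print.gating_thresholds <- function(x, ...) {
  cat(sprintf(paste0("gating_thresholds: exon expression > %.3f, ",
                     "intron background < %.3f (exon mode %.3f)\n"),
              x$exon_expression_threshold, x$intron_background_threshold,
              x$exon_mode))
  invisible(x)
}

#' Gate genes eligible for the intron-level splicing test
#'
#' A gene enters the splicing analysis when it (i) is represented by at
#' least `min_probes` mapped probes (default 9, i.e. more than eight),
#' (ii) has at least one intron probe, and (iii) in at least one condition
#' its mean exonic expression (replicate-averaged) exceeds the exon
#' expression threshold while its mean intronic signal stays below the
#' intron background threshold — i.e. the gene is expressed but its introns
#' are at background in that condition.
#'
#' @param m an `intensity_matrix` in state `"normalized_log2"`.
#' @param map a `probe_map`.
#' @param ge a `gene_expression` object (provides per-array exon/intron
#'   means; compute with `min_probes = 1` downstream of [gene_expression()]
#'   if you want the gate itself to impose the probe-count rule).
#' @param thresholds optional precomputed [gating_thresholds()].
#' @param min_probes minimum mapped probes per gene (default 9).
#' @return list of class `gene_gate`: `eligible` (character vector of gene
#'   ids), `thresholds`, and `funnel` (named integer vector of counts after
#'   each successive filter).
#' @export
gate_genes <- function(m, map, ge, thresholds = NULL, min_probes = 9L) {
  stopifnot(inherits(ge, "gene_expression"))
  if (is.null(thresholds)) thresholds <- gating_thresholds(m, map)
  counts <- probe_counts_per_gene(map)

  enough <- counts$gene_id[counts$n_probes >= min_probes]
  with_intron <- counts$gene_id[counts$n_probes >= min_probes &
                                  counts$n_intron_probes >= 1L]
  cand <- intersect(with_intron, rownames(ge$exon))

  is_ctrl <- ge$samples$condition == "control"
  is_trt <- ge$samples$condition == "treatment"
  cond_mean <- function(mat, sel) rowMeans(mat[cand, sel, drop = FALSE])
  ex_c <- cond_mean(ge$exon, is_ctrl)
  ex_t <- cond_mean(ge$exon, is_trt)
  in_c <- cond_mean(ge$intron, is_ctrl)
  in_t <- cond_mean(ge$intron, is_trt)

  exon_thr <- thresholds$exon_expression_threshold
  intr_thr <- thresholds$intron_background_threshold
  pass <- (ex_c > exon_thr & in_c < intr_thr) |
          (ex_t > exon_thr & in_t < intr_thr)
  pass[is.na(pass)] <- FALSE
  eligible <- cand[pass]
  if (length(eligible) == 0L) {
    warning("no genes pass the splicing gate; downstream results are empty")
  }
  structure(list(
    eligible = eligible,
    thresholds = thresholds,
    funnel = c(genes_total = nrow(counts),
               min_probes = length(enough),
               with_intron_probe = length(with_intron),
               with_expression = length(cand),
               eligible = length(eligible))
  ), class = "gene_gate")
}

#' @export
print.gene_gate <- function(x, ...) {
  cat("gene_gate:", length(x$eligible), "eligible genes\n")
  print(x$funnel)
  invisible(x)
}

#' Probe-level one-sided tests with the complement rule
#'
#' For every probe (row), a one-sided two-sample t-test of treatment greater
#' than control across replicate arrays gives `p_up`; the complementary
#' direction gets `p_down = 1 - p_up`, so a probe moving against the tested
#' direction is assigned the complementary value rather than being tested
#' twice. Each probe is only ever compared with itself across conditions.
#'
#' @param m an `intensity_matrix` in state `"normalized_log2"`.
#' @param probe_ids probes to test (default: all rows).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data frame `probe_id`, `p_up`, `p_down`.
#' @export
probe_level_tests <- function(m, probe_ids = rownames(m$values),
                              var_equal = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "normalized_log2") stop("probe tests need normalized log2 data")
  rows <- match(probe_ids, rownames(m$values))
  if (anyNA(rows)) stop("unknown probe id(s): ",
                        paste(utils::head(probe_ids[is.na(rows)], 5),
                              collapse = ", "))
  tt <- row_t_test(m$values[rows, , drop = FALSE],
                   m$samples$condition == "control",
                   m$samples$condition == "treatment",
                   alternative = "greater", var_equal = var_equal)
  data.frame(probe_id = probe_ids, p_up = tt$p_value,
             p_down = 1 - tt$p_value, stringsAsFactors = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines k p-values into X^2 = -2 * sum(log p), referred to the upper
#' tail of a chi-square distribution with 2k degrees of freedom. Valid for
#' independent tests; on tiling arrays with non-overlapping probes the
#' residual correlation between neighbouring probes is deliberately ignored.
#'
#' @param p p-values in (0, 1]; zeros are floored at 1e-300 with a warning.
#' @return the combined p-value (for k = 1, the input itself).
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (any(p == 0)) {
    warning("p-value(s) of 0 floored at 1e-300 before combining")
    p[p == 0] <- 1e-300
  }
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Splice-type classification of a significant intron
#'
#' An intron is *retained* only when every one of its probes changes
#' significantly (unadjusted p below `alpha`) in the winning direction;
#' any other pattern — partial events such as alternative 5'/3' splice
#' sites, or mixed probe behaviour — is *unknown*.
#'
#' @param p_winning per-probe p-values in the intron's winning direction.
#' @param alpha per-probe significance level (default 0.05).
#' @return `"retained"` or `"unknown"`.
#' @export
classify_splice_type <- function(p_winning, alpha = 0.05) {
  if (length(p_winning) == 0L) return("unknown")
  if (all(p_winning < alpha)) "retained" else "unknown"
}

#' Intron-level differential-splicing test
#'
#' For every intron of the eligible genes, the per-probe directional
#' p-values are combined with Fisher's method separately for the two
#' directions; the minimum of the two combined p-values is the intron-level
#' p. Intron p-values are BH-adjusted across all tested introns, and
#' introns with adjusted p at most `fdr` (default 0.1) are called
#' differentially spliced. The direction is the side achieving the minimum;
#' the presence call is the condition with the higher mean intronic signal;
#' significant introns are classified with [classify_splice_type()].
#'
#' The min-of-two-directions rule is anti-conservative by up to a factor of
#' two relative to a proper two-sided combination; set
#' `two_sided_correction = TRUE` to Bonferroni-double the intron p-value
#' (default off, matching the published procedure).
#'
#' @param m an `intensity_matrix` in state `"normalized_log2"`.
#' @param map a `probe_map`.
#' @param genes gene ids to test (typically `gate$eligible`).
#' @param fdr BH threshold on the intron-level adjusted p (default 0.1).
#' @param probe_alpha per-probe level for splice-type classification
#'   (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @param two_sided_correction double the intron p (default `FALSE`).
#' @return data frame of class `intron_results`: `gene_id`, `intron_index`,
#'   `n_probes`, `combined_p_up`, `combined_p_down`, `intron_p`, `adj_p`,
#'   `direction` (`higher_in_treatment` / `higher_in_control`), `presence`
#'   (`treatment` / `control`), `significant`, `splice_type` (`retained` /
#'   `unknown`, `NA` for non-significant introns).
#' @export
intron_test <- function(m, map, genes, fdr = 0.1, probe_alpha = 0.05,
                        var_equal = TRUE, two_sided_correction = FALSE) {
  mapped <- if (inherits(map, "probe_map")) map$mapped else map
  ip <- mapped[mapped$segment_kind == "intron" & mapped$gene_id %in% genes, ,
               drop = FALSE]
  empty <- data.frame(gene_id = character(0), intron_index = integer(0),
                      n_probes = integer(0), combined_p_up = numeric(0),
                      combined_p_down = numeric(0), intron_p = numeric(0),
                      adj_p = numeric(0), direction = character(0),
                      presence = character(0), significant = logical(0),
                      splice_type = character(0))
  if (nrow(ip) == 0L) return(structure(empty, class = c("intron_results",
                                                        "data.frame")))

  pt <- probe_level_tests(m, ip$probe_id, var_equal = var_equal)
  is_ctrl <- m$samples$condition == "control"
  is_trt <- m$samples$condition == "treatment"
  vals <- m$values[match(ip$probe_id, rownames(m$values)), , drop = FALSE]
  probe_mean_c <- rowMeans(vals[, is_ctrl, drop = FALSE])
  probe_mean_t <- rowMeans(vals[, is_trt, drop = FALSE])

  key <- paste(ip$gene_id, ip$segment_index, sep = "\r")
  groups <- split(seq_len(nrow(ip)), key)

  res <- lapply(groups, function(idx) {
    p_up <- pt$p_up[idx]
    p_down <- pt$p_down[idx]
    cp_up <- fisher_combine(p_up)
    cp_down <- fisher_combine(p_down)
    p_min <- min(cp_up, cp_down)
    if (two_sided_correction) p_min <- min(1, 2 * p_min)
    up_wins <- cp_up <= cp_down
    data.frame(
      gene_id = ip$gene_id[idx[1L]],
      intron_index = ip$segment_index[idx[1L]],
      n_probes = length(idx),
      combined_p_up = cp_up,
      combined_p_down = cp_down,
      intron_p = p_min,
      direction = if (up_wins) "higher_in_treatment" else "higher_in_control",
      presence = if (mean(probe_mean_t[idx]) >= mean(probe_mean_c[idx]))
        "treatment" else "control",
      winning_p = I(list(if (up_wins) p_up else p_down)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$gene_id, out$intron_index), , drop = FALSE]
  out$adj_p <- bh_adjust(out$intron_p)
  out$significant <- out$adj_p <= fdr
  out$splice_type <- NA_character_
  sig <- which(out$significant)
  out$splice_type[sig] <- vapply(
    out$winning_p[sig],
    function(p) classify_splice_type(p, alpha = probe_alpha),
    character(1)
  )
  out$winning_p <- NULL
  rownames(out) <- NULL
  structure(out[, names(empty)], class = c("intron_results", "data.frame"))
}

#' Write intron-level splicing results
#'
#' Columns mirror a per-event report: gene, intron number (transcript
#' order), splice type (`r` retained / `u` unknown), presence condition,
#' combined and adjusted p-values, and direction.
#'
#' @param results an `intron_results` data frame.
#' @param path output TSV path.
#' @param significant_only write only the significant calls (default TRUE).
#' @export
write_intron_results <- function(results, path, significant_only = TRUE) {
  r <- if (significant_only) results[results$significant, , drop = FALSE]
       else results
  out <- data.frame(
    gene_id = r$gene_id,
    intron_no = r$intron_index,
    type = c(retained = "r", unknown = "u")[r$splice_type],
    presence = r$presence,
    combined_p = r$intron_p,
    adjusted_p = r$adj_p,
    direction = r$direction,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
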