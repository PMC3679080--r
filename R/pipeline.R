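#' Run the full splicing-detection pipeline
#'
#' Executes the stages in their fixed order: probe mapping, preprocessing
#' (background correction, quantile normalization, log2), gene expression
#' and the differential-expression call, the splicing gate, the intron-level
#' combined-p test, and splice-type classification. A per-stage funnel of
#' counts is collected for logging, and a manifest records the options so a
#' run can be reproduced exactly.
#'
#' @param models a `gene_models` object (or a GFF3 path).
#' @param probes probe coordinate table (or a TSV path, see
#'   [read_probe_table()]).
#' @param intensities a raw `intensity_matrix` (or a length-2 character
#'   vector `c(intensity_tsv, design_tsv)`).
#' @param background background-correction method (`"none"` or
#'   `"normexp"`).
#' @param gene_fdr,min_fold gene-level call thresholds (defaults 0.05, 2).
#' @param intron_fdr intron-level BH threshold (default 0.1).
#' @param probe_alpha per-probe level for splice-type classification
#'   (default 0.05).
#' @param min_probes_expression,min_probes_splicing probe-count gates for
#'   the expression table (default 4, i.e. > 3 probes) and the splicing
#'   analysis (default 9, i.e. > 8 probes).
#' @param stranded restrict probe mapping to same-strand genes (default
#'   `FALSE`).
#' @param var_equal pooled-variance t-tests (default) or Welch.
#' @param two_sided_correction see [intron_test()] (default `FALSE`).
#' @return list of class `splice_run`: `map`, `normalized`, `expression`,
#'   `gene_table`, `gate`, `intron_results`, `funnel`, `manifest`.
#' @export
run_splicing_pipeline <- function(models, probes, intensities,
                                  background = c("none", "normexp"),
                                  gene_fdr = 0.05, min_fold = 2,
                                  intron_fdr = 0.1, probe_alpha = 0.05,
                                  min_probes_expression = 4L,
                                  min_probes_splicing = 9L,
                                  stranded = FALSE, var_equal = TRUE,
                                  two_sided_correction = FALSE) {
  background <- match.arg(background)
  if (is.character(models)) models <- read_gene_models(models)
  if (is.character(probes)) probes <- read_probe_table(probes)
  if (is.character(intensities)) {
    intensities <- read_intensity_matrix(intensities[1L], intensities[2L])
  }

  map <- map_probes(probes, models, stranded = stranded)
  norm <- preprocess_intensities(intensities, background = background)
  ge <- gene_expression(norm, map, min_probes = min_probes_expression)
  gene_table <- fold_change_and_test(ge, fdr = gene_fdr, min_fold = min_fold,
                                     var_equal = var_equal)
  gate <- gate_genes(norm, map, ge, min_probes = min_probes_splicing)
  intron_results <- intron_test(norm, map, gate$eligible, fdr = intron_fdr,
                                probe_alpha = probe_alpha,
                                var_equal = var_equal,
                                two_sided_correction = two_sided_correction)

  funnel <- c(
    probes_input = nrow(probes),
    probes_retained = nrow(map$mapped),
    probes_excluded = nrow(map$excluded),
    genes_with_expression = sum(!is.na(rowSums(ge$exon))),
    genes_responsive = sum(gene_table$responsive),
    genes_gated = length(gate$eligible),
    introns_tested = nrow(intron_results),
    introns_significant = sum(intron_results$significant),
    introns_retained_type = sum(intron_results$splice_type == "retained",
                                na.rm = TRUE)
  )
  manifest <- list(
    package = "tilesplice",
    version = as.character(utils::packageVersion("tilesplice")),
    options = list(background = background, gene_fdr = gene_fdr,
                   min_fold = min_fold, intron_fdr = intron_fdr,
                   probe_alpha = probe_alpha,
                   min_probes_expression = min_probes_expression,
                   min_probes_splicing = min_probes_splicing,
                   stranded = stranded, var_equal = var_equal,
                   two_sided_correction = two_sided_correction),
    thresholds = list(
      exon_expression = gate$thresholds$exon_expression_threshold,
      intron_background = gate$thresholds$intron_background_threshold),
    funnel = as.list(funnel)
  )
  structure(list(map = map, normalized = norm, expression = ge,
                 gene_table = gene_table, gate = gate,
                 intron_results = intron_results, funnel = funnel,
                 manifest = manifest),
            class = "splice_run")
}

#' @export
print.splice_run <- function(x, ...) {
  cat("splice_run funnel:\n")
  print(x$funnel)
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Writes the gene-level table, the full and significant intron results,
#' the exclusion report, and a JSON run manifest (when jsonlite is
#' available).
#'
#' @param run a `splice_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "splice_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(run$gene_table, file.path(dir, "gene_table.tsv"))
  utils::write.table(run$intron_results,
                     file.path(dir, "intron_results_all.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_intron_results(run$intron_results,
                       file.path(dir, "intron_events.tsv"))
  write_probe_map(run$map, report_path = file.path(dir,
                                                   "exclusion_report.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
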