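#' Build a stress index from a fold-change table
#'
#' An index summarising one stress experiment: the `k` genes (default 1,000)
#' with the largest absolute log2 fold change among those with unadjusted
#' p-value below `alpha`, stored with their signed log2 fold changes.
#' Ties in |log2 FC| are broken by gene id so the index is deterministic.
#'
#' @param fold_changes data frame with columns `gene_id`, `log2_fc`,
#'   `p_value`.
#' @param k index size (default 1000).
#' @param alpha unadjusted p-value cutoff (default 0.05).
#' @param name optional index label.
#' @return data frame of class `stress_index` with columns `gene_id`,
#'   `log2_fc`, at most `k` rows; fewer (with a warning) when not enough
#'   genes qualify.
#' @export
build_stress_index <- function(fold_changes, k = 1000L, alpha = 0.05,
                               name = NULL) {
  req <- c("gene_id", "log2_fc", "p_value")
  miss <- setdiff(req, names(fold_changes))
  if (length(miss)) stop("fold-change table lacks columns: ",
                         paste(miss, collapse = ", "))
  qual <- fold_changes[fold_changes$p_value < alpha, , drop = FALSE]
  if (nrow(qual) < k) {
    warning("only ", nrow(qual), " genes pass p < ", alpha,
            " (requested ", k, "); keeping all of them")
  }
  qual <- qual[order(-abs(qual$log2_fc), qual$gene_id), , drop = FALSE]
  idx <- utils::head(qual[, c("gene_id", "log2_fc")], k)
  rownames(idx) <- NULL
  structure(idx, class = c("stress_index", "data.frame"),
            index_name = name)
}

#' Correlate an experiment against a stress index
#'
#' Pearson correlation of the signed log2 fold changes over the genes shared
#' between the index and the experiment: 1 means direction and intensity of
#' the responses agree completely, -1 that they are exact opposites.
#'
#' @param index a `stress_index` (or any data frame with `gene_id`,
#'   `log2_fc`).
#' @param experiment data frame with `gene_id`, `log2_fc` for the experiment
#'   to score.
#' @param min_shared minimum shared genes required (default 3); below this
#'   the correlation is undefined and `NA` is returned with a warning.
#' @return correlation coefficient in \[-1, 1\], or `NA`.
#' @export
correlate_index <- function(index, experiment, min_shared = 3L) {
  shared <- intersect(index$gene_id, experiment$gene_id)
  if (length(shared) < min_shared) {
    warning("only ", length(shared), " genes shared between index and ",
            "experiment; correlation undefined")
    return(NA_real_)
  }
  x <- index$log2_fc[match(shared, index$gene_id)]
  y <- experiment$log2_fc[match(shared, experiment$gene_id)]
  stats::cor(x, y, method = "pearson")
}

#' Correlate several experiments against several indexes
#'
#' @param indexes named list of `stress_index` objects.
#' @param experiments named list of fold-change data frames (`gene_id`,
#'   `log2_fc`).
#' @return matrix of correlations, experiments in rows, indexes in columns.
#' @export
correlation_matrix <- function(indexes, experiments) {
  out <- matrix(NA_real_, nrow = length(experiments), ncol = length(indexes),
                dimnames = list(names(experiments), names(indexes)))
  for (i in seq_along(experiments)) {
    for (j in seq_along(indexes)) {
      out[i, j] <- correlate_index(indexes[[j]], experiments[[i]])
    }
  }
  out
}

#' Read / write stress index TSVs
#'
#' @param path TSV with columns `gene_id`, `log2_fc`.
#' @return a `stress_index`.
#' @export
read_stress_index <- function(path) {
  idx <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(idx[, c("gene_id", "log2_fc")],
            class = c("stress_index", "data.frame"))
}

#' @rdname read_stress_index
#' @param index a `stress_index` to write.
#' @export
write_stress_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
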