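#' Overlap statistics between two event sets
#'
#' Quantifies the agreement between two lists of events (e.g. differentially
#' spliced introns from two experiments) drawn from a common universe.
#' The representation factor is the observed overlap divided by the overlap
#' expected for independent draws, `n_a * n_b / n_universe`; values above 1
#' indicate enrichment. Significance is the exact upper-tail hypergeometric
#' probability P(X >= overlap) of drawing at least the observed overlap.
#'
#' @param set_a,set_b character vectors of event identifiers (duplicates are
#'   dropped), or data frames with `gene_id` and `intron_index` columns,
#'   which are combined into identifiers.
#' @param n_universe size of the common universe (total events that could
#'   have been called, e.g. all tested introns); must be at least
#'   `length(union(set_a, set_b))`.
#' @return list of class `overlap_result`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `expected_overlap`, `representation_factor`,
#'   `hypergeometric_p`.
#' @examples
#' overlap_sets(paste0("i", 1:10), paste0("i", 6:20), n_universe = 1000)
#' @export
overlap_sets <- function(set_a, set_b, n_universe) {
  set_a <- .event_ids(set_a)
  set_b <- .event_ids(set_b)
  if (n_universe < length(union(set_a, set_b))) {
    stop("n_universe (", n_universe, ") is smaller than |union| (",
         length(union(set_a, set_b)), ")")
  }
  n_a <- length(set_a)
  n_b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  expected <- n_a * n_b / n_universe
  rf <- if (expected > 0) k / expected else NA_real_
  # P(X >= k) with population n_universe, n_a successes, n_b draws
  p <- stats::phyper(k - 1, m = n_a, n = n_universe - n_a, k = n_b,
                     lower.tail = FALSE)
  structure(list(n_universe = n_universe, n_a = n_a, n_b = n_b,
                 n_overlap = k, expected_overlap = expected,
                 representation_factor = rf, hypergeometric_p = p),
            class = "overlap_result")
}

.event_ids <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "intron_index") %in% names(x))) {
      stop("event data frame needs gene_id and intron_index columns")
    }
    x <- paste(x$gene_id, x$intron_index, sep = ":")
  }
  unique(as.character(x))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("overlap: %d of %d x %d (universe %d)\n",
                     "expected %.4f, representation factor %.2f, ",
                     "hypergeometric p = %.4g\n"),
              x$n_overlap, x$n_a, x$n_b, x$n_universe,
              x$expected_overlap, x$representation_factor,
              x$hypergeometric_p))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(n_universe = x$n_universe, n_a = x$n_a, n_b = x$n_b,
             n_overlap = x$n_overlap, expected_overlap = x$expected_overlap,
             representation_factor = x$representation_factor,
             hypergeometric_p = x$hypergeometric_p)
}
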