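#' Probe intensity matrices
#'
#' An `intensity_matrix` couples a probes-by-arrays matrix of intensities
#' with the array design (condition and replicate of each column) and a
#' state flag: `"raw"` (linear scale, strictly positive) or
#' `"normalized_log2"`. The only legal state transition is
#' raw -> normalized_log2, performed by [log2_transform()].
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   arrays in columns (colnames = array ids).
#' @param condition character/factor of length `ncol(values)` with values
#'   `"control"` / `"treatment"`.
#' @param replicate optional replicate index per array; defaults to a
#'   running count within condition.
#' @param state `"raw"` or `"normalized_log2"`.
#' @return an `intensity_matrix`.
#' @export
intensity_matrix <- function(values, condition, replicate = NULL,
                             state = c("raw", "normalized_log2")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have probe ids as rownames")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("array", seq_len(ncol(values)))
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("length(condition) != number of arrays")
  }
  bad <- setdiff(unique(condition), c("control", "treatment"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (state == "raw" && any(values <= 0)) {
    off <- rownames(values)[which(rowSums(values <= 0) > 0)]
    stop("raw intensities must be strictly positive; offending probes: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  structure(list(
    values = values,
    samples = data.frame(array_id = colnames(values),
                         condition = condition,
                         replicate = as.integer(replicate),
                         stringsAsFactors = FALSE),
    state = state
  ), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "arrays (", sum(x$samples$condition == "control"), "control /",
      sum(x$samples$condition == "treatment"), "treatment ), state:",
      x$state, "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Normal+exponential background correction
#'
#' Models each array's raw intensities as signal ~ Exp(mean theta) plus
#' background noise ~ Normal(mu, sigma^2) — the background model underlying
#' RMA — and replaces every intensity by the conditional expectation
#' E\[signal | observed\]. Parameters are estimated per array by the method
#' of moments (theta^3 = half the third central moment; sigma^2 and mu from
#' the remaining variance and mean), which is closed-form and deterministic.
#' Outputs are strictly positive. `method = "none"` is the identity, the
#' default for synthetic background-free data.
#'
#' @param m an `intensity_matrix` in state `"raw"`.
#' @param method `"none"` or `"normexp"`.
#' @return an `intensity_matrix`, still `"raw"` (linear scale).
#' @export
background_correct <- function(m, method = c("none", "normexp")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") stop("background correction requires raw intensities")
  if (method == "none") return(m)
  v <- m$values
  for (j in seq_len(ncol(v))) {
    par <- .normexp_moments(v[, j])
    v[, j] <- limma::normexp.signal(par, v[, j])
  }
  m$values <- v
  m
}

# Moment estimates on limma's scale: c(mu, log(sigma), log(alpha)), where
# alpha is the exponential signal mean. Guards keep all parameters positive
# for near-degenerate inputs (e.g. a constant array).
.normexp_moments <- function(x) {
  meanx <- mean(x)
  varx <- stats::var(x)
  m3 <- mean((x - meanx)^3)
  alpha <- max((max(m3, 0) / 2)^(1 / 3), 1e-6)
  sigma2 <- max(varx - alpha^2, 1e-12)
  mu <- meanx - alpha
  c(mu = mu, logsigma = log(sqrt(sigma2)), logalpha = log(alpha))
}

#' Quantile normalization across arrays
#'
#' Forces every array to the same intensity distribution: the across-array
#' mean of the sorted columns. Within-array rank order is preserved; tied
#' values receive the mean of the reference quantiles they span, which makes
#' the operation idempotent. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param m an `intensity_matrix` in state `"raw"` with at least 2 arrays.
#' @return an `intensity_matrix`, still `"raw"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") stop("quantile normalization precedes log2 transform")
  if (ncol(m$values) < 2L) stop("quantile normalization needs >= 2 arrays")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  m$values <- v
  m
}

#' Log2 transformation
#'
#' @param m an `intensity_matrix` in state `"raw"`, strictly positive.
#' @return an `intensity_matrix` in state `"normalized_log2"`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") stop("matrix is already log2-transformed")
  if (any(m$values <= 0)) stop("log2 transform requires strictly positive values")
  m$values <- log2(m$values)
  m$state <- "normalized_log2"
  m
}

#' RMA-style preprocessing pipeline
#'
#' Fixed order: background correction, quantile normalization across arrays,
#' log2 transformation.
#'
#' @param m an `intensity_matrix` in state `"raw"`.
#' @param background background method, see [background_correct()];
#'   default `"none"` (appropriate for background-free synthetic data;
#'   use `"normexp"` for raw scanner intensities).
#' @return an `intensity_matrix` in state `"normalized_log2"`.
#' @export
preprocess_intensities <- function(m, background = c("none", "normexp")) {
  log2_transform(quantile_normalize(background_correct(m, match.arg(background))))
}

#' Read an intensity matrix and its array design
#'
#' The intensity TSV has a `probe_id` column plus one column per array; the
#' sidecar design TSV has columns `array_id`, `condition`, `replicate`.
#'
#' @param path intensity TSV.
#' @param design_path array design TSV.
#' @param state state flag of the stored values.
#' @return an `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path, design_path,
                                  state = c("raw", "normalized_log2")) {
  for (p in c(path, design_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, design$array_id, drop = FALSE])
  rownames(v) <- tab$probe_id
  intensity_matrix(v, condition = design$condition,
                   replicate = design$replicate, state = match.arg(state))
}

#' Write an intensity matrix and its array design
#'
#' @param m an `intensity_matrix`.
#' @param path intensity TSV path.
#' @param design_path array design TSV path.
#' @export
write_intensity_matrix <- function(m, path, design_path) {
  tab <- data.frame(probe_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}
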