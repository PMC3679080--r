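# Internal numerical helpers shared across modules.

# Row-wise two-sample t-tests on a matrix (rows = features, columns = arrays).
#
# Hand-vectorised rather than looping over stats::t.test because the splice
# pipeline tests tens of thousands of probes, and because degenerate
# (zero-variance) rows need the package's documented fallback instead of the
# "data are essentially constant" error. Cross-checked against stats::t.test
# in the test suite.
#
# Degenerate rule: if the pooled variance collapses (< .tsp_var_tol) the
# p-value is 1 (two-sided) / 0.5 (one-sided) when the group means agree;
# otherwise the variance is floored at `var_floor` so the statistic stays
# finite and the direction of change is preserved.
.tsp_var_tol <- 1e-12

row_t_test <- function(x, is_control, is_treatment,
                       alternative = c("two.sided", "greater"),
                       var_equal = TRUE, var_floor = 1e-8) {
  alternative <- match.arg(alternative)
  x <- as.matrix(x)
  xc <- x[, is_control, drop = FALSE]
  xt <- x[, is_treatment, drop = FALSE]
  n1 <- ncol(xc)
  n2 <- ncol(xt)
  if (n1 < 2L || n2 < 2L) {
    stop("each condition needs at least 2 replicate arrays (got ",
         n1, " control, ", n2, " treatment)")
  }
  m1 <- rowMeans(xc)
  m2 <- rowMeans(xt)
  v1 <- .row_vars(xc, m1)
  v2 <- .row_vars(xt, m2)
  diff <- m2 - m1

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    degen <- sp2 < .tsp_var_tol
    sp2[degen] <- var_floor
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    degen <- (v1 + v2) < .tsp_var_tol
    v1[v1 < var_floor & degen] <- var_floor
    v2[v2 < var_floor & degen] <- var_floor
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- diff / se

  if (alternative == "two.sided") {
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    p[degen & abs(diff) < .tsp_var_tol] <- 1
  } else {
    p <- stats::pt(tstat, df = df, lower.tail = FALSE)
    p[degen & abs(diff) < .tsp_var_tol] <- 0.5
  }
  list(statistic = tstat, df = df, p_value = pmin(p, 1),
       mean_control = m1, mean_treatment = m2)
}

.row_vars <- function(x, means = rowMeans(x)) {
  rowSums((x - means)^2) / (ncol(x) - 1L)
}

# Histogram mode of a continuous sample: midpoint of the tallest
# Freedman-Diaconis bin. Diagnostic only; continuous data have no exact mode.
histogram_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids
  mids[which.max(h$counts)]
}

# Benjamini-Hochberg step-up, delegated to stats::p.adjust. Kept as a named
# seam so every module adjusts p-values the same way.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
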