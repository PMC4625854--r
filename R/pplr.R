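#' Normal-theory probability of positive log ratio (PPLR)
#'
#' Combines each class's replicates into a mean log2 expression with a
#' standard error and, under a normal posterior for the case-minus-control
#' difference, reports `PPLR = P(difference > 0) = Phi(delta / sigma)` with
#' `sigma^2` the sum of the two squared standard errors. The p-value-like
#' form follows the convention for this measure: `1 - PPLR` for
#' up-regulated probes and `PPLR` for down-regulated ones, with a fixed
#' significance threshold and no further multiplicity adjustment.
#'
#' This is a summarized-data stand-in for probe-level Bayesian hierarchical
#' models: it keeps the PPLR-to-p-like conversion and thresholding exactly,
#' while the posterior itself is plain normal theory.
#'
#' @param ds An [expression_dataset()].
#' @param threshold Significance threshold on the p-like value
#'   (default 0.01, i.e. a 1 % probability of including false positives).
#'
#' @return A `de_result` tibble with `statistic` (the PPLR), `direction`,
#'   `p_like`, `fdr` (`NA`: the convention applies no adjustment),
#'   `significant` and `method = "PPLR"`.
#' @export
pplr_test <- function(ds, threshold = 0.01) {
  stopifnot(inherits(ds, "expression_dataset"))
  threshold <- check_number(threshold, "threshold", min = 0, max = 1)
  x <- ds$log_exprs
  y <- ds$samples$class
  case <- x[, y == "case", drop = FALSE]
  ctrl <- x[, y == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (min(n1, n2) < 2L) {
    message("a class has a single sample; variance pooled across probes")
    pool_var <- var(as.vector(x - rowMeans(x)))
    v1 <- rep(pool_var, nrow(x)); v2 <- v1
  } else {
    v1 <- rowSums((case - rowMeans(case))^2) / (n1 - 1)
    v2 <- rowSums((ctrl - rowMeans(ctrl))^2) / (n2 - 1)
  }
  delta <- unname(rowMeans(case) - rowMeans(ctrl))
  sigma <- unname(sqrt(v1 / n1 + v2 / n2))
  sigma <- pmax(sigma, .Machine$double.eps)
  pplr <- pnorm(delta / sigma)
  up <- delta >= 0
  res <- tibble(
    probe_id = ds$probes$probe_id,
    gene_id = ds$probes$gene_id,
    statistic = pplr,
    direction = ifelse(up, "up", "down"),
    p_like = ifelse(up, 1 - pplr, pplr),
    fdr = NA_real_,
    significant = ifelse(up, 1 - pplr, pplr) < threshold,
    method = "PPLR"
  )
  new_de_result(res, threshold = threshold)
}
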