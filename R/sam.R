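#' Permutation settings for the resampling-based tests
#'
#' @param n_permutations Number of label/rank permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param delta Optional significance threshold on the statistic (SAM delta);
#'   when `NULL` significance is decided on the estimated FDR instead.
#' @return A `permutation_spec` list.
#' @export
permutation_spec <- function(n_permutations = 1000, seed = 1L, delta = NULL) {
  structure(list(
    n_permutations = check_count(n_permutations, "n_permutations"),
    seed = check_count(seed, "seed", min = 0L),
    delta = if (!is.null(delta)) check_number(delta, "delta", min = 0)
  ), class = "permutation_spec")
}

#' SAM-style moderated difference statistic with permutation FDR
#'
#' Computes, per probe, `d = (mean_case - mean_control) / (s + s0)` where
#' `s` is the pooled standard error and the fudge factor `s0` is the
#' percentile of `s` minimizing the coefficient of variation of the median
#' absolute `d` across windows of `s` (the classic variance-stabilizing
#' choice). Per-probe p-like values come from the pooled permutation null of
#' `|d|` under class-label shuffles; the FDR at each probe's `|d|` threshold
#' is the median number of permuted exceedances divided by the observed
#' count, made monotone.
#'
#' @param ds An [expression_dataset()] (typically after [sam_prefilter()]).
#' @param perm A [permutation_spec()]; its `delta`, when given, overrides the
#'   FDR cutoff for the `significant` flag.
#' @param fdr_cutoff Estimated-FDR threshold for the `significant` flag
#'   (default 0.05).
#'
#' @return A `de_result` tibble: `probe_id`, `gene_id`, `statistic`,
#'   `direction`, `p_like`, `fdr`, `significant`, `method = "SAM"`. The
#'   chosen `s0` is attached as attribute `"s0"`.
#' @export
sam_test <- function(ds, perm = permutation_spec(), fdr_cutoff = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(perm, "permutation_spec"))
  fdr_cutoff <- check_number(fdr_cutoff, "fdr_cutoff", min = 0, max = 1)
  x <- ds$log_exprs
  y <- ds$samples$class
  if (min(table(y)) < 2L) {
    abort("sam_test needs at least 2 samples per class.",
          class = "pdblood_validation_error")
  }
  stat <- sam_stat(x, y)
  s0 <- sam_s0(stat$r, stat$s)
  d <- stat$r / (stat$s + s0)

  b <- perm$n_permutations
  n <- nrow(x)
  d_perm <- with_seed(perm$seed, {
    vapply(seq_len(b), function(i) {
      yp <- sample(y)
      st <- sam_stat(x, yp)
      st$r / (st$s + s0)
    }, numeric(n))
  })

  abs_d <- abs(d)
  # pooled permutation tail p: P(|d*| >= |d_i|)
  pool <- sort(abs(as.vector(d_perm)))
  p_like <- (length(pool) - findInterval(abs_d - 1e-12, pool)) / length(pool)
  p_like <- pmax(p_like, 1 / (length(pool) + 1))

  # estimated FDR at threshold t = |d_i|: median permuted exceedances / called
  ord <- order(abs_d, decreasing = TRUE)
  called <- seq_along(ord)
  exceed <- vapply(seq_len(b), function(i) {
    sp <- sort(abs(d_perm[, i]))
    length(sp) - findInterval(abs_d[ord] - 1e-12, sp)
  }, numeric(n))
  med_false <- apply(exceed, 1L, median)
  fdr_ord <- pmin(med_false / called, 1)
  fdr_ord <- rev(cummin(rev(fdr_ord)))  # monotone in the threshold
  fdr <- numeric(n)
  fdr[ord] <- fdr_ord

  sig <- if (!is.null(perm$delta)) abs_d >= perm$delta else fdr <= fdr_cutoff
  res <- tibble(
    probe_id = ds$probes$probe_id,
    gene_id = ds$probes$gene_id,
    statistic = d,
    direction = ifelse(stat$r >= 0, "up", "down"),
    p_like = p_like,
    fdr = fdr,
    significant = sig,
    method = "SAM"
  )
  new_de_result(res, s0 = s0)
}

# Per-probe mean difference r and pooled standard error s.
sam_stat <- function(x, y) {
  case <- x[, y == "case", drop = FALSE]
  ctrl <- x[, y == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  r <- rowMeans(case) - rowMeans(ctrl)
  ss <- rowSums((case - rowMeans(case))^2) + rowSums((ctrl - rowMeans(ctrl))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(r = unname(r), s = unname(s))
}

# Tusher-style fudge factor: the s-percentile (5 % grid) minimizing the CV of
# the median absolute d across s-quantile windows.
sam_s0 <- function(r, s, n_windows = 20L) {
  if (all(s < .Machine$double.eps)) {
    message("all pooled standard errors are ~0; s0 fallback to 1e-6")
    return(1e-6)
  }
  alphas <- seq(0, 1, by = 0.05)
  qs <- quantile(s, alphas, names = FALSE)
  breaks <- unique(quantile(s, seq(0, 1, length.out = n_windows + 1L),
                            names = FALSE))
  win <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(qs, function(s0) {
    da <- r / (s + s0)
    v <- tapply(abs(da), win, median)
    v <- v[!is.na(v)]
    if (mean(v) < .Machine$double.eps) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  qs[which.min(cv)]
}

# Tag a DE tibble with its class and optional attributes.
new_de_result <- function(tbl, ...) {
  extra <- list(...)
  out <- structure(tbl, class = c("de_result", class(tibble())))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}
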