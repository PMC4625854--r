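# Independent oracle implementations: deliberately naive loop/enumeration
# code, kept apart from the package's own paths.

# Classic (optionally weighted) KS running sum, computed step by step.
oracle_es <- function(ranked, gene_set, scores = NULL, weight = 0) {
  n <- length(ranked)
  if (is.null(scores)) scores <- as.numeric(n:1)
  n_hit <- sum(ranked %in% gene_set)
  denom_hit <- sum(abs(scores[ranked %in% gene_set])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (ranked[i] %in% gene_set) {
      run <- run + abs(scores[i])^weight / denom_hit
    } else {
      run <- run - 1 / (n - n_hit)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Hypergeometric upper tail P(X >= k) by direct summation of choose().
oracle_hyper_tail <- function(k, term_size, universe_size, query_size) {
  if (k <= 0) return(1)
  ks <- k:min(term_size, query_size)
  sum(choose(term_size, ks) *
        choose(universe_size - term_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Hypergeometric upper tail by exhaustive enumeration of all query subsets.
oracle_hyper_enum <- function(k, term, universe, query_size) {
  subsets <- utils::combn(universe, query_size)
  hits <- apply(subsets, 2L, function(s) sum(s %in% term) >= k)
  mean(hits)
}

# All permutations of 1..n (rows), naive recursion.
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    m <- matrix(0L, nrow(sub), n)
    m[, pos] <- n
    m[, -pos] <- sub
    m
  }))
}

# Brute-force rank-product null over all per-comparison rank assignments of
# an n-probe, k-comparison design; returns the pooled sorted null RP values.
oracle_rp_null <- function(n, k) {
  perms <- oracle_perms(n)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nrow(perms))), k)))
  vals <- c()
  for (row in seq_len(nrow(idx))) {
    ranks <- sapply(seq_len(k), function(j) perms[idx[row, j], ])
    vals <- c(vals, exp(rowMeans(log(matrix(ranks, n, k)))))
  }
  sort(vals)
}

# Vectorised per-probe two-sample (pooled-variance) t-test p-values.
oracle_row_t_p <- function(x, labels) {
  a <- x[, labels == "case", drop = FALSE]
  b <- x[, labels == "control", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  va <- rowSums((a - rowMeans(a))^2)
  vb <- rowSums((b - rowMeans(b))^2)
  sp <- sqrt((va + vb) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  t_stat <- (rowMeans(a) - rowMeans(b)) / sp
  2 * pt(abs(t_stat), n1 + n2 - 2, lower.tail = FALSE)
}

# Build a tiny expression dataset from an explicit log2 matrix.
make_dataset <- function(log_exprs, labels, calls = NULL, gene_ids = NULL,
                         truth = NULL) {
  expression_dataset(log_exprs, calls = calls, class_labels = labels,
                     gene_ids = gene_ids, truth = truth)
}

# Dataset whose case/control pairwise log-ratio columns equal `ratios`
# (probes x K matrix), using one case and K controls at baseline 0.
make_ratio_dataset <- function(ratios) {
  n <- nrow(ratios); k <- ncol(ratios)
  le <- cbind(rep(0, n), -ratios, deparse.level = 0)
  # need 2 classes non-empty: 1 case, k controls; case - ctrl_j = ratios[, j]
  rownames(le) <- sprintf("p%02d", seq_len(n))
  colnames(le) <- c("case1", sprintf("ctrl%d", seq_len(k)))
  expression_dataset(le, class_labels = c("case", rep("control", k)))
}
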