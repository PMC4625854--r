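#' Rank Product test over all pairwise case/control comparisons
#'
#' For each of the `K = n_case * n_control` pairwise case-minus-control
#' log-ratios, probes are ranked descending (for up-regulation) and
#' ascending (for down-regulation); the rank product is the geometric mean
#' of a probe's ranks across comparisons. Significance comes from the
#' permutation null obtained by shuffling the ratio values within each
#' comparison: when the full permutation space `(n!)^K` is small
#' (<= `exact_cap` assignments) it is enumerated exhaustively, otherwise
#' `n_permutations` seeded draws are used. The per-probe p-like value is the
#' pooled fraction of null rank products at or below the observed one;
#' `fdr` is the percentage-of-false-prediction estimate `p * n / rank`.
#'
#' @param ds An [expression_dataset()].
#' @param perm A [permutation_spec()].
#' @param max_pairs Cap on the number of pairwise comparisons; above it a
#'   seeded random subset of pairs is used (default 2000).
#' @param pfp_cutoff Significance threshold on the estimated percentage of
#'   false predictions (default 0.05).
#' @param exact_cap Enumerate the null exhaustively while `(n!)^K` stays at
#'   or below this many assignments (default 50000).
#'
#' @return A `de_result` tibble with `statistic` (the rank product in the
#'   probe's direction), `direction`, `p_like`, `fdr` (PFP), `significant`
#'   and `method = "RP"`. Both one-sided rank products are attached as
#'   attribute `"rp_table"`.
#' @export
rank_product_test <- function(ds, perm = permutation_spec(),
                              max_pairs = 2000, pfp_cutoff = 0.05,
                              exact_cap = 50000) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(perm, "permutation_spec"))
  x <- ds$log_exprs
  y <- ds$samples$class
  n <- nrow(x)
  case_idx <- which(y == "case")
  ctrl_idx <- which(y == "control")
  pairs <- expand.grid(case = case_idx, ctrl = ctrl_idx)
  if (nrow(pairs) > max_pairs) {
    message(sprintf("rank_product_test: subsampling %d of %d pairwise comparisons",
                    max_pairs, nrow(pairs)))
    pairs <- with_seed(perm$seed, pairs[sample.int(nrow(pairs), max_pairs), ])
  }
  k <- nrow(pairs)
  ratios <- x[, pairs$case, drop = FALSE] - x[, pairs$ctrl, drop = FALSE]

  rank_desc <- apply(-ratios, 2L, rank, ties.method = "average")
  rank_asc <- apply(ratios, 2L, rank, ties.method = "average")
  rp_up <- unname(exp(rowMeans(log(rank_desc))))
  rp_down <- unname(exp(rowMeans(log(rank_asc))))

  null_rp <- rp_null_values(n, k, perm, exact_cap)
  null_sorted <- sort(null_rp)
  p_of <- function(rp) {
    findInterval(rp + 1e-12, null_sorted) / length(null_sorted)
  }
  p_up <- pmax(p_of(rp_up), 1 / (length(null_sorted) + 1))
  p_down <- pmax(p_of(rp_down), 1 / (length(null_sorted) + 1))

  up <- unname(rowMeans(ratios) >= 0)
  statistic <- ifelse(up, rp_up, rp_down)
  p_like <- ifelse(up, p_up, p_down)
  pfp <- pmin(p_like * n / rank(p_like, ties.method = "min"), 1)

  res <- tibble(
    probe_id = ds$probes$probe_id,
    gene_id = ds$probes$gene_id,
    statistic = statistic,
    direction = ifelse(up, "up", "down"),
    p_like = p_like,
    fdr = pfp,
    significant = pfp <= pfp_cutoff,
    method = "RP"
  )
  new_de_result(res, rp_table = tibble(probe_id = ds$probes$probe_id,
                                       rp_up = rp_up, rp_down = rp_down),
                n_comparisons = k)
}

# Null rank products under within-comparison shuffles. Exhaustive when the
# assignment space is small; otherwise seeded sampling. Returns the pooled
# vector of null RP values (one per probe slot per assignment/draw).
rp_null_values <- function(n, k, perm, exact_cap) {
  n_assign <- factorial(n)^k
  if (is.finite(n_assign) && n_assign <= exact_cap) {
    perms <- all_permutations(n)
    idx <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), k))
    null_rp <- apply(idx, 1L, function(row) {
      ranks <- vapply(seq_len(k), function(j) perms[row[j], ], numeric(n))
      exp(rowMeans(log(matrix(ranks, n, k))))
    })
    as.vector(null_rp)
  } else {
    with_seed(perm$seed + 1L, {
      vals <- replicate(perm$n_permutations, {
        ranks <- vapply(seq_len(k), function(j) sample.int(n), numeric(n))
        exp(rowMeans(log(matrix(ranks, n, k))))
      })
      as.vector(vals)
    })
  }
}

# All permutations of 1..n as rows (n small).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}
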