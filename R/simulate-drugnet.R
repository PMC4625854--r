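#' Simulate a drug network with planted communities
#'
#' Each drug carries a genome-wide ranked transcriptional profile. Drugs of
#' the same community share a latent prototype score vector: a drug's gene
#' scores are `w * prototype + sqrt(1 - w^2) * noise` with
#' `w = within_similarity`, so same-community profiles are rank-correlated at
#' about that level (`w = 1` makes them identical, `w = 0` independent).
#'
#' @param n_drugs Number of compounds.
#' @param n_genes Genes per ranked profile.
#' @param communities Integer vector of community sizes; must sum to
#'   `n_drugs`.
#' @param within_similarity Correlation of same-community profiles, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return A `drug_network`: list with `ranks` (genes x drugs integer matrix,
#'   rank 1 = most up-regulated gene for that drug), `communities` (tibble:
#'   `drug`, `community`) and `genes`.
#' @examples
#' net <- simulate_drug_network(12, 100, communities = c(4, 4, 4),
#'                              within_similarity = 0.9, seed = 1)
#' @export
simulate_drug_network <- function(n_drugs, n_genes, communities,
                                  within_similarity = 0.8, seed = 1L) {
  n_drugs <- check_count(n_drugs, "n_drugs")
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  within_similarity <- check_number(within_similarity, "within_similarity",
                                    min = 0, max = 1)
  seed <- check_count(seed, "seed", min = 0L)
  if (sum(communities) != n_drugs) {
    abort("`communities` sizes must sum to `n_drugs`.",
          class = "pdblood_validation_error")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  comm <- rep(seq_along(communities), communities)
  w <- within_similarity
  with_seed(seed, {
    proto <- matrix(rnorm(n_genes * length(communities)), n_genes)
    scores <- vapply(seq_len(n_drugs), function(d) {
      w * proto[, comm[d]] + sqrt(1 - w^2) * rnorm(n_genes)
    }, numeric(n_genes))
    # rank 1 = highest score (most up-regulated)
    ranks <- apply(-scores, 2L, rank, ties.method = "first")
    dimnames(ranks) <- list(genes, drugs)
    new_drug_network(ranks, tibble(drug = drugs, community = comm))
  })
}

new_drug_network <- function(ranks, communities) {
  stopifnot(is.matrix(ranks), !is.null(rownames(ranks)),
            !is.null(colnames(ranks)))
  communities <- as_tibble(communities)
  if (!all(colnames(ranks) %in% communities$drug) ||
      anyNA(communities$community)) {
    abort("every drug must have a community label.",
          class = "pdblood_validation_error")
  }
  structure(list(ranks = ranks,
                 communities = communities,
                 genes = rownames(ranks)),
            class = "drug_network")
}

#' @export
print.drug_network <- function(x, ...) {
  cat(sprintf("<drug_network> %d drugs x %d genes, %d communities\n",
              ncol(x$ranks), nrow(x$ranks),
              length(unique(x$communities$community))))
  invisible(x)
}

# Ranked gene list (most up-regulated first) for one drug.
drug_signature <- function(net, drug) {
  r <- net$ranks[, drug]
  names(sort(r))
}
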