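#' GSEA-based distance between two ranked signatures
#'
#' A symmetric transcriptional-similarity measure built from enrichment
#' scores: take the `q` most up- and `q` most down-regulated genes of
#' signature `a` as gene sets and score them in signature `b`'s ranked list
#' (unweighted ES), giving `TES_ab = (ES_top - ES_bottom) / 2`; the
#' similarity is the average of `TES_ab` and `TES_ba` and lies in
#' `[-1, 1]`; the distance is `1 - similarity` in `[0, 2]`. Two identical
#' signatures are maximally similar; reversing one of them flips the sign
#' of the similarity.
#'
#' @param a,b Character vectors: ranked gene ids, most up-regulated first,
#'   over a shared gene universe.
#' @param q Extreme-set size (default 250); must be at most half the list
#'   length.
#' @return A single distance in `[0, 2]`; the similarity is attached as
#'   attribute `"similarity"`.
#' @export
signature_distance <- function(a, b, q = 250) {
  q <- check_count(q, "q")
  if (!setequal(a, b)) {
    abort("signatures must share the same gene universe.",
          class = "pdblood_validation_error")
  }
  if (q > length(a) / 2) {
    abort("`q` must be at most half the signature length.",
          class = "pdblood_validation_error")
  }
  tes <- function(from, into) {
    top <- head(from, q)
    bottom <- tail(from, q)
    es_top <- gsea_es(into, top, weight = 0)$es
    es_bot <- gsea_es(into, bottom, weight = 0)$es
    (es_top - es_bot) / 2
  }
  sim <- (tes(a, b) + tes(b, a)) / 2
  structure(1 - sim, similarity = sim)
}

#' Query a drug network with a disease signature
#'
#' Ranks every drug by its signature distance to the disease signature
#' (similar list) and to the reversed disease signature (anti-similar
#' list). Anti-similar drugs up-regulate what the disease down-regulates
#' and vice versa — the candidate-therapeutic direction. Genes absent from
#' the network are dropped from the query with a message.
#'
#' @param net A `drug_network` (see [simulate_drug_network()] or
#'   [read_drug_network()]).
#' @param disease Character vector: ranked disease gene list, most
#'   up-regulated first.
#' @param q Extreme-set size for [signature_distance()].
#' @return A `drugnet_query`: list of two tibbles `similar` and
#'   `anti_similar` (columns `rank`, `drug`, `distance`, `weight` =
#'   1/distance, `community`), each sorted ascending by distance.
#' @export
query_network <- function(net, disease, q = 250) {
  stopifnot(inherits(net, "drug_network"))
  common <- intersect(disease, net$genes)
  if (length(common) < length(disease) || length(common) < length(net$genes)) {
    message(sprintf("query_network: intersected universe of %d genes",
                    length(common)))
  }
  if (length(common) < 2L) {
    abort("disease signature shares too few genes with the network.",
          class = "pdblood_validation_error")
  }
  disease <- disease[disease %in% common]
  q <- min(q, floor(length(common) / 2))
  rank_one <- function(query_sig) {
    d <- vapply(colnames(net$ranks), function(drug) {
      sig <- drug_signature(net, drug)
      sig <- sig[sig %in% common]
      as.numeric(signature_distance(query_sig, sig, q = q))
    }, numeric(1))
    tibble(drug = names(d), distance = unname(d)) |>
      dplyr::arrange(.data$distance, .data$drug) |>
      dplyr::mutate(rank = dplyr::row_number(),
                    weight = 1 / .data$distance) |>
      dplyr::left_join(net$communities, by = "drug") |>
      dplyr::select("rank", "drug", "distance", "weight", "community")
  }
  structure(list(
    similar = rank_one(disease),
    anti_similar = rank_one(rev(disease)),
    q = q
  ), class = "drugnet_query")
}

#' @export
print.drugnet_query <- function(x, ...) {
  cat(sprintf("<drugnet_query> %d drugs ranked (q = %d)\n",
              nrow(x$similar), x$q))
  cat("  top similar:",
      paste(head(x$similar$drug, 3), collapse = ", "), "\n")
  cat("  top anti-similar:",
      paste(head(x$anti_similar$drug, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Community enrichment among top-ranked drugs
#'
#' Hypergeometric upper-tail test of over-representation of one drug
#' community among the `top_k` drugs of a ranking.
#'
#' @param net A `drug_network`.
#' @param ranked_drugs Character vector of drugs, best first (e.g.
#'   `query$similar$drug`), or a `drugnet_query` tibble with a `drug`
#'   column.
#' @param community Community label to test.
#' @param top_k How many top-ranked drugs to consider.
#' @return One-row tibble: `community`, `top_k`, `overlap`, `community_size`,
#'   `p_value`.
#' @export
community_enrichment <- function(net, ranked_drugs, community, top_k) {
  stopifnot(inherits(net, "drug_network"))
  if (is.data.frame(ranked_drugs)) ranked_drugs <- ranked_drugs$drug
  top_k <- check_count(top_k, "top_k")
  if (top_k > length(ranked_drugs)) {
    abort("`top_k` exceeds the number of ranked drugs.",
          class = "pdblood_validation_error")
  }
  members <- net$communities$drug[net$communities$community == community]
  if (!length(members)) {
    abort(sprintf("unknown community '%s'.", community),
          class = "pdblood_validation_error")
  }
  n <- nrow(net$communities)
  top <- head(ranked_drugs, top_k)
  k <- length(intersect(top, members))
  p <- if (k == 0L) 1 else
    phyper(k - 1L, length(members), n - length(members), top_k,
           lower.tail = FALSE)
  tibble(community = community, top_k = top_k, overlap = k,
         community_size = length(members), p_value = p)
}
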