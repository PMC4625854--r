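#' Over-representation test of annotation terms (Fisher / EASE)
#'
#' One-sided hypergeometric upper-tail test of each term's overlap with a
#' query gene set against a gene universe. `mode = "ease"` applies the
#' conservative EASE-score variant: one gene is removed from the overlap
#' before testing, so a single-gene overlap is never significant. P-values
#' are Benjamini-Hochberg adjusted across all tested terms before the
#' output is filtered by minimum overlap and p-value cutoff.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param universe Character vector: the gene universe (conventionally the
#'   genes surviving probe filtering, not the whole array).
#' @param terms A named list of character vectors (term members, e.g. from
#'   [read_gmt()]) or a tibble with columns `term_id`, `term_name`,
#'   `genes` (list-column).
#' @param mode `"fisher"` (plain hypergeometric) or `"ease"`.
#' @param min_count Minimum overlap for a reported row (default 10).
#' @param p_cut Report rows with p-value strictly below this (default 0.02;
#'   any value above 1 reports every term).
#'
#' @return Tibble of `enrichment` rows sorted by ascending p:
#'   `term_id`, `term_name`, `count`, `percent` (of query), `p_value`,
#'   `adjusted_p`.
#' @export
fisher_term_test <- function(query, universe, terms,
                             mode = c("fisher", "ease"),
                             min_count = 10, p_cut = 0.02) {
  mode <- match.arg(mode)
  min_count <- check_count(min_count, "min_count", min = 0L)
  p_cut <- check_number(p_cut, "p_cut", min = 0, strict_min = TRUE)
  query <- unique(query)
  universe <- unique(universe)
  missing <- setdiff(query, universe)
  if (length(missing)) {
    abort(paste0("query genes absent from the universe: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."),
          class = "pdblood_validation_error")
  }
  terms <- as_term_list(terms)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::imap(terms, function(members, id) {
    tm <- intersect(unique(members), universe)
    k <- length(intersect(tm, query))
    m <- length(tm)
    k_test <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- if (k_test == 0L) 1 else
      phyper(k_test - 1L, m, n_u - m, n_q, lower.tail = FALSE)
    tibble(term_id = id, count = k, percent = 100 * k / n_q, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$term_name <- attr(terms, "term_names")[out$term_id] %||% out$term_id
  out$adjusted_p <- bh_adjust(out$p_value)
  out |>
    dplyr::filter(.data$count >= min_count, .data$p_value < p_cut) |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "count", "percent",
                  "p_value", "adjusted_p")
}

# Normalize term input to a named list with a term_names attribute.
as_term_list <- function(terms) {
  if (is.data.frame(terms)) {
    stopifnot(all(c("term_id", "genes") %in% names(terms)))
    lst <- setNames(terms$genes, terms$term_id)
    attr(lst, "term_names") <-
      setNames(terms$term_name %||% terms$term_id, terms$term_id)
    return(lst)
  }
  if (!is.list(terms) || is.null(names(terms))) {
    abort("`terms` must be a named list or a term tibble.",
          class = "pdblood_validation_error")
  }
  nm <- attr(terms, "term_names") %||% setNames(names(terms), names(terms))
  attr(terms, "term_names") <- nm
  terms
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; adjusted values are monotone
#' non-decreasing in the p-value rank and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1].", class = "pdblood_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Preranked GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running sum over a ranked gene list: the
#' running statistic steps up by `|score|^weight` (normalized over the hits)
#' at each gene-set member and down by `1/(N - N_hit)` elsewhere; the
#' enrichment score (ES) is the signed maximum deviation from zero. With
#' `weight = 0` this is the classic unweighted KS statistic. A permutation
#' null (random gene sets of the same size) gives a normalized ES and
#' p-value on request.
#'
#' @param ranked_genes Character vector of gene ids, most up-regulated
#'   first.
#' @param gene_set Character vector; must intersect `ranked_genes`.
#' @param scores Optional numeric vector of ranking scores aligned with
#'   `ranked_genes` (required when `weight > 0`; defaults to `N..1` so the
#'   list order itself acts as the score).
#' @param weight Hit-weighting exponent (default 1).
#' @param n_permutations Gene-label permutations for NES/p (default 0:
#'   score only).
#' @param seed Seed for the permutations.
#'
#' @return A `gsea_result`: list with `es`, `running` (tibble: `position`,
#'   `gene`, `running_es`, `hit`), and when permuted `nes` and `p_value`.
#' @export
gsea_es <- function(ranked_genes, gene_set, scores = NULL, weight = 1,
                    n_permutations = 0, seed = 1L) {
  weight <- check_number(weight, "weight", min = 0)
  if (anyDuplicated(ranked_genes)) {
    abort("`ranked_genes` must be unique.", class = "pdblood_validation_error")
  }
  hits <- ranked_genes %in% gene_set
  if (!any(hits)) {
    abort("`gene_set` does not intersect the ranked list.",
          class = "pdblood_validation_error")
  }
  n <- length(ranked_genes)
  if (is.null(scores)) scores <- as.numeric(n:1)
  if (length(scores) != n) {
    abort("`scores` must align with `ranked_genes`.",
          class = "pdblood_validation_error")
  }
  run <- gsea_running(hits, scores, weight)
  es <- run[which.max(abs(run))]
  out <- list(
    es = es,
    running = tibble(position = seq_len(n), gene = ranked_genes,
                     running_es = run, hit = hits),
    weight = weight
  )
  if (n_permutations > 0) {
    n_hit <- sum(hits)
    null_es <- with_seed(seed, {
      replicate(n_permutations, {
        h <- logical(n)
        h[sample.int(n, n_hit)] <- TRUE
        r <- gsea_running(h, scores, weight)
        r[which.max(abs(r))]
      })
    })
    same_sign <- null_es[sign(null_es) == sign(es)]
    out$nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    # compared within the same-sign null, as is conventional for signed ES
    out$p_value <- (1 + sum(abs(same_sign) >= abs(es))) /
      (1 + length(same_sign))
  }
  structure(out, class = "gsea_result")
}

# Running weighted KS sum for a logical hit vector.
gsea_running <- function(hits, scores, weight) {
  n <- length(hits)
  n_hit <- sum(hits)
  w <- abs(scores)^weight
  up <- ifelse(hits, w / sum(w[hits]), 0)
  down <- ifelse(hits, 0, 1 / (n - n_hit))
  cumsum(up - down)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.3f (weight %g)", x$es, x$weight))
  if (!is.null(x$p_value)) cat(sprintf(", NES = %.2f, p = %.3g",
                                       x$nes, x$p_value))
  cat("\n")
  invisible(x)
}

#' Tidy a GSEA result
#' @param x A `gsea_result`.
#' @param ... Ignored.
#' @return The running-sum tibble.
#' @export
tidy.gsea_result <- function(x, ...) x$running

#' Summarise a GSEA result
#' @param x A `gsea_result`.
#' @param ... Ignored.
#' @return One-row tibble with `es` (and `nes`, `p_value` when permuted).
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(es = x$es, nes = x$nes %||% NA_real_,
         p_value = x$p_value %||% NA_real_)
}
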