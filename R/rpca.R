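#' Ranking-PCA: greedy ranking of variables by discriminant ability
#'
#' Orders variables by how much discriminant ability they add to a
#' PCA-based classifier: at each step every remaining variable is
#' tentatively appended to the selected set, principal components (at most
#' `max_pcs`) are computed on that set, and the candidate is scored by the
#' leave-one-out non-error rate (NER%) of a two-class LDA on the component
#' scores. The best candidate is appended; ties are broken by the larger
#' univariate between/within variance ratio, then by the lexicographically
#' smallest variable id, so the ranking is deterministic.
#'
#' @param x Samples x variables numeric matrix (typically the PLS-DA
#'   preselected columns).
#' @param labels Per-sample class labels (`"case"` / `"control"`).
#' @param max_pcs Maximum principal components for the embedded classifier
#'   (default 6).
#' @param max_rank How many variables to rank (default: all). Larger than
#'   `ncol(x)` is truncated with a warning.
#' @param patience Stop early after this many consecutive steps without
#'   improvement of the LOO NER criterion (default `Inf`: rank to
#'   `max_rank`).
#'
#' @return An `rpca_ranking`: list with `ranking` (tibble: `rank`,
#'   `variable`, `criterion` = LOO NER% after inclusion, `f_ratio`),
#'   `max_pcs`, and `n_selected`.
#' @seealso [plsda_fit_select()], [lda_forward()]
#' @export
rpca_rank <- function(x, labels, max_pcs = 6, max_rank = ncol(x),
                      patience = Inf) {
  stopifnot(is.matrix(x), is.numeric(x))
  max_pcs <- check_count(max_pcs, "max_pcs")
  cls <- as_class_factor(labels)
  if (length(cls) != nrow(x)) {
    abort("`labels` must have one entry per row of `x`.",
          class = "pdblood_validation_error")
  }
  if (max_rank > ncol(x)) {
    warn("`max_rank` exceeds the number of variables; truncated.")
    max_rank <- ncol(x)
  }
  max_rank <- check_count(max_rank, "max_rank")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  y <- as.integer(cls == "case")  # 0 = control, 1 = case

  xc <- scale(x, center = TRUE, scale = FALSE)
  # univariate between/within F ratio, the deterministic tie-break
  f_ratio <- univariate_f(xc, y)

  n <- nrow(xc)
  sel <- integer(0)
  remaining <- seq_len(ncol(xc))
  g_sel <- matrix(0, n, n)
  trace <- numeric(max_rank)
  best_so_far <- -Inf
  stale <- 0L
  order_key <- order(colnames(xc))  # for lexicographic tie-break
  lex <- match(seq_len(ncol(xc)), order_key)

  for (step in seq_len(max_rank)) {
    ner <- cpp_rpca_score(xc, y, g_sel, remaining - 1L, max_pcs)
    # argmax NER, ties -> larger F ratio -> smaller variable id
    best <- order(-ner, -f_ratio[remaining], lex[remaining])[1L]
    j <- remaining[best]
    sel <- c(sel, j)
    remaining <- remaining[-best]
    g_sel <- g_sel + tcrossprod(xc[, j])
    trace[step] <- ner[best]
    if (ner[best] > best_so_far + 1e-9) {
      best_so_far <- ner[best]
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) {
        trace <- trace[seq_len(step)]
        break
      }
    }
    if (length(remaining) == 0L) break
  }

  structure(list(
    ranking = tibble(
      rank = seq_along(sel),
      variable = colnames(xc)[sel],
      criterion = trace[seq_along(sel)],
      f_ratio = f_ratio[sel]
    ),
    max_pcs = max_pcs,
    n_selected = length(sel)
  ), class = "rpca_ranking")
}

# Between/within variance ratio per (centered) column for a 0/1 class vector.
univariate_f <- function(xc, y) {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  m0 <- colMeans(xc[y == 0, , drop = FALSE])
  m1 <- colMeans(xc[y == 1, , drop = FALSE])
  ssb <- n0 * m0^2 + n1 * m1^2
  ssw <- colSums(sweep(xc[y == 0, , drop = FALSE], 2L, m0)^2) +
    colSums(sweep(xc[y == 1, , drop = FALSE], 2L, m1)^2)
  ssb / pmax(ssw, .Machine$double.eps)
}

#' @export
print.rpca_ranking <- function(x, ...) {
  cat(sprintf("<rpca_ranking> %d variables ranked (max %d PCs); final LOO NER %.1f%%\n",
              x$n_selected, x$max_pcs,
              tail(x$ranking$criterion, 1)))
  invisible(x)
}

#' Tidy a Ranking-PCA result
#'
#' @param x An `rpca_ranking`.
#' @param ... Ignored.
#' @return The ranking tibble (`rank`, `variable`, `criterion`, `f_ratio`).
#' @export
tidy.rpca_ranking <- function(x, ...) x$ranking

#' Summarise a Ranking-PCA result
#'
#' @param x An `rpca_ranking`.
#' @param ... Ignored.
#' @return One-row tibble with the number of ranked variables and the best
#'   LOO NER% reached along the ranking.
#' @export
glance.rpca_ranking <- function(x, ...) {
  tibble(n_selected = x$n_selected,
         max_pcs = x$max_pcs,
         best_criterion = max(x$ranking$criterion))
}
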