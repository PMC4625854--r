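#' Principal-component scores of a variable set
#'
#' Centered (not scaled) PCA returning at most `max_pcs` component scores —
#' the representation the LDA stage operates on.
#'
#' @param x Samples x variables numeric matrix.
#' @param max_pcs Maximum number of components (default 6).
#' @return Samples x components score matrix with columns `PC1`, `PC2`, ...
#' @export
pca_scores <- function(x, max_pcs = 6) {
  stopifnot(is.matrix(x), is.numeric(x))
  max_pcs <- check_count(max_pcs, "max_pcs")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = min(max_pcs, dim(xc)), nv = 0)
  k <- min(max_pcs, sum(sv$d > 1e-9 * max(sv$d, 1)))
  s <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(s) <- list(rownames(x), paste0("PC", seq_len(k)))
  s
}

# Wilks' lambda of a two-class LDA on a subset of columns.
wilks_lambda <- function(s, y) {
  if (ncol(s) == 0L) return(1)
  m <- colMeans(s)
  tot <- crossprod(sweep(s, 2L, m))
  w <- matrix(0, ncol(s), ncol(s))
  for (g in unique(y)) {
    sg <- s[y == g, , drop = FALSE]
    w <- w + crossprod(sweep(sg, 2L, colMeans(sg)))
  }
  dw <- det(w); dt <- det(tot)
  if (dt <= 0) return(1)
  max(min(dw / dt, 1), 0)
}

#' LDA with forward selection of principal components
#'
#' Enters principal components one at a time by the Wilks' lambda partial-F
#' test: at each step the component with the smallest entry p-value is added
#' while that p-value is below `alpha`. The final equal-prior LDA (pooled
#' within-class covariance) classifies all samples; the report carries the
#' entry order and p-levels, training and leave-one-out NER%, per-sample
#' squared Mahalanobis distances to both class centroids and predicted
#' labels.
#'
#' @param scores Samples x components numeric matrix (e.g. from
#'   [pca_scores()]).
#' @param labels Per-sample class labels (`"case"` / `"control"`).
#' @param alpha Entry significance threshold on the partial-F p-value
#'   (default 0.01).
#' @param margin Ambiguity margin: samples with
#'   `|d2_own - d2_other| < margin` are flagged (default 1).
#'
#' @return A `classification_report`: list with `selected_pcs` (tibble:
#'   `order`, `pc`, `p_level`), `ner_percent` (training), `ner_loo`,
#'   `samples` (tibble: `sample_id`, `class`, `d2_own`, `d2_other`,
#'   `predicted`, `correct`, `ambiguous`) and the fitted pieces
#'   (`centroids`, `pooled_cov`).
#' @export
lda_forward <- function(scores, labels, alpha = 0.01, margin = 1) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  cls <- as_class_factor(labels)
  y <- as.character(cls)
  n <- nrow(scores)
  if (length(y) != n) {
    abort("`labels` must have one entry per row of `scores`.",
          class = "pdblood_validation_error")
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  g <- 2L

  sel <- integer(0)
  entry <- list()
  lambda_sel <- 1
  remaining <- seq_len(ncol(scores))
  while (length(remaining) > 0L) {
    p_sz <- length(sel)
    df2 <- n - g - p_sz
    if (df2 <= 0L) break
    cand <- vapply(remaining, function(j) {
      lam <- wilks_lambda(scores[, c(sel, j), drop = FALSE], y)
      f <- (lambda_sel / lam - 1) * df2 / (g - 1)
      c(lam, pf(f, g - 1, df2, lower.tail = FALSE))
    }, numeric(2))
    best <- which.min(cand[2, ])
    if (cand[2, best] >= alpha) break
    j <- remaining[best]
    entry[[length(entry) + 1L]] <- tibble(
      order = length(sel) + 1L,
      pc = colnames(scores)[j],
      p_level = cand[2, best]
    )
    lambda_sel <- cand[1, best]
    sel <- c(sel, j)
    remaining <- remaining[-best]
  }
  selected_pcs <- if (length(entry)) dplyr::bind_rows(entry) else
    tibble(order = integer(0), pc = character(0), p_level = numeric(0))

  if (length(sel) == 0L) {
    warn("no principal component passed the entry test; majority-class model.")
    maj <- names(which.max(table(y)))
    samples_tbl <- tibble(
      sample_id = rownames(scores) %||% sprintf("S%03d", seq_len(n)),
      class = y, d2_own = NA_real_, d2_other = NA_real_,
      predicted = maj, correct = y == maj, ambiguous = TRUE
    )
    return(structure(list(
      selected_pcs = selected_pcs,
      ner_percent = 100 * mean(samples_tbl$correct),
      ner_loo = NA_real_,
      samples = samples_tbl,
      centroids = NULL, pooled_cov = NULL, alpha = alpha
    ), class = "classification_report"))
  }

  s_sel <- scores[, sel, drop = FALSE]
  fit <- lda_fit(s_sel, y)
  dist <- mahalanobis_report(s_sel, y, fit, margin = margin)
  ner_loo <- cpp_loo_ner(s_sel, as.integer(y == "case"))

  structure(list(
    selected_pcs = selected_pcs,
    ner_percent = 100 * mean(dist$correct),
    ner_loo = ner_loo,
    samples = dist,
    scores = s_sel,
    centroids = fit$centroids,
    pooled_cov = fit$pooled_cov,
    alpha = alpha
  ), class = "classification_report")
}

# Equal-prior two-class LDA pieces: centroids + pooled within-class
# covariance (ridge-regularized if singular).
lda_fit <- function(s, y) {
  cents <- rbind(control = colMeans(s[y == "control", , drop = FALSE]),
                 case = colMeans(s[y == "case", , drop = FALSE]))
  w <- matrix(0, ncol(s), ncol(s))
  for (gl in c("control", "case")) {
    sg <- s[y == gl, , drop = FALSE]
    w <- w + crossprod(sweep(sg, 2L, colMeans(sg)))
  }
  pooled <- w / (nrow(s) - 2)
  if (rcond(pooled) < 1e-12) {
    eps <- 1e-8 * mean(diag(pooled))
    message(sprintf("singular pooled covariance; ridge eps = %g applied", eps))
    pooled <- pooled + diag(eps, ncol(pooled))
  }
  list(centroids = cents, pooled_cov = pooled)
}

#' Per-sample squared Mahalanobis distances to both class centroids
#'
#' Distances use the pooled within-class covariance of the fitted model;
#' each sample is assigned to the nearer centroid and flagged ambiguous when
#' the two squared distances differ by less than `margin`.
#'
#' @param scores Samples x components matrix the model was fitted on.
#' @param labels True class labels.
#' @param model A list with `centroids` and `pooled_cov` (as produced inside
#'   [lda_forward()]); if `NULL`, fitted from `scores` and `labels`.
#' @param margin Ambiguity margin on `|d2_own - d2_other|` (default 1).
#' @return Tibble: `sample_id`, `class`, `d2_own`, `d2_other`, `predicted`,
#'   `correct`, `ambiguous`.
#' @export
mahalanobis_report <- function(scores, labels, model = NULL, margin = 1) {
  y <- as.character(as_class_factor(labels))
  if (is.null(model)) model <- lda_fit(scores, y)
  d2_ctrl <- mahalanobis(scores, model$centroids["control", ],
                         model$pooled_cov)
  d2_case <- mahalanobis(scores, model$centroids["case", ], model$pooled_cov)
  own <- unname(ifelse(y == "case", d2_case, d2_ctrl))
  other <- unname(ifelse(y == "case", d2_ctrl, d2_case))
  predicted <- unname(ifelse(d2_case <= d2_ctrl, "case", "control"))
  tibble(
    sample_id = rownames(scores) %||% sprintf("S%03d", seq_along(y)),
    class = y,
    d2_own = own,
    d2_other = other,
    predicted = predicted,
    correct = predicted == y,
    ambiguous = abs(own - other) < margin
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d PCs entered (alpha = %g); NER %.1f%% (LOO %.1f%%)\n",
              nrow(x$selected_pcs), x$alpha, x$ner_percent, x$ner_loo))
  if (nrow(x$selected_pcs)) {
    cat("  entry order:",
        paste(sprintf("%s (p=%.2g)", x$selected_pcs$pc,
                      x$selected_pcs$p_level), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a classification report
#'
#' @param x A `classification_report`.
#' @param ... Ignored.
#' @return The per-sample tibble (distances, prediction, correctness).
#' @export
tidy.classification_report <- function(x, ...) x$samples

#' Summarise a classification report
#'
#' @param x A `classification_report`.
#' @param ... Ignored.
#' @return One-row tibble: PCs entered, training NER%, LOO NER%, number of
#'   ambiguous samples.
#' @export
glance.classification_report <- function(x, ...) {
  tibble(n_pcs = nrow(x$selected_pcs),
         ner_percent = x$ner_percent,
         ner_loo = x$ner_loo,
         n_ambiguous = sum(x$samples$ambiguous))
}
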