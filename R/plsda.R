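#' PLS-DA fit with VIP-based variable preselection
#'
#' Fits a NIPALS partial-least-squares model of a binary class code
#' (control = -1, case = +1) on the column-centered variable matrix and
#' ranks variables by their Variable Importance in Projection (VIP). This is
#' the preliminary supervised screen that reduces an array-wide variable set
#' to the order of 10^3 discriminating variables before Ranking-PCA.
#'
#' @param x Samples x variables numeric matrix (log2 expression, samples in
#'   rows). For an [expression_dataset()] use `t(ds$log_exprs)`.
#' @param labels Per-sample class labels (`"case"` / `"control"`).
#' @param max_components Maximum number of latent components (default 6).
#' @param keep How many top-VIP variables to preselect (default
#'   `min(1612, ncol(x))`, the order of magnitude this screen is meant to
#'   return on discovery-scale data).
#' @param scale Autoscale variables to unit variance before fitting
#'   (default `FALSE`: centering only, the log-scale microarray convention).
#'
#' @return A `plsda` object: list with `scores`, `weights`, `loadings`,
#'   `y_loadings`, `vip` (tibble: `variable`, `vip`, `rank`), `selected`
#'   (character vector of the `keep` top-VIP variables) and `n_components`.
#' @seealso [rpca_rank()] for the downstream ranking; [tidy.plsda()].
#' @export
plsda_fit_select <- function(x, labels, max_components = 6,
                             keep = min(1612L, ncol(x)), scale = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  max_components <- check_count(max_components, "max_components")
  keep <- check_count(keep, "keep")
  cls <- as_class_factor(labels)
  if (length(cls) != nrow(x)) {
    abort("`labels` must have one entry per row of `x`.",
          class = "pdblood_validation_error")
  }
  if (nlevels(droplevels(cls)) < 2L) {
    abort("both classes must be present.", class = "pdblood_validation_error")
  }
  if (keep > ncol(x)) {
    abort("`keep` must not exceed the number of variables.",
          class = "pdblood_validation_error")
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  y <- ifelse(cls == "case", 1, -1)

  v_sd <- apply(x, 2L, sd)
  constant <- v_sd == 0
  if (any(constant)) {
    warn(sprintf("%d constant variables excluded from PLS-DA.",
                 sum(constant)))
    x <- x[, !constant, drop = FALSE]
    v_sd <- v_sd[!constant]
  }
  vars <- colnames(x)
  xc <- scale(x, center = TRUE, scale = if (scale) v_sd else FALSE)
  yc <- y - mean(y)

  n <- nrow(xc); p <- ncol(xc)
  a_max <- min(max_components, n - 1L, p)
  W <- P <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max)
  q <- numeric(a_max)
  e_x <- xc; e_y <- yc
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(e_x, e_y)        # X'y: exact one-step NIPALS for PLS1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- as.vector(e_x %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(e_x, t_a) / tt
    q_a <- sum(e_y * t_a) / tt
    e_x <- e_x - tcrossprod(t_a, p_a)
    e_y <- e_y - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) {
    abort("PLS-DA found no usable component (is X constant?).",
          class = "pdblood_validation_error")
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]

  # VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ), SSY_a = q_a^2 t_a't_a
  ssy <- q^2 * colSums(Tm^2)
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  vip_tbl <- tibble(variable = vars, vip = vip) |>
    dplyr::arrange(dplyr::desc(.data$vip), .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(list(
    scores = Tm, weights = W, loadings = P, y_loadings = q,
    y_coding = c(control = -1, case = 1),
    n_components = a_used,
    vip = vip_tbl,
    selected = head(vip_tbl$variable, keep),
    labels = as.character(cls)
  ), class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d components, %d variables, %d preselected\n",
              x$n_components, nrow(x$vip), length(x$selected)))
  invisible(x)
}

#' Tidy a PLS-DA fit
#'
#' @param x A `plsda` object.
#' @param ... Ignored.
#' @return Tibble of per-variable VIP scores with ranks and a `selected`
#'   flag.
#' @export
tidy.plsda <- function(x, ...) {
  x$vip |> dplyr::mutate(selected = .data$variable %in% x$selected)
}

#' Summarise a PLS-DA fit
#'
#' @param x A `plsda` object.
#' @param ... Ignored.
#' @return One-row tibble: components used, variables, preselection size,
#'   mean squared VIP (1 by construction).
#' @export
glance.plsda <- function(x, ...) {
  tibble(n_components = x$n_components,
         n_variables = nrow(x$vip),
         n_selected = length(x$selected),
         mean_sq_vip = mean(x$vip$vip^2))
}
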