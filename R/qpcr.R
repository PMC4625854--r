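#' Build a qPCR plate from a long Cq table
#'
#' @param cq_table Data frame with columns `gene`, `sample`, `group`
#'   (`"case"`/`"control"`) and `cq`.
#' @param reference_genes Character vector of candidate reference genes
#'   present in the table (at least 2 for normalization).
#' @param efficiency Optional named numeric of per-gene amplification
#'   efficiencies (default 2 for every gene; values outside `[1.8, 2.2]`
#'   trigger a warning).
#' @return A `qpcr_plate` tibble.
#' @export
qpcr_plate <- function(cq_table, reference_genes, efficiency = NULL) {
  tbl <- as_tibble(cq_table)
  stopifnot(all(c("gene", "sample", "group", "cq") %in% names(tbl)))
  as_class_factor(tbl$group)
  if (length(reference_genes) < 2L) {
    abort("at least 2 reference genes are required.",
          class = "pdblood_validation_error")
  }
  if (!all(reference_genes %in% tbl$gene)) {
    abort("all reference genes must appear in the Cq table.",
          class = "pdblood_validation_error")
  }
  new_qpcr_plate(tbl, reference_genes = reference_genes,
                 efficiency = efficiency)
}

# Wide gene x sample Cq matrix for a subset of genes.
cq_matrix <- function(plate, genes) {
  sub <- plate[plate$gene %in% genes, , drop = FALSE]
  wide <- tidyr::pivot_wider(as_tibble(sub)[c("gene", "sample", "cq")],
                             names_from = "sample", values_from = "cq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m[genes, , drop = FALSE]
}

#' geNorm reference-gene stability ranking
#'
#' For each candidate gene, the stability value M is the mean over all
#' partner genes of the standard deviation of the pairwise log2 expression
#' ratio across samples (with efficiency 2, the log2 ratio of genes j and k
#' in a sample is `Cq_k - Cq_j`, so only Cq differences enter). The
#' least-stable (highest-M) gene is removed and M recomputed, iterating
#' until the best pair remains.
#'
#' @param plate A `qpcr_plate`.
#' @param candidates Candidate reference genes (default: the plate's
#'   reference set); at least 3.
#' @return A `stability_ranking`: tibble `gene`, `stability` (M at the
#'   round the gene was excluded; the surviving pair shares its final M),
#'   `rank` (1 = most stable), `method = "geNorm"`; the selected pair is in
#'   attribute `"selected_pair"`.
#' @export
genorm_rank <- function(plate, candidates = reference_genes(plate)) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (length(candidates) < 3L) {
    abort("geNorm needs at least 3 candidate genes.",
          class = "pdblood_validation_error")
  }
  eff <- attr(plate, "efficiency")[candidates]
  logq <- -cq_matrix(plate, candidates) * log2(eff)
  remaining <- candidates
  excluded <- character(0)
  m_at_exclusion <- numeric(0)
  final_m <- NULL
  while (length(remaining) > 2L) {
    m <- genorm_m(logq[remaining, , drop = FALSE])
    worst <- names(which.max(m))[1]
    excluded <- c(excluded, worst)
    m_at_exclusion <- c(m_at_exclusion, m[worst])
    remaining <- setdiff(remaining, worst)
  }
  final_m <- genorm_m(logq[remaining, , drop = FALSE])
  genes <- c(remaining[order(final_m)], rev(excluded))
  stab <- c(sort(final_m), rev(m_at_exclusion))
  out <- tibble(gene = genes, stability = unname(stab),
                rank = seq_along(genes), method = "geNorm")
  structure(out, class = c("stability_ranking", class(tibble())),
            selected_pair = sort(remaining))
}

# geNorm M per gene of a log-quantity matrix (genes x samples).
genorm_m <- function(logq) {
  g <- rownames(logq)
  vapply(g, function(j) {
    partners <- setdiff(g, j)
    mean(vapply(partners, function(k) sd(logq[j, ] - logq[k, ]), numeric(1)))
  }, numeric(1))
}

#' NormFinder-style reference-gene stability ranking
#'
#' Model-based stability on log2 quantities: each sample's gene-mean is
#' subtracted (removing the shared loading offset), then per gene the
#' inter-group bias (difference of group means of the centered values) and
#' the intra-group variances are estimated and combined into
#' `stability = sqrt(bias^2 + mean intra-group variance)`. Smaller is more
#' stable; a gene with no group bias and no excess noise scores near 0.
#'
#' @param plate A `qpcr_plate`.
#' @param candidates Candidate reference genes; at least 3.
#' @return A `stability_ranking` tibble (`method = "NormFinder"`) with the
#'   best pair in attribute `"selected_pair"`.
#' @export
normfinder_rank <- function(plate, candidates = reference_genes(plate)) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (length(candidates) < 3L) {
    abort("NormFinder needs at least 3 candidate genes.",
          class = "pdblood_validation_error")
  }
  groups <- plate |>
    as_tibble() |>
    dplyr::distinct(.data$sample, .data$group)
  if (length(unique(groups$group)) < 2L) {
    abort("NormFinder needs both groups on the plate.",
          class = "pdblood_validation_error")
  }
  eff <- attr(plate, "efficiency")[candidates]
  logq <- -cq_matrix(plate, candidates) * log2(eff)
  centered <- sweep(logq, 2L, colMeans(logq))
  grp <- groups$group[match(colnames(centered), groups$sample)]
  stab <- vapply(candidates, function(g) {
    z <- centered[g, ]
    z_case <- z[grp == "case"]; z_ctrl <- z[grp == "control"]
    bias <- mean(z_case) - mean(z_ctrl)
    v_case <- if (length(z_case) > 1L) var(z_case) else NA_real_
    v_ctrl <- if (length(z_ctrl) > 1L) var(z_ctrl) else NA_real_
    if (anyNA(c(v_case, v_ctrl))) {
      message("a group has a single sample; intra-group variance pooled")
      v_case <- v_ctrl <- var(z)
    }
    sqrt(bias^2 + mean(c(v_case, v_ctrl)))
  }, numeric(1))
  ord <- order(stab, candidates)
  out <- tibble(gene = candidates[ord], stability = unname(stab[ord]),
                rank = seq_along(candidates), method = "NormFinder")
  structure(out, class = c("stability_ranking", class(tibble())),
            selected_pair = sort(candidates[ord][1:2]))
}

#' Selected reference pair of a stability ranking
#' @param ranking A `stability_ranking`.
#' @return Character vector of the two selected genes.
#' @export
selected_pair <- function(ranking) attr(ranking, "selected_pair")

#' Relative expression normalized to reference genes
#'
#' Comparative quantification: per gene, the raw quantity of a sample is
#' `Q = efficiency^(Cq_calibrator - Cq_sample)` with the calibrator defined
#' as the pooled healthy-control condition (mean control Cq per gene, the
#' in-silico analogue of a physical control pool). The normalized quantity
#' divides each target's Q by the geometric mean of the reference genes' Q
#' in the same sample; its natural log is reported for plotting and
#' testing.
#'
#' @param plate A `qpcr_plate`.
#' @param targets Target genes to quantify (default: all non-reference
#'   genes on the plate).
#' @param references Reference genes used for normalization (default: the
#'   plate's reference set; at least 2).
#' @return Tibble: `gene`, `sample`, `group`, `rq` (normalized relative
#'   quantity), `log_rq` (natural log).
#' @export
relative_expression <- function(plate,
                                targets = setdiff(unique(plate$gene),
                                                  reference_genes(plate)),
                                references = reference_genes(plate)) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (length(references) < 2L) {
    abort("normalization needs at least 2 reference genes.",
          class = "pdblood_validation_error")
  }
  tbl <- as_tibble(plate)
  n_missing <- sum(!complete.cases(tbl[c("gene", "sample", "cq")]))
  if (n_missing) {
    message(sprintf("dropping %d rows with missing Cq", n_missing))
    tbl <- tbl[complete.cases(tbl[c("gene", "sample", "cq")]), ]
  }
  eff <- attr(plate, "efficiency")
  calib <- tbl |>
    dplyr::filter(.data$group == "control") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cal_cq = mean(.data$cq), .groups = "drop")
  q_tbl <- tbl |>
    dplyr::inner_join(calib, by = "gene") |>
    dplyr::mutate(q = eff[.data$gene]^(.data$cal_cq - .data$cq))
  ref_q <- q_tbl |>
    dplyr::filter(.data$gene %in% references) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ref_geo = exp(mean(log(.data$q))), .groups = "drop")
  q_tbl |>
    dplyr::filter(.data$gene %in% targets) |>
    dplyr::inner_join(ref_q, by = "sample") |>
    dplyr::mutate(rq = .data$q / .data$ref_geo,
                  log_rq = log(.data$rq)) |>
    dplyr::select("gene", "sample", "group", "rq", "log_rq") |>
    dplyr::arrange(.data$gene, .data$sample)
}

#' Per-gene group comparison of normalized quantities
#'
#' Two-sample t-test on the natural-log normalized quantities per target
#' gene, Student by default with a Welch fallback when the group variance
#' ratio exceeds 4. Significance stars follow the usual banding
#' (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param rq Tibble from [relative_expression()] (columns `gene`, `group`,
#'   `log_rq`).
#' @return Tibble: `gene`, `ln_mean_case`, `ln_mean_control`, `ratio`
#'   (case/control on the linear scale), `p_value`, `stars`.
#' @export
group_compare <- function(rq) {
  rq <- as_tibble(rq)
  stopifnot(all(c("gene", "group", "log_rq") %in% names(rq)))
  rq |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      a <- df$log_rq[df$group == "case"]
      b <- df$log_rq[df$group == "control"]
      if (length(a) < 2L || length(b) < 2L) {
        abort("both groups need at least 2 samples per gene.",
              class = "pdblood_validation_error")
      }
      vr <- max(var(a), var(b)) / max(min(var(a), var(b)),
                                      .Machine$double.eps)
      welch <- vr > 4
      if (welch) message(sprintf("%s: variance ratio %.1f, Welch t-test used",
                                 key$gene, vr))
      p <- if (var(a) + var(b) < 1e-20) {
        # both groups noiseless: identical means or a certain difference
        if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
      } else {
        t.test(a, b, var.equal = !welch)$p.value
      }
      tibble(
        ln_mean_case = mean(a),
        ln_mean_control = mean(b),
        ratio = exp(mean(a) - mean(b)),
        p_value = p,
        stars = stars_for(p)
      )
    }) |>
    dplyr::ungroup()
}

stars_for <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}
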