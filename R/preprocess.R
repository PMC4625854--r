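#' Probe filtering parameters
#'
#' @param intensity_floor Linear-scale intensity floor (default 100, i.e. a
#'   log2 intensity of log2(100)).
#' @param drop_poor_call_in_all Drop probes whose detection call is
#'   non-Present in every sample.
#' @param require_all_samples_below Drop on intensity only when the probe is
#'   below the floor in *all* samples (the conservative reading used here).
#' @param sam_prefilter_min_fraction Fraction of the smaller class that must
#'   pass Present-and-above-floor in [sam_prefilter()] (default 0.5, "at
#'   least half").
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(intensity_floor = 100,
                        drop_poor_call_in_all = TRUE,
                        require_all_samples_below = TRUE,
                        sam_prefilter_min_fraction = 0.5) {
  structure(list(
    intensity_floor = check_number(intensity_floor, "intensity_floor",
                                   min = 0, strict_min = TRUE),
    drop_poor_call_in_all = check_flag(drop_poor_call_in_all,
                                       "drop_poor_call_in_all"),
    require_all_samples_below = check_flag(require_all_samples_below,
                                           "require_all_samples_below"),
    sam_prefilter_min_fraction = check_number(sam_prefilter_min_fraction,
                                              "sam_prefilter_min_fraction",
                                              min = 0, max = 1,
                                              strict_min = TRUE)
  ), class = "filter_spec")
}

#' Filter probes by detection call and intensity
#'
#' Removes probes whose detection call is non-Present in every sample, and
#' probes whose linear intensity stays below the floor (default 100) in
#' every sample. Probe order is preserved; retained/removed counts are
#' attached as the `"filter_counts"` attribute and reported via a message.
#'
#' @param ds An [expression_dataset()].
#' @param spec A [filter_spec()].
#' @return The filtered `expression_dataset`.
#' @export
filter_probes <- function(ds, spec = filter_spec()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(spec, "filter_spec"))
  lin <- intensities(ds)
  keep <- rep(TRUE, nrow(lin))
  if (spec$drop_poor_call_in_all) {
    keep <- keep & rowSums(ds$calls == "P") > 0L
  }
  below_all <- rowSums(lin >= spec$intensity_floor) == 0L
  keep <- keep & !below_all
  if (!any(keep)) {
    warn("filter_probes removed every probe.")
  }
  out <- ds[keep, ]
  message(sprintf("filter_probes: retained %d / %d probes",
                  sum(keep), length(keep)))
  attr(out, "filter_counts") <- c(retained = sum(keep),
                                  removed = sum(!keep))
  out
}

#' SAM prefilter
#'
#' Retains probes that are Present with linear intensity above the floor in
#' at least `ceil(fraction * n_smaller)` arrays of the smaller class
#' (default: at least half of the smaller group).
#'
#' @inheritParams filter_probes
#' @return The filtered `expression_dataset`.
#' @export
sam_prefilter <- function(ds, spec = filter_spec()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(spec, "filter_spec"))
  cls <- ds$samples$class
  sizes <- table(cls)
  smaller <- names(sizes)[which.min(sizes)]
  idx <- which(cls == smaller)
  need <- ceiling(spec$sam_prefilter_min_fraction * length(idx))
  lin <- intensities(ds)[, idx, drop = FALSE]
  ok <- (ds$calls[, idx, drop = FALSE] == "P") & (lin > spec$intensity_floor)
  keep <- rowSums(ok) >= need
  out <- ds[keep, ]
  message(sprintf("sam_prefilter: retained %d / %d probes (smaller class %s, n=%d, need %d)",
                  sum(keep), length(keep), smaller, length(idx), need))
  attr(out, "filter_counts") <- c(retained = sum(keep),
                                  removed = sum(!keep))
  out
}

#' Quantile normalization of a log-scale matrix
#'
#' Forces every column (array) to share the same empirical distribution: the
#' k-th largest value in each column becomes the mean of the k-th largest
#' values across columns. Row order and within-column ranks are preserved.
#' Ties receive the mean of the reference values they span.
#'
#' @param log_matrix Numeric matrix (probes x samples), no missing values,
#'   at least 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(log_matrix) {
  stopifnot(is.matrix(log_matrix), is.numeric(log_matrix))
  if (ncol(log_matrix) < 2L) {
    abort("quantile normalization needs at least 2 columns.",
          class = "pdblood_validation_error")
  }
  if (anyNA(log_matrix)) {
    abort("missing values are not allowed.",
          class = "pdblood_validation_error")
  }
  ref <- rowMeans(apply(log_matrix, 2L, sort))
  out <- apply(log_matrix, 2L, function(col) {
    x <- numeric(length(col))
    x[order(col)] <- ref
    # tied input values share the mean of the reference values they span
    if (anyDuplicated(col)) x <- stats::ave(x, col, FUN = mean)
    x
  })
  dimnames(out) <- dimnames(log_matrix)
  out
}

#' Median global array scaling
#'
#' Shifts each column (log scale) so its median equals the global median of
#' the input matrix. Idempotent.
#'
#' @param log_matrix Numeric matrix with at least one column.
#' @return Matrix of the same shape.
#' @export
median_scale <- function(log_matrix) {
  stopifnot(is.matrix(log_matrix), is.numeric(log_matrix),
            ncol(log_matrix) >= 1L)
  global <- median(log_matrix)
  meds <- apply(log_matrix, 2L, median)
  sweep(log_matrix, 2L, meds - global)
}

#' Normalize an expression dataset
#'
#' Convenience wrapper applying [quantile_normalize()] then [median_scale()]
#' to the log2 matrix of a dataset (the summarized-data analogue of
#' RMA-style between-array normalization followed by median global array
#' scaling).
#'
#' @param ds An [expression_dataset()].
#' @return The normalized `expression_dataset` (calls and annotation kept).
#' @export
normalize_arrays <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds$log_exprs <- median_scale(quantile_normalize(ds$log_exprs))
  ds
}

#' Collapse probes to genes
#'
#' Keeps one representative probe per gene: the probe with the highest mean
#' log2 intensity (ties broken by lexicographically smallest probe id).
#' Probes without gene annotation (`NA` or empty gene id) are kept under
#' their probe id and flagged.
#'
#' @param ds An [expression_dataset()].
#' @return An `expression_dataset` with one row per gene; the probe-to-gene
#'   mapping used is attached as attribute `"collapse_map"` (tibble:
#'   `gene_id`, `probe_id`, `mean_log2`).
#' @export
collapse_to_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  gene <- ds$probes$gene_id
  unannotated <- is.na(gene) | gene == ""
  if (any(unannotated)) {
    warn(sprintf("%d probes lack gene annotation; kept under their probe id.",
                 sum(unannotated)))
    gene[unannotated] <- ds$probes$probe_id[unannotated]
  }
  map <- tibble(
    gene_id = gene,
    probe_id = ds$probes$probe_id,
    mean_log2 = rowMeans(ds$log_exprs)
  ) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$mean_log2),
                   .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  keep <- match(map$probe_id, ds$probes$probe_id)
  out <- ds[keep, ]
  out$probes$gene_id <- map$gene_id
  attr(out, "collapse_map") <- map
  out
}
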