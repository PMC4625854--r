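#' Expression dataset container
#'
#' Bundles a probes-by-samples log2 expression matrix with Present/Marginal/
#' Absent detection calls, per-sample class labels and a probe-to-gene map.
#' This is the object every pipeline stage consumes and returns; linear-scale
#' intensities are always derived as `2^log2` so the two scales cannot drift
#' apart.
#'
#' @param log_exprs Numeric matrix of log2 intensities, probes in rows,
#'   samples in columns. Row names are probe ids, column names sample ids.
#' @param calls Character matrix of the same shape with entries `"P"`
#'   (Present), `"M"` (Marginal) or `"A"` (Absent). Defaults to all-Present.
#' @param class_labels Character vector, one of `"case"`/`"control"` per
#'   sample (column).
#' @param gene_ids Character vector of gene symbols, one per probe. Probes
#'   may share a gene. Defaults to the probe ids.
#' @param truth Optional character vector per probe in
#'   `c("spiked-up", "spiked-down", "null")`; recorded by the simulator.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `log_exprs`, `calls`, `samples` (tibble: `sample_id`, `class`) and
#'   `probes` (tibble: `probe_id`, `gene_id`, optionally `truth`).
#' @seealso [simulate_cohort()], [filter_probes()], [tidy.expression_dataset()]
#' @export
expression_dataset <- function(log_exprs, calls = NULL, class_labels,
                               gene_ids = NULL, truth = NULL) {
  if (!is.matrix(log_exprs) || !is.numeric(log_exprs)) {
    abort("`log_exprs` must be a numeric matrix.",
          class = "pdblood_validation_error")
  }
  if (is.null(rownames(log_exprs))) {
    rownames(log_exprs) <- sprintf("probe_%04d", seq_len(nrow(log_exprs)))
  }
  if (is.null(colnames(log_exprs))) {
    colnames(log_exprs) <- sprintf("S%03d", seq_len(ncol(log_exprs)))
  }
  if (anyDuplicated(rownames(log_exprs))) {
    abort("probe ids (rownames) must be unique.",
          class = "pdblood_validation_error")
  }
  if (is.null(calls)) {
    calls <- matrix("P", nrow(log_exprs), ncol(log_exprs),
                    dimnames = dimnames(log_exprs))
  }
  if (!identical(dim(calls), dim(log_exprs))) {
    abort("`calls` must have the same shape as `log_exprs`.",
          class = "pdblood_validation_error")
  }
  if (!all(calls %in% c("P", "M", "A"))) {
    abort("`calls` entries must be 'P', 'M' or 'A'.",
          class = "pdblood_validation_error")
  }
  dimnames(calls) <- dimnames(log_exprs)
  if (length(class_labels) != ncol(log_exprs)) {
    abort("`class_labels` must have one entry per sample.",
          class = "pdblood_validation_error")
  }
  cls <- as_class_factor(class_labels)
  if (nlevels(droplevels(cls)) < 2L) {
    abort("both classes (case and control) must be non-empty.",
          class = "pdblood_validation_error")
  }
  gene_ids <- gene_ids %||% rownames(log_exprs)
  if (length(gene_ids) != nrow(log_exprs)) {
    abort("`gene_ids` must have one entry per probe.",
          class = "pdblood_validation_error")
  }
  probes <- tibble(probe_id = rownames(log_exprs), gene_id = gene_ids)
  if (!is.null(truth)) {
    if (length(truth) != nrow(log_exprs) ||
        !all(truth %in% c("spiked-up", "spiked-down", "null"))) {
      abort("`truth` must be per-probe in {spiked-up, spiked-down, null}.",
            class = "pdblood_validation_error")
    }
    probes$truth <- truth
  }
  structure(
    list(
      log_exprs = log_exprs,
      calls = calls,
      samples = tibble(sample_id = colnames(log_exprs),
                       class = as.character(cls)),
      probes = probes
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  n_case <- sum(x$samples$class == "case")
  n_ctrl <- sum(x$samples$class == "control")
  cat(sprintf("<expression_dataset> %d probes x %d samples (%d case / %d control)\n",
              nrow(x$log_exprs), ncol(x$log_exprs), n_case, n_ctrl))
  cat(sprintf("  detection calls: %s\n",
              paste(sprintf("%s=%d", c("P", "M", "A"),
                            c(sum(x$calls == "P"), sum(x$calls == "M"),
                              sum(x$calls == "A"))), collapse = " ")))
  if ("truth" %in% names(x$probes)) {
    cat(sprintf("  spiked probes: %d up, %d down\n",
                sum(x$probes$truth == "spiked-up"),
                sum(x$probes$truth == "spiked-down")))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$log_exprs)

#' Linear-scale intensities of an expression dataset
#'
#' @param ds An [expression_dataset()].
#' @return Numeric matrix `2^log_exprs`.
#' @export
intensities <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  2^ds$log_exprs
}

#' Subset an expression dataset by probe and/or sample
#'
#' @param x An [expression_dataset()].
#' @param i Probe index (integer, logical or probe-id character vector).
#' @param j Sample index.
#' @param ... Ignored.
#' @return The subset, still an `expression_dataset`.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$log_exprs))
  if (missing(j)) j <- seq_len(ncol(x$log_exprs))
  le <- x$log_exprs[i, j, drop = FALSE]
  expression_dataset(
    log_exprs = le,
    calls = x$calls[i, j, drop = FALSE],
    class_labels = x$samples$class[match(colnames(le), x$samples$sample_id)],
    gene_ids = x$probes$gene_id[match(rownames(le), x$probes$probe_id)],
    truth = if ("truth" %in% names(x$probes))
      x$probes$truth[match(rownames(le), x$probes$probe_id)]
  )
}

#' Tidy an expression dataset into long format
#'
#' One row per (probe, sample) with log2 intensity, detection call, class and
#' gene annotation — convenient for dplyr/ggplot2 work.
#'
#' @param x An [expression_dataset()].
#' @param ... Ignored.
#' @return A tibble with columns `probe_id`, `gene_id`, `sample_id`, `class`,
#'   `log2_intensity`, `call`.
#' @export
tidy.expression_dataset <- function(x, ...) {
  long <- tibble(
    probe_id = rep(rownames(x$log_exprs), times = ncol(x$log_exprs)),
    sample_id = rep(colnames(x$log_exprs), each = nrow(x$log_exprs)),
    log2_intensity = as.vector(x$log_exprs),
    call = as.vector(x$calls)
  )
  long |>
    dplyr::left_join(x$probes, by = "probe_id") |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::select("probe_id", "gene_id", "sample_id", "class",
                  "log2_intensity", "call")
}

#' Summarise an expression dataset
#'
#' @param x An [expression_dataset()].
#' @param ... Ignored.
#' @return One-row tibble with dimensions, class sizes and call fractions.
#' @export
glance.expression_dataset <- function(x, ...) {
  tibble(
    n_probes = nrow(x$log_exprs),
    n_samples = ncol(x$log_exprs),
    n_case = sum(x$samples$class == "case"),
    n_control = sum(x$samples$class == "control"),
    frac_present = mean(x$calls == "P"),
    n_spiked = if ("truth" %in% names(x$probes))
      sum(x$probes$truth != "null") else NA_integer_
  )
}
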