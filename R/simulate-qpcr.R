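#' Simulate an RT-qPCR plate with planted reference-gene stabilities
#'
#' Generates Cq values under the additive model
#' `Cq = gene baseline + per-sample loading offset + group shift + noise`.
#' The per-sample loading offset (pipetting / input-amount variation) is
#' shared by every gene on a sample, so it cancels under reference-gene
#' normalization. Reference genes carry no group shift; their designed extra
#' noise (`ref_stabilities`) plants a known stability ordering that
#' [genorm_rank()] and [normfinder_rank()] should recover.
#'
#' @param n_cases,n_controls Samples per group.
#' @param gene_specs Data frame (or tibble) of target genes with columns
#'   `gene`, `group_shift_cq` (Cq shift added to cases; negative means
#'   higher expression in cases) and `noise_sd`.
#' @param ref_stabilities Data frame of candidate reference genes with
#'   columns `gene` and `noise_sd`; at least two rows.
#' @param baseline_cq Named numeric of per-gene baseline Cq; genes absent
#'   from it get staggered defaults starting at 22 cycles.
#' @param loading_sd Sd of the shared per-sample loading offset (cycles).
#' @param seed Integer seed.
#'
#' @return A `qpcr_plate`: a tibble with columns `gene`, `sample`, `group`,
#'   `cq`, carrying attributes `reference_genes` (the candidate reference
#'   set) and `efficiency` (per-gene amplification efficiency, default 2).
#' @examples
#' plate <- simulate_qpcr_plate(
#'   gene_specs = data.frame(gene = "TCF3", group_shift_cq = -1, noise_sd = 0.3),
#'   ref_stabilities = data.frame(gene = c("PGK1", "UBC", "GAPDH"),
#'                                noise_sd = c(0.05, 0.05, 0.6)),
#'   seed = 3)
#' @export
simulate_qpcr_plate <- function(n_cases = 12, n_controls = 12,
                                gene_specs,
                                ref_stabilities,
                                baseline_cq = NULL,
                                loading_sd = 0.5,
                                seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  seed <- check_count(seed, "seed", min = 0L)
  gene_specs <- as_tibble(gene_specs)
  ref_stabilities <- as_tibble(ref_stabilities)
  stopifnot(all(c("gene", "group_shift_cq", "noise_sd") %in% names(gene_specs)),
            all(c("gene", "noise_sd") %in% names(ref_stabilities)))
  if (nrow(ref_stabilities) < 2L) {
    abort("at least 2 candidate reference genes are required.",
          class = "pdblood_validation_error")
  }
  if (any(gene_specs$noise_sd < 0) || any(ref_stabilities$noise_sd < 0)) {
    abort("noise sds must be non-negative.",
          class = "pdblood_validation_error")
  }
  genes <- c(gene_specs$gene, ref_stabilities$gene)
  if (anyDuplicated(genes)) {
    abort("gene names must be unique across targets and references.",
          class = "pdblood_validation_error")
  }
  base <- setNames(22 + 0.7 * (seq_along(genes) - 1L), genes)
  if (!is.null(baseline_cq)) base[names(baseline_cq)] <- baseline_cq
  n <- n_cases + n_controls
  samples <- c(sprintf("PD%02d", seq_len(n_cases)),
               sprintf("HC%02d", seq_len(n_controls)))
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  shift <- setNames(c(gene_specs$group_shift_cq,
                      rep(0, nrow(ref_stabilities))), genes)
  noise <- setNames(c(gene_specs$noise_sd, ref_stabilities$noise_sd), genes)
  with_seed(seed, {
    loading <- rnorm(n, 0, loading_sd)
    rows <- tidyr::expand_grid(gene = genes, idx = seq_len(n))
    cq <- base[rows$gene] + loading[rows$idx] +
      ifelse(group[rows$idx] == "case", shift[rows$gene], 0) +
      rnorm(nrow(rows), 0, noise[rows$gene])
    plate <- tibble(
      gene = rows$gene,
      sample = samples[rows$idx],
      group = group[rows$idx],
      cq = as.numeric(cq)
    )
    new_qpcr_plate(plate, reference_genes = ref_stabilities$gene)
  })
}

new_qpcr_plate <- function(tbl, reference_genes, efficiency = NULL) {
  genes <- unique(tbl$gene)
  eff <- setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiency)) eff[names(efficiency)] <- efficiency
  if (any(eff < 1.8 | eff > 2.2)) {
    warn("amplification efficiency outside [1.8, 2.2]; check assay quality.")
  }
  structure(tbl, class = c("qpcr_plate", class(tibble())),
            reference_genes = reference_genes, efficiency = eff)
}

#' Candidate reference genes of a qPCR plate
#' @param plate A `qpcr_plate`.
#' @return Character vector of reference gene names.
#' @export
reference_genes <- function(plate) attr(plate, "reference_genes")
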