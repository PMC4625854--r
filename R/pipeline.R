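#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis in one
#' validated list. Unknown keys are rejected so typos cannot silently fall
#' back to defaults; every stochastic stage has its seed derived from the
#' single `seed` entry.
#'
#' @param seed Master seed for all stochastic stages.
#' @param filter_floor Linear intensity floor for probe filtering.
#' @param sam_fraction Smaller-class fraction for the SAM prefilter.
#' @param plsda_keep Variables kept by the PLS-DA preselection.
#' @param max_pcs Component cap for Ranking-PCA and the LDA chain.
#' @param rpca_max_rank Variables ranked by Ranking-PCA.
#' @param alpha Entry threshold for LDA forward selection.
#' @param n_permutations Permutations for SAM and Rank Product.
#' @param sam_fdr SAM significance cutoff on estimated FDR.
#' @param rp_pfp Rank Product significance cutoff on estimated PFP.
#' @param pplr_threshold PPLR p-like significance threshold.
#' @param ... Must be empty; present to catch unknown keys.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, filter_floor = 100,
                            sam_fraction = 0.5, plsda_keep = 200L,
                            max_pcs = 6L, rpca_max_rank = 50L,
                            alpha = 0.01, n_permutations = 100L,
                            sam_fdr = 0.05, rp_pfp = 0.05,
                            pplr_threshold = 0.01, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("unknown configuration keys: ",
                 paste(names(extra), collapse = ", ")),
          class = "pdblood_validation_error")
  }
  structure(list(
    seed = check_count(seed, "seed", min = 0L),
    filter_floor = check_number(filter_floor, "filter_floor", min = 0,
                                strict_min = TRUE),
    sam_fraction = check_number(sam_fraction, "sam_fraction", min = 0,
                                max = 1, strict_min = TRUE),
    plsda_keep = check_count(plsda_keep, "plsda_keep"),
    max_pcs = check_count(max_pcs, "max_pcs"),
    rpca_max_rank = check_count(rpca_max_rank, "rpca_max_rank"),
    alpha = check_number(alpha, "alpha", min = 0, max = 1),
    n_permutations = check_count(n_permutations, "n_permutations"),
    sam_fdr = check_number(sam_fdr, "sam_fdr", min = 0, max = 1),
    rp_pfp = check_number(rp_pfp, "rp_pfp", min = 0, max = 1),
    pplr_threshold = check_number(pplr_threshold, "pplr_threshold",
                                  min = 0, max = 1)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline on an expression dataset
#'
#' Executes preprocess (filter, normalize), the classification chain
#' (PLS-DA preselection, Ranking-PCA, LDA forward selection), the three
#' differential-expression procedures, their gene-level intersection, and
#' optional term enrichment of the intersection, writing versioned TSV
#' outputs plus a machine-readable JSON manifest (parameters, seeds and
#' counts at every stage) into `out_dir`. Rerunning with the same dataset
#' and config reproduces the manifest byte for byte.
#'
#' @param ds An [expression_dataset()] (e.g. from [simulate_cohort()] or
#'   [read_expression_dataset()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param terms Optional annotation sets (see [fisher_term_test()]) to
#'   enrich the intersection against the filtered-gene universe.
#' @return A `pipeline_run` list: `filtered`, `plsda`, `rpca`, `report`,
#'   `de` (list of the three `de_result`s), `intersection`, `enrichment`
#'   (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), out_dir = NULL,
                         terms = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "pdblood_stage_error")
    })
  }

  fspec <- filter_spec(intensity_floor = config$filter_floor,
                       sam_prefilter_min_fraction = config$sam_fraction)
  filtered <- stage("preprocess", {
    normalize_arrays(filter_probes(ds, fspec))
  })

  x <- t(filtered$log_exprs)
  labels <- filtered$samples$class
  plsda <- stage("plsda", {
    plsda_fit_select(x, labels, max_components = config$max_pcs,
                     keep = min(config$plsda_keep, ncol(x)))
  })
  rpca <- stage("rpca", {
    rpca_rank(x[, plsda$selected, drop = FALSE], labels,
              max_pcs = config$max_pcs,
              max_rank = min(config$rpca_max_rank, length(plsda$selected)))
  })
  report <- stage("lda", {
    sel <- rpca$ranking$variable
    lda_forward(pca_scores(x[, sel, drop = FALSE], config$max_pcs),
                labels, alpha = config$alpha)
  })

  perm <- permutation_spec(n_permutations = config$n_permutations,
                           seed = config$seed)
  de <- stage("diffexpr", {
    list(
      sam = sam_test(sam_prefilter(filtered, fspec), perm,
                     fdr_cutoff = config$sam_fdr),
      rp = rank_product_test(filtered, perm, pfp_cutoff = config$rp_pfp),
      pplr = pplr_test(filtered, threshold = config$pplr_threshold)
    )
  })
  intersection <- stage("intersect", {
    intersect_signatures(unname(de), level = "gene")
  })
  enrichment <- if (!is.null(terms)) stage("enrichment", {
    universe <- unique(filtered$probes$gene_id)
    fisher_term_test(intersect(intersection$id, universe), universe, terms,
                     mode = "ease", min_count = 1, p_cut = 1)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("pdblood")),
    config = unclass(config),
    counts = list(
      probes_in = nrow(ds$log_exprs),
      probes_filtered = nrow(filtered$log_exprs),
      variables_preselected = length(plsda$selected),
      variables_ranked = rpca$n_selected,
      pcs_entered = nrow(report$selected_pcs),
      ner_percent = report$ner_percent,
      significant = lapply(de, function(r) sum(r$significant)),
      intersection_genes = nrow(intersection)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(tidy(rpca), file.path(out_dir, "ranking.tsv"))
    write_tsv_plain(tidy(report), file.path(out_dir, "classification.tsv"))
    for (m in names(de)) {
      write_tsv_plain(as_tibble(de[[m]]),
                      file.path(out_dir, sprintf("de_%s.tsv", m)))
    }
    write_tsv_plain(intersection, file.path(out_dir, "intersection.tsv"))
    if (!is.null(enrichment)) {
      write_tsv_plain(enrichment, file.path(out_dir, "enrichment.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(filtered = filtered, plsda = plsda, rpca = rpca,
                 report = report, de = de, intersection = intersection,
                 enrichment = enrichment, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<pipeline_run>\n")
  cat(sprintf("  probes: %d -> %d after filtering\n",
              cnt$probes_in, cnt$probes_filtered))
  cat(sprintf("  classification: %d PCs, NER %.1f%%\n",
              cnt$pcs_entered, cnt$ner_percent))
  cat(sprintf("  significant probes: SAM %d, RP %d, PPLR %d; intersection %d genes\n",
              cnt$significant$sam, cnt$significant$rp, cnt$significant$pplr,
              cnt$intersection_genes))
  invisible(x)
}
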