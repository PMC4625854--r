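# Plain-TSV interchange: tab-separated, '#' comment lines, UTF-8, no
# quoting. Every writer here round-trips through its reader.

read_tsv_plain <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

write_tsv_plain <- function(tbl, path) {
  readr::write_tsv(tbl, path, quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Write an expression dataset as four TSV files
#'
#' Emits `matrix.tsv` (probe_id + one log2 column per sample), `calls.tsv`
#' (same shape), `samples.tsv` (`sample_id`, `class`) and `probes.tsv`
#' (`probe_id`, `gene_id` and `truth` when present) into a directory.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- as_tibble(ds$log_exprs, rownames = "probe_id")
  write_tsv_plain(mat, file.path(dir, "matrix.tsv"))
  calls <- as_tibble(ds$calls, rownames = "probe_id")
  write_tsv_plain(calls, file.path(dir, "calls.tsv"))
  write_tsv_plain(ds$samples, file.path(dir, "samples.tsv"))
  write_tsv_plain(ds$probes, file.path(dir, "probes.tsv"))
  invisible(dir)
}

#' Read an expression dataset written by [write_expression_dataset()]
#'
#' @param dir Directory containing `matrix.tsv`, `calls.tsv`, `samples.tsv`
#'   and `probes.tsv`.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(dir) {
  mat <- read_tsv_plain(file.path(dir, "matrix.tsv"))
  le <- as.matrix(mat[, -1])
  rownames(le) <- mat$probe_id
  calls <- read_tsv_plain(file.path(dir, "calls.tsv"))
  cm <- as.matrix(calls[, -1])
  rownames(cm) <- calls$probe_id
  samples <- read_tsv_plain(file.path(dir, "samples.tsv"))
  probes <- read_tsv_plain(file.path(dir, "probes.tsv"))
  ord_p <- match(rownames(le), probes$probe_id)
  expression_dataset(
    log_exprs = le,
    calls = cm[rownames(le), colnames(le), drop = FALSE],
    class_labels = samples$class[match(colnames(le), samples$sample_id)],
    gene_ids = probes$gene_id[ord_p],
    truth = if ("truth" %in% names(probes)) probes$truth[ord_p]
  )
}

#' Write / read a qPCR plate as long-format TSV
#'
#' Columns `gene`, `sample`, `group`, `cq`; the candidate reference genes
#' are recorded in a `# reference_genes:` comment header so the file is
#' self-contained.
#'
#' @param plate A `qpcr_plate`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `qpcr_plate` (reader).
#' @export
write_qpcr_plate <- function(plate, path) {
  stopifnot(inherits(plate, "qpcr_plate"))
  header <- sprintf("# reference_genes: %s",
                    paste(reference_genes(plate), collapse = ","))
  writeLines(header, path)
  readr::write_tsv(as_tibble(plate), path, append = TRUE, col_names = TRUE,
                   quote = "none", escape = "none", progress = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_plate
#' @export
read_qpcr_plate <- function(path) {
  first <- readLines(path, n = 1L)
  refs <- if (startsWith(first, "# reference_genes:")) {
    strsplit(sub("^# reference_genes:\\s*", "", first), ",")[[1]]
  } else character(0)
  tbl <- read_tsv_plain(path)
  qpcr_plate(tbl, reference_genes = refs)
}

#' Write / read a drug network (profiles + communities TSV)
#'
#' `profiles.tsv` is long format (`drug`, `gene`, `rank`; rank 1 = most
#' up-regulated), `communities.tsv` maps `drug` to `community`.
#'
#' @param net A `drug_network`.
#' @param dir Output directory.
#' @return `dir` invisibly (writer); a `drug_network` (reader).
#' @export
write_drug_network <- function(net, dir) {
  stopifnot(inherits(net, "drug_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- tibble(
    drug = rep(colnames(net$ranks), each = nrow(net$ranks)),
    gene = rep(rownames(net$ranks), times = ncol(net$ranks)),
    rank = as.vector(net$ranks)
  )
  write_tsv_plain(profiles, file.path(dir, "profiles.tsv"))
  write_tsv_plain(net$communities, file.path(dir, "communities.tsv"))
  invisible(dir)
}

#' @rdname write_drug_network
#' @export
read_drug_network <- function(dir) {
  profiles <- read_tsv_plain(file.path(dir, "profiles.tsv"))
  communities <- read_tsv_plain(file.path(dir, "communities.tsv"))
  if (is.numeric(communities$community) &&
      all(communities$community == round(communities$community))) {
    communities$community <- as.integer(communities$community)
  }
  wide <- tidyr::pivot_wider(profiles, names_from = "drug",
                             values_from = "rank")
  ranks <- as.matrix(wide[, -1])
  if (all(ranks == round(ranks))) storage.mode(ranks) <- "integer"
  rownames(ranks) <- wide$gene
  new_drug_network(ranks[, communities$drug, drop = FALSE], communities)
}

#' Read / write GMT gene-set collections
#'
#' The GMT dialect: one term per line, tab-separated `term_id`,
#' `description`, then member genes.
#'
#' @param path GMT file.
#' @return A named list of character vectors with a `term_names` attribute
#'   (reader); `path` invisibly (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")),
          class = "pdblood_validation_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  lst <- setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  attr(lst, "term_names") <-
    setNames(vapply(parts, `[[`, character(1), 2L), ids)
  lst
}

#' @rdname read_gmt
#' @param terms Named list of character vectors (optionally with a
#'   `term_names` attribute for descriptions).
#' @export
write_gmt <- function(terms, path) {
  terms <- as_term_list(terms)
  nm <- attr(terms, "term_names")
  lines <- vapply(names(terms), function(id) {
    paste(c(id, nm[[id]], terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GEO series-matrix text file
#'
#' Minimal reader for the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` fenced block of a GEO series matrix (the
#' deposited form of processed expression tables). Values are returned as a
#' probes x samples matrix; a class-label vector can be derived from a
#' characteristics line via `label_from`.
#'
#' @param path Series-matrix text file (uncompressed).
#' @param label_from Optional regular expression matched against the
#'   `!Sample_` header lines; samples whose matched line contains
#'   `case_pattern` are labelled case, the rest control.
#' @param case_pattern Pattern identifying case samples (default
#'   `"disease|patient|PD"`).
#' @return A list with `exprs` (numeric matrix) and `class_labels`
#'   (character or `NULL`).
#' @export
read_series_matrix <- function(path, label_from = NULL,
                               case_pattern = "disease|patient|PD") {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort("no series-matrix table fencing found.",
          class = "pdblood_validation_error")
  }
  block <- lines[(begin + 1L):(end - 1L)]
  tbl <- readr::read_tsv(I(block), show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- gsub('"', "", as.character(tbl[[1]]))
  colnames(m) <- gsub('"', "", colnames(m))
  labels <- NULL
  if (!is.null(label_from)) {
    meta <- grep(label_from, lines[seq_len(begin - 1L)], value = TRUE)
    if (length(meta)) {
      fields <- strsplit(meta[1], "\t", fixed = TRUE)[[1]][-1]
      fields <- gsub('"', "", fields)
      labels <- ifelse(grepl(case_pattern, fields, ignore.case = TRUE),
                       "case", "control")
    }
  }
  list(exprs = m, class_labels = labels)
}
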