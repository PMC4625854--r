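#' Intersect differential-expression signatures
#'
#' Set intersection of significant identifiers across two or more method
#' outputs, at probe or gene level. With `direction_consistent = TRUE`,
#' identifiers whose direction of change disagrees between any two lists are
#' excluded. Plain character vectors (e.g. an ortholog-mapped external gene
#' list) are accepted alongside `de_result` tibbles, which makes the
#' cross-species comparison the same operation.
#'
#' @param results List of two or more `de_result` tibbles (only rows with
#'   `significant == TRUE` are used) and/or character vectors of
#'   identifiers.
#' @param level `"gene"` (default) or `"probe"` — which identifier to
#'   intersect on (ignored for character-vector inputs).
#' @param direction_consistent Exclude identifiers with discordant
#'   directions across lists (default `FALSE`).
#'
#' @return A tibble with column `id` (and `direction` when all inputs carry
#'   one), sorted; zero rows if any input list is empty.
#' @export
intersect_signatures <- function(results, level = c("gene", "probe"),
                                 direction_consistent = FALSE) {
  level <- match.arg(level)
  if (!is.list(results) || length(results) < 2L) {
    abort("`results` must be a list of at least 2 signatures.",
          class = "pdblood_validation_error")
  }
  id_col <- if (level == "gene") "gene_id" else "probe_id"
  pieces <- lapply(results, function(r) {
    if (is.character(r)) {
      tibble(id = unique(r), direction = NA_character_)
    } else {
      r <- as_tibble(r)
      sig <- r[r$significant %||% TRUE, , drop = FALSE]
      tibble(id = sig[[id_col]], direction = sig$direction) |>
        dplyr::distinct(.data$id, .keep_all = TRUE)
    }
  })
  if (any(vapply(pieces, nrow, 0L) == 0L)) {
    warn("an input signature is empty; intersection is empty.")
    return(tibble(id = character(0), direction = character(0)))
  }
  ids <- Reduce(intersect, lapply(pieces, function(p) p$id))
  dirs <- lapply(pieces, function(p) setNames(p$direction, p$id))
  direction <- vapply(ids, function(i) {
    d <- unique(stats::na.omit(vapply(dirs, function(v) unname(v[i]),
                                      character(1))))
    if (length(d) == 1L) d else if (length(d) == 0L) NA_character_ else "discordant"
  }, character(1))
  out <- tibble(id = ids, direction = unname(direction)) |>
    dplyr::arrange(.data$id)
  if (direction_consistent) {
    out <- out[is.na(out$direction) | out$direction != "discordant", ,
               drop = FALSE]
  }
  out
}
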