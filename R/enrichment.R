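#' Read a term-to-node annotation table
#'
#' Two tab-separated columns, `term` then `node_id`, one row per
#' annotation. The background defaults to the union of annotated nodes but
#' should usually be supplied explicitly (e.g. all targets of the
#' network): the choice of background changes every p-value.
#'
#' @param path TSV path with columns `term`, `node_id` (header optional,
#'   detected by those exact names on line 1).
#' @param background Optional character vector of all annotatable nodes.
#' @return A list of class `dtn_annotation`: `terms` (named list of node-id
#'   character vectors) and `background`.
#' @export
read_annotation_table <- function(path, background = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    abort(sprintf("line %d of %s does not have 2 tab-separated fields",
                  which(lengths(fields) != 2)[1], path))
  }
  mat <- do.call(rbind, fields)
  if (identical(unname(mat[1, ]), c("term", "node_id"))) {
    mat <- mat[-1, , drop = FALSE]
  }
  annotation_map(split(mat[, 2], mat[, 1]), background = background)
}

#' Build an annotation map from a named list
#'
#' @param terms Named list: term -> character vector of annotated node ids.
#' @param background Character vector of all annotatable nodes; defaults to
#'   the union of the term sets.
#' @return A `dtn_annotation` list.
#' @export
annotation_map <- function(terms, background = NULL) {
  terms <- lapply(terms, function(x) unique(as.character(x)))
  if (any(lengths(terms) == 0)) abort("annotation terms must be non-empty")
  background <- unique(as.character(
    background %||% unlist(terms, use.names = FALSE)
  ))
  outside <- setdiff(unlist(terms, use.names = FALSE), background)
  if (length(outside) > 0) {
    abort(sprintf("annotated nodes outside the background: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  structure(list(terms = terms, background = background),
            class = "dtn_annotation")
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least the seen number of query hits when `query_size` nodes
#' are drawn without replacement from the background: the standard
#' over-representation analysis run against user-supplied annotations
#' (disease classes, pathways, ...). Benjamini-Hochberg adjustment is
#' applied by default.
#'
#' @param query Character vector of node ids; must lie inside the
#'   annotation background.
#' @param annotation A `dtn_annotation`.
#' @param correction `"bh"` (Benjamini-Hochberg step-up, default) or
#'   `"none"` (adjusted value equals the raw p-value).
#' @return A tibble of class `dtn_enrichment`, one row per term, sorted by
#'   `adjusted_p` ascending: `term`, `query_hits`, `term_size`,
#'   `background_size`, `query_size`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(query, annotation, correction = c("bh", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(annotation, "dtn_annotation"))
  query <- unique(as.character(query))
  outside <- setdiff(query, annotation$background)
  if (length(outside) > 0) {
    abort(sprintf("query nodes outside the background: %s",
                  paste(head(outside, 10), collapse = ", ")))
  }
  n_bg <- length(annotation$background)
  n_q <- length(query)
  rows <- purrr::imap(annotation$terms, function(members, term) {
    m <- length(members)
    hits <- length(intersect(query, members))
    p <- phyper(hits - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    tibble(term = term, query_hits = hits, term_size = m,
           background_size = n_bg, query_size = n_q, p_value = p)
  })
  out <- bind_rows(rows)
  out$adjusted_p <- switch(correction,
    bh = p.adjust(out$p_value, method = "BH"),
    none = out$p_value
  )
  out <- out[canonical_order(out$adjusted_p, out$p_value, out$term), ]
  structure(out, class = c("dtn_enrichment", class(tibble())),
            correction = correction)
}
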