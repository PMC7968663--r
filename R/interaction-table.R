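#' Construct a canonical drug-target interaction table
#'
#' An interaction table is the package's native representation of a directed
#' drug-target edge list: one row per (drug, target) interaction, with opaque
#' identifiers and display names for both endpoints. Construction
#' canonicalizes the table so that downstream analyses are reproducible:
#' identifiers are matched after trimming whitespace and case-folding,
#' duplicate (drug, target) pairs are collapsed to their first occurrence,
#' and rows are sorted by drug then target identifier in C-locale order.
#'
#' @param x A data frame with columns `drug_id`, `drug_name`, `target_id`,
#'   `target_name`, and optionally `target_organism`. Name columns default to
#'   the id columns when absent.
#' @param provenance Free-text provenance string recorded on the result
#'   (source file, filter description, database version).
#'
#' @return A tibble of class `dtn_interactions` with columns `drug_id`,
#'   `drug_name`, `target_id`, `target_name`, `target_organism`, sorted and
#'   deduplicated. The number of duplicate rows collapsed is recorded in the
#'   `n_duplicates_removed` attribute, the provenance string in `provenance`.
#' @examples
#' interaction_table(data.frame(
#'   drug_id = c("D1", "D1"), target_id = c("T1", "T2")
#' ))
#' @export
interaction_table <- function(x, provenance = NULL) {
  x <- as_tibble(x)
  if (!all(c("drug_id", "target_id") %in% names(x))) {
    abort("`x` must have columns `drug_id` and `target_id`.")
  }
  if (is.null(x[["drug_name"]])) x$drug_name <- x$drug_id
  if (is.null(x[["target_name"]])) x$target_name <- x$target_id
  if (is.null(x[["target_organism"]])) x$target_organism <- NA_character_
  x <- x[, c("drug_id", "drug_name", "target_id", "target_name",
             "target_organism")]
  x <- mutate(x, dplyr::across(dplyr::everything(), as.character))
  if (any(!nzchar(trimws(x$drug_id))) || any(!nzchar(trimws(x$target_id)))) {
    abort("drug_id and target_id must be non-empty.")
  }
  key_d <- canonical_key(x$drug_id)
  key_t <- canonical_key(x$target_id)
  dup <- duplicated(paste(key_d, key_t, sep = "\r"))
  n_dup <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  ord <- canonical_order(canonical_key(x$drug_id), canonical_key(x$target_id))
  x <- x[ord, , drop = FALSE]
  structure(
    x,
    class = c("dtn_interactions", class(tibble())),
    n_duplicates_removed = n_dup,
    provenance = provenance %||% "in-memory"
  )
}

#' Read a drug-target edge table from TSV
#'
#' Reads the package's native tab-separated edge format: columns `drug_id`,
#' `drug_name`, `target_id`, `target_name` (and optionally
#' `target_organism`), UTF-8, LF line endings. The result is canonicalized
#' with [interaction_table()], so reading is idempotent with
#' [write_edge_table()].
#'
#' @param path Path to a tab-separated file.
#' @param has_header Whether the first line is a header row. When `FALSE` the
#'   columns are assumed to be in the native order.
#' @return A `dtn_interactions` tibble.
#' @export
read_edge_table <- function(path, has_header = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(interaction_table(
      tibble(drug_id = character(), target_id = character()),
      provenance = paste0("edge_table:", path)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  width <- max(nf)
  ok_counts <- if (width == 5L) c(4L, 5L) else width
  bad <- which(!nf %in% ok_counts)
  if (width > 5L || width < 4L || length(bad) > 0) {
    at <- if (length(bad) > 0) bad[1] else which(nf == width)[1]
    abort(sprintf(
      "line %d of %s has %d tab-separated fields (expected 4 or 5)",
      at, path, nf[at]
    ))
  }
  # a trailing empty organism field is dropped by strsplit; pad it back
  fields <- lapply(fields, function(f) c(f, rep("", width - length(f))))
  mat <- do.call(rbind, fields)
  cols <- c("drug_id", "drug_name", "target_id", "target_name",
            "target_organism")[seq_len(ncol(mat))]
  if (has_header) {
    if (!identical(unname(mat[1, 1:4]),
                   c("drug_id", "drug_name", "target_id", "target_name"))) {
      abort(sprintf("header of %s does not match the native edge format", path))
    }
    mat <- mat[-1, , drop = FALSE]
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  df[df == ""] <- NA_character_
  interaction_table(as_tibble(df), provenance = paste0("edge_table:", path))
}

#' Write a drug-target edge table as TSV
#'
#' Writes the canonical, sorted edge format with a header row, UTF-8 and LF
#' line endings. Reading the file back with [read_edge_table()] reproduces
#' the table exactly, and writing a table read from a canonical file
#' reproduces the file byte for byte.
#'
#' @param table A `dtn_interactions` table (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(table, path) {
  if (!inherits(table, "dtn_interactions")) table <- interaction_table(table)
  cols <- c("drug_id", "drug_name", "target_id", "target_name",
            "target_organism")
  keep <- if (all(is.na(table$target_organism))) cols[1:4] else cols
  body <- as.data.frame(table)[, keep, drop = FALSE]
  lines <- c(
    paste(keep, collapse = "\t"),
    if (nrow(body) > 0)
      do.call(paste, c(lapply(body, function(x) ifelse(is.na(x), "", x)),
                       sep = "\t"))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.dtn_interactions <- function(x, ...) {
  cat(sprintf(
    "# Drug-target interaction table: %d interactions, %d drugs, %d targets\n",
    nrow(x), dplyr::n_distinct(canonical_key(x$drug_id)),
    dplyr::n_distinct(canonical_key(x$target_id))
  ))
  cat(sprintf("# Provenance: %s\n", attr(x, "provenance")))
  NextMethod()
}
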