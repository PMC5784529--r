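#' Select the longest protein isoform for every gene
#'
#' Reduces a proteome to one representative protein per gene, the standard
#' preparation before family assignment so that each gene contributes a
#' single leaf to its family phylogeny. The annotation links proteins
#' (transcript records) to genes through configurable GFF3 attributes
#' (default: `ID`/`Parent` chains); lengths are measured on the amino-acid
#' sequence as given, excluding a trailing stop symbol `*` if present.
#' Length ties are broken by lexicographically smallest protein id.
#'
#' Proteins present in the annotation but missing from the FASTA are
#' excluded with a warning and counted in the summary; FASTA sequences with
#' no annotation are likewise excluded and counted.
#'
#' @param annotation Path to a GFF3 file (gzip tolerated) or a `GRanges`
#'   from [rtracklayer::import()].
#' @param proteins Path to a protein FASTA (gzip tolerated) or an
#'   `AAStringSet`.
#' @param tx_types GFF3 `type` values treated as protein-coding transcript
#'   records. Default `c("mRNA", "transcript")`.
#' @param id_attr,parent_attr Attribute names carrying the transcript id and
#'   its gene parent.
#' @param id_trim Optional regular expression removed from both FASTA and
#'   annotation ids before matching (e.g. `"\\.\\d+$"` to drop versions).
#' @param fasta_out Optional path; the chosen-protein FASTA is written
#'   there.
#' @return An object of class `isoform_selection`: a list with `records`
#'   (tibble: `gene_id`, `chosen_protein_id`, `protein_length`,
#'   `n_isoforms`), `fasta` (`AAStringSet` of chosen sequences) and
#'   `summary` (exclusion counts). `tidy()` returns the records.
#' @export
select_longest_isoforms <- function(annotation, proteins,
                                    tx_types = c("mRNA", "transcript"),
                                    id_attr = "ID", parent_attr = "Parent",
                                    id_trim = NULL, fasta_out = NULL) {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else annotation
  aa <- if (is.character(proteins)) {
    Biostrings::readAAStringSet(proteins)
  } else proteins
  names(aa) <- sub("\\s.*$", "", names(aa))
  trim <- function(x) if (is.null(id_trim)) x else sub(id_trim, "", x)
  names(aa) <- trim(names(aa))

  mc <- S4Vectors::mcols(gr)
  is_tx <- as.character(mc$type) %in% tx_types
  if (!any(is_tx)) og_abort("annotation contains no transcript records.")
  tx_id <- trim(as.character(mc[[id_attr]][is_tx]))
  parent <- mc[[parent_attr]][is_tx]
  gene_id <- vapply(as.list(parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  ok <- !is.na(tx_id) & !is.na(gene_id)
  links <- tibble(protein_id = tx_id[ok], gene_id = gene_id[ok]) |>
    distinct()

  in_fasta <- links$protein_id %in% names(aa)
  n_missing <- sum(!in_fasta)
  if (n_missing > 0L) {
    warn(sprintf(
      "%d annotated protein(s) missing from the FASTA were excluded.",
      n_missing
    ))
  }
  links <- links[in_fasta, ]
  n_unannotated <- sum(!(names(aa) %in% links$protein_id))

  seqs <- as.character(aa[links$protein_id])
  len <- nchar(seqs) - as.integer(endsWith(seqs, "*"))
  links$protein_length <- len

  records <- links |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$protein_length), .data$protein_id,
            .by_group = TRUE) |>
    summarise(
      chosen_protein_id = first(.data$protein_id),
      protein_length = first(.data$protein_length),
      n_isoforms = n(),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)

  chosen <- aa[records$chosen_protein_id]
  if (!is.null(fasta_out)) Biostrings::writeXStringSet(chosen, fasta_out)

  structure(
    list(
      records = records,
      fasta = chosen,
      summary = tibble(
        n_genes = nrow(records),
        n_proteins_seen = length(aa),
        n_missing_from_fasta = n_missing,
        n_unannotated_sequences = n_unannotated
      )
    ),
    class = "isoform_selection"
  )
}

#' @export
print.isoform_selection <- function(x, ...) {
  cat(sprintf(
    "<isoform_selection> %d genes (%d sequences seen, %d missing, %d unannotated)\n",
    x$summary$n_genes, x$summary$n_proteins_seen,
    x$summary$n_missing_from_fasta, x$summary$n_unannotated_sequences
  ))
  print(x$records, ...)
  invisible(x)
}

#' @method tidy isoform_selection
#' @export
tidy.isoform_selection <- function(x, ...) x$records

#' @method glance isoform_selection
#' @export
glance.isoform_selection <- function(x, ...) x$summary

#' Load an id-to-symbol mapping table
#'
#' Two-or-more-column TSV: first column source id (e.g. Ensembl protein id),
#' second column display symbol (e.g. HGNC gene symbol). Duplicate source
#' ids keep the first symbol; conflicting duplicates are kept in the
#' `conflicts` attribute and reported with a warning.
#'
#' @param table Path to a TSV file, or a data frame with at least two
#'   columns.
#' @return An `id_map`: a tibble with `source_id` and `symbol` columns.
#' @export
load_id_map <- function(table) {
  df <- if (is.character(table)) {
    readr::read_tsv(table, comment = "#", col_names = FALSE,
                    col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else as_tibble(table)
  if (nrow(df) == 0L) og_abort("empty id-mapping table.")
  if (ncol(df) < 2L) og_abort("id-mapping table needs at least two columns.")
  m <- tibble(source_id = as.character(df[[1L]]),
              symbol = as.character(df[[2L]]))
  dup <- m |>
    group_by(.data$source_id) |>
    filter(n() > 1L, dplyr::n_distinct(.data$symbol) > 1L) |>
    ungroup()
  if (nrow(dup) > 0L) {
    warn(sprintf(
      "%d source id(s) map to multiple symbols; first occurrence kept.",
      dplyr::n_distinct(dup$source_id)
    ))
  }
  out <- m |> distinct(.data$source_id, .keep_all = TRUE)
  attr(out, "conflicts") <- dup
  class(out) <- c("id_map", class(out))
  out
}

#' Map ids to display symbols
#'
#' Unmapped ids pass through unchanged and are flagged, so the lookup is
#' total.
#'
#' @param ids Character vector of ids.
#' @param id_map An [load_id_map()] result.
#' @return A tibble with `id`, `symbol` and logical `mapped`.
#' @export
map_symbols <- function(ids, id_map) {
  hit <- match(ids, id_map$source_id)
  tibble(
    id = ids,
    symbol = ifelse(is.na(hit), ids, id_map$symbol[hit]),
    mapped = !is.na(hit)
  )
}
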