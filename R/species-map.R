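#' Build a species map
#'
#' A species map resolves every leaf label of a gene tree to a species code,
#' and records which species are query genomes (the newly sequenced genomes
#' being classified) and which are the reference species the classification
#' is made against. Resolution uses an explicit lookup table first and falls
#' back to a pattern rule on the label; the default rule takes the suffix
#' after the last underscore, so `"ENSP00000123_HSA"` resolves to `"HSA"`.
#'
#' @param query_species Character vector of query species codes (e.g. the
#'   four cichlid genomes).
#' @param reference_species Ordered character vector of reference species
#'   codes to classify against. Default human then zebrafish.
#' @param table Optional named character vector (or 2-column data frame)
#'   mapping leaf labels to species codes; takes precedence over the
#'   pattern.
#' @param pattern Regular expression with exactly one capture group
#'   extracting the species code from a leaf label, or `NULL` to disable
#'   pattern resolution.
#' @return An object of class `species_map`.
#' @export
#' @examples
#' sm <- species_map(query_species = c("MZE", "PNY"))
#' resolve_species(c("g1_MZE", "p9_HSA"), sm)
species_map <- function(query_species,
                        reference_species = c("HSA", "DRE"),
                        table = NULL,
                        pattern = "_([^_]+)$") {
  if (is.data.frame(table)) {
    table <- setNames(as.character(table[[2L]]), as.character(table[[1L]]))
  }
  if (!is.null(table) && is.null(names(table))) {
    og_abort("`table` must be a named character vector (label -> species).")
  }
  query_species <- as.character(query_species)
  reference_species <- as.character(reference_species)
  if (length(intersect(query_species, reference_species)) > 0L) {
    og_abort("query and reference species must be disjoint.")
  }
  structure(
    list(
      table = table,
      pattern = pattern,
      query_species = query_species,
      reference_species = reference_species
    ),
    class = "species_map"
  )
}

#' @export
print.species_map <- function(x, ...) {
  cat("<species_map>\n")
  cat("  query:     ", paste(x$query_species, collapse = ", "), "\n")
  cat("  reference: ", paste(x$reference_species, collapse = ", "), "\n")
  cat("  table:     ", if (is.null(x$table)) "none"
      else paste0(length(x$table), " labels"), "\n")
  cat("  pattern:   ", x$pattern %||% "none", "\n")
  invisible(x)
}

#' Read a leaf-to-species table from TSV
#'
#' Two columns (leaf label, species code); `#` starts a comment line.
#'
#' @param path Path to the TSV file.
#' @return Named character vector suitable for [species_map()]'s `table`.
#' @export
read_species_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    og_abort(sprintf("species map %s must have two tab-separated columns.",
                     path))
  }
  setNames(df[[2L]], df[[1L]])
}

#' Resolve leaf labels to species codes
#'
#' Table entries take precedence over the pattern rule. Any label that
#' resolves by neither route is an error naming the label (there is no
#' silent "unknown" bucket).
#'
#' @param labels Character vector of leaf labels.
#' @param map A [species_map()].
#' @return Character vector of species codes, same length as `labels`.
#' @export
resolve_species <- function(labels, map) {
  stopifnot(inherits(map, "species_map"))
  if (any(!nzchar(labels))) og_abort("empty leaf label.")
  out <- rep(NA_character_, length(labels))
  if (!is.null(map$table)) {
    hit <- match(labels, names(map$table))
    out[!is.na(hit)] <- unname(map$table[hit[!is.na(hit)]])
  }
  need <- is.na(out)
  if (any(need) && !is.null(map$pattern)) {
    m <- regmatches(labels[need], regexec(map$pattern, labels[need]))
    cap <- vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
                  character(1))
    out[need] <- cap
  }
  if (anyNA(out)) {
    og_abort(sprintf(
      "leaf label(s) with no resolvable species: %s.",
      paste(unique(labels[is.na(out)]), collapse = ", ")
    ))
  }
  out
}
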