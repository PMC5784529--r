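#' Assemble per-species homology report tables
#'
#' Joins homology calls, family assignments and the id-to-symbol map into
#' one table per query species — one row per query gene, ordered by gene id.
#' For the first reference species the row carries the closest protein, its
#' display symbol, the relationship, multiplicity, X and the median copy
#' number over the query genomes; subsequent reference species contribute
#' closest protein, relationship and multiplicity. Genes without a family
#' assignment appear with family `NA` and relationship `no_family_hit`.
#'
#' @param calls Tibble of homology calls from [call_genes()] (query genes
#'   keyed by protein id).
#' @param assignments Tibble from [assign_families()].
#' @param gene_records Tibble from [select_longest_isoforms()]'s records
#'   (`gene_id`, `chosen_protein_id`, ...).
#' @param map A [species_map()] (provides the reference-species order).
#' @param id_map Optional [load_id_map()] result for symbol resolution.
#' @param ref_labels Named character vector giving a human-readable label
#'   per reference species code, used in column names. Defaults to
#'   `c(HSA = "human", DRE = "zebrafish")`, falling back to the code.
#' @return A named list of tibbles, one per query species present among the
#'   genes.
#' @export
build_report <- function(calls, assignments, gene_records, map,
                         id_map = NULL,
                         ref_labels = c(HSA = "human", DRE = "zebrafish")) {
  refs <- map$reference_species
  lab <- function(sp) unname(ref_labels[sp] %|na|% sp)

  genes <- gene_records |>
    select("gene_id", "chosen_protein_id") |>
    left_join(
      assignments |>
        select("protein_id", "best_family_id", "chimera_flag"),
      by = c(chosen_protein_id = "protein_id")
    )
  unmatched <- calls$query_gene[!calls$query_gene %in% genes$chosen_protein_id]
  if (length(unmatched) > 0L) {
    og_abort(sprintf(
      "homology call(s) without a matching assignment/gene record: %s.",
      paste(unique(unmatched), collapse = ", ")
    ))
  }

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    row <- tibble(gene_id = g$gene_id,
                  family_id = g$best_family_id %|na|% NA_character_)
    for (k in seq_along(refs)) {
      ref <- refs[k]
      l <- lab(ref)
      cl <- calls |>
        filter(.data$query_gene == g$chosen_protein_id,
               .data$reference_species == ref)
      rel <- if (is.na(g$best_family_id)) "no_family_hit"
             else if (nrow(cl) == 0L) "tree_unavailable"
             else cl$relationship
      prot <- if (nrow(cl) == 1L) cl$closest_reference_protein else NA_character_
      row[[paste0("closest_", l, "_protein")]] <- prot
      if (k == 1L) {
        sym <- if (!is.null(id_map) && !is.na(prot)) {
          map_symbols(prot, id_map)$symbol
        } else NA_character_
        row[[paste0(l, "_symbol")]] <- sym
      }
      row[[paste0(l, "_relationship")]] <- rel
      row[[paste0(l, "_multiplicity")]] <-
        if (nrow(cl) == 1L) cl$multiplicity else NA_character_
      if (k == 1L) {
        row[[paste0(l, "_x")]] <- if (nrow(cl) == 1L) cl$x_value else NA_integer_
        row[["median_query_hits"]] <-
          if (nrow(cl) == 1L) cl$median_query_copies else NA_real_
      }
    }
    row$chimera_flag <- isTRUE(g$chimera_flag)
    row
  })
  tab <- bind_rows(rows) |> arrange(.data$gene_id)

  # split per query species of the gene's chosen protein
  sp <- resolve_species(genes$chosen_protein_id[
    match(tab$gene_id, genes$gene_id)], map)
  split(tab, sp) |> lapply(as_tibble)
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Summarise homology calls into relationship categories
#'
#' Buckets follow the standard genome-wide summary: one-to-one ortholog,
#' one-to-two ortholog, one-to-X (X > 2) ortholog, many-to-many ortholog,
#' paralog, no_homolog, plus no_family_hit for genes never assigned to a
#' family.
#'
#' @param calls Tibble of homology calls.
#' @param n_no_family_hit Count of genes without a family assignment to add
#'   as a `no_family_hit` row per reference species.
#' @return A tibble with `reference_species`, `category`, `n`; class
#'   `homology_summary` (has an `autoplot()` method).
#' @export
summarize_calls <- function(calls, n_no_family_hit = 0L) {
  cat_of <- function(relationship, multiplicity, x) {
    case_when(
      relationship == "no_homolog" ~ "no_homolog",
      relationship == "paralog" ~ "paralog",
      multiplicity %in% c("many-to-many", "many-to-one") ~
        "many_to_many_ortholog",
      x == 1L ~ "one_to_one_ortholog",
      x == 2L ~ "one_to_two_ortholog",
      x > 2L ~ "one_to_many_ortholog",
      TRUE ~ "other"
    )
  }
  out <- calls |>
    mutate(category = cat_of(.data$relationship, .data$multiplicity,
                             .data$x_value)) |>
    count(.data$reference_species, .data$category, name = "n")
  if (n_no_family_hit > 0L) {
    out <- bind_rows(out, tibble(
      reference_species = unique(calls$reference_species),
      category = "no_family_hit",
      n = as.integer(n_no_family_hit)
    ))
  }
  out <- arrange(out, .data$reference_species, .data$category)
  class(out) <- c("homology_summary", class(out))
  out
}

#' @method autoplot homology_summary
#' @export
autoplot.homology_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~reference_species) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Run the whole homology pipeline
#'
#' Executes ingest (longest-isoform selection), family assignment (with
#' chimera flagging), optional graft-bundle preparation, classification on
#' the family trees, and report assembly, writing per-species TSV reports,
#' pruned Newick trees and a category summary. Family trees are expected to
#' already contain the query proteins as leaves (grafting via external
#' alignment/placement tools is prepared by [prepare_graft_bundle()] and
#' consumed here once done). The run is a pure function of its inputs:
#' re-running on unchanged inputs gives byte-identical outputs.
#'
#' @param config A named list or path to a YAML file with entries:
#'   `proteins`, `annotation`, `hits`, `trees_dir`, `species_map`, `id_map`
#'   (optional), `query_species`, `reference_species`, `prune_keep`
#'   (optional species codes for pruned-tree export). Relative paths are
#'   resolved against the config file's directory.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `records`, `assignments`, `calls`,
#'   `reports` (list of tibbles), `summary` (a `homology_summary`) and
#'   `fraction_with_family_hit`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    rel <- c("proteins", "annotation", "hits", "trees_dir", "species_map",
             "id_map")
    for (f in intersect(rel, names(config))) {
      if (!startsWith(config[[f]], "/")) {
        config[[f]] <- file.path(base, config[[f]])
      }
    }
  }
  need <- c("proteins", "annotation", "hits", "trees_dir", "species_map",
            "query_species", "reference_species")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L) {
    og_abort(sprintf("config is missing: %s.", paste(miss, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, ...) {
    inform(sprintf("[%s] %s", name, paste0(...)))
  }

  sel <- select_longest_isoforms(config$annotation, config$proteins)
  if (nrow(sel$records) == 0L) og_abort("ingest produced no genes.")
  stage("ingest", nrow(sel$records), " genes from ",
        sel$summary$n_proteins_seen, " sequences")

  hits <- parse_hit_table(config$hits)
  asg <- assign_families(hits, all_proteins = sel$records$chosen_protein_id)
  n_hit <- sum(!is.na(asg$best_family_id))
  stage("assign", n_hit, "/", nrow(asg), " proteins assigned to ",
        dplyr::n_distinct(asg$best_family_id, na.rm = TRUE), " families")

  map <- species_map(
    query_species = config$query_species,
    reference_species = config$reference_species,
    table = read_species_map(config$species_map)
  )
  tree_files <- sort(list.files(config$trees_dir, pattern = "\\.nwk$",
                                full.names = TRUE))
  trees <- lapply(tree_files, read_newick)
  names(trees) <- sub("\\.nwk$", "", basename(tree_files))
  calls <- call_genes(trees, map,
                      queries = sel$records$chosen_protein_id)
  # attach the assigned family where the tree name did not already carry it
  stage("classify", nrow(calls), " calls over ", length(trees), " trees")

  id_map <- if (!is.null(config$id_map)) load_id_map(config$id_map) else NULL
  reports <- build_report(calls, asg, sel$records, map, id_map = id_map)
  for (spn in names(reports)) {
    readr::write_tsv(reports[[spn]],
                     file.path(out_dir, sprintf("report_%s.tsv", spn)),
                     progress = FALSE)
  }

  n_no_hit <- sum(is.na(asg$best_family_id))
  summ <- summarize_calls(calls, n_no_family_hit = n_no_hit)
  readr::write_tsv(as_tibble(summ), file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  frac <- n_hit / nrow(asg)
  writeLines(c(
    sprintf("genes: %d", nrow(sel$records)),
    sprintf("fraction_with_family_hit: %.6f", frac),
    sprintf("calls: %d", nrow(calls))
  ), file.path(out_dir, "summary.txt"))

  if (!is.null(config$prune_keep)) {
    pdir <- file.path(out_dir, "pruned")
    dir.create(pdir, showWarnings = FALSE)
    for (fam in sort(names(trees))) {
      pt <- tryCatch(
        prune_to_taxa(trees[[fam]], config$prune_keep, map),
        error = function(e) NULL
      )
      if (!is.null(pt)) {
        write_newick(pt, file.path(pdir, paste0(fam, ".nwk")))
      }
    }
  }
  stage("report", length(reports), " report table(s) written to ", out_dir)

  invisible(list(
    records = sel$records, assignments = asg, calls = calls,
    reports = reports, summary = summ,
    fraction_with_family_hit = frac
  ))
}
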