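#' Smallest subtree containing a query leaf and a reference-species leaf
#'
#' Walks from the query leaf towards the root and returns the first ancestor
#' whose subtree contains at least one leaf of the reference species. If the
#' root is reached without finding one (no reference leaf anywhere in the
#' family tree) the gene has no homolog in that species and `NA` is
#' returned.
#'
#' @param tree A rooted `phylo`.
#' @param query_leaf Leaf label of the query protein.
#' @param reference A single species code.
#' @param map A [species_map()].
#' @return Integer node id, or `NA_integer_` (the no-homolog sentinel).
#' @export
smallest_containing_subtree <- function(tree, query_leaf, reference, map) {
  validate_gene_tree(tree)
  q <- tip_index(tree, query_leaf)
  sp <- resolve_species(tree$tip.label, map)
  ref_tips <- which(sp == reference)
  if (length(ref_tips) == 0L) return(NA_integer_)
  tips <- node_tipsets(tree)
  anc <- phangorn::Ancestors(tree, q, type = "all") # parent first
  for (a in anc) {
    if (any(ref_tips %in% tips[[a]])) return(as.integer(a))
  }
  NA_integer_
}

#' Closest reference-species homolog of a query leaf
#'
#' Among the reference-species leaves inside the smallest containing
#' subtree, returns the one at minimal patristic distance from the query
#' leaf; ties are broken by lexicographic leaf label.
#'
#' @inheritParams smallest_containing_subtree
#' @param subtree_node Optional precomputed result of
#'   [smallest_containing_subtree()]; computed when `NULL`.
#' @return A one-row tibble with `leaf` and `distance`, or a zero-row tibble
#'   when there is no homolog.
#' @export
closest_homolog <- function(tree, query_leaf, reference, map,
                            subtree_node = NULL) {
  if (is.null(subtree_node)) {
    subtree_node <- smallest_containing_subtree(tree, query_leaf,
                                                reference, map)
  }
  empty <- tibble(leaf = character(0), distance = numeric(0))
  if (is.na(subtree_node)) return(empty)
  sp <- resolve_species(tree$tip.label, map)
  in_clade <- node_tipsets(tree)[[subtree_node]]
  cand <- sort(tree$tip.label[intersect(in_clade, which(sp == reference))])
  d <- vapply(cand, function(l) patristic_distance(tree, query_leaf, l),
              numeric(1))
  best <- which(d == min(d))[1L] # cand sorted: first minimum is the tie-break
  tibble(leaf = cand[best], distance = unname(d[best]))
}

#' Classify a leaf pair as ortholog or paralog
#'
#' The pair is orthologous iff the species-overlap event at their most
#' recent common ancestor is a speciation, paralogous iff it is a
#' duplication. Symmetric in its two leaf arguments.
#'
#' @param tree A rooted `phylo`.
#' @param leaf_a,leaf_b Leaf labels.
#' @param events Result of [label_events()] on the same (rooted) tree;
#'   computed when `NULL`.
#' @param map A [species_map()].
#' @return `"ortholog"` or `"paralog"`.
#' @export
classify_relationship <- function(tree, leaf_a, leaf_b, events = NULL, map) {
  if (is.null(events)) events <- label_events(tree, map)
  m <- tree_mrca(tree, c(leaf_a, leaf_b))
  ev <- events$event[match(m, events$node)]
  if (is.na(ev)) og_abort("MRCA is not an internal node of the tree.")
  if (ev == "speciation") "ortholog" else "paralog"
}

num_word <- function(x) {
  w <- c("one", "two", "three", "four", "five",
         "six", "seven", "eight", "nine", "ten")
  if (x >= 1 && x <= 10) w[x] else as.character(x)
}

#' One-to-X multiplicity and median query copy number of an ortholog pair
#'
#' For an orthologous query/reference pair, the ortholog clade is the
#' smallest subtree containing the query leaf and a reference-species leaf.
#' `X` counts the leaves of the query gene's own species in that clade;
#' the multiplicity is `"one-to-X"` when the clade holds exactly one
#' reference leaf (e.g. `"one-to-two"` for a gene retained in duplicate
#' since the teleost genome duplication), `"many-to-many"` when it holds two
#' or more reference leaves and `X >= 2`, and `"many-to-one"` in the
#' remaining multi-reference case. The median copy number is the median,
#' over the configured query genomes, of each genome's leaf count in the
#' clade; genomes absent from the clade count 0 by default (capturing loss).
#'
#' @inheritParams smallest_containing_subtree
#' @param reference_leaf The reference leaf of the pair (used to check the
#'   orthology contract).
#' @param events Result of [label_events()]; computed when `NULL`.
#' @param count_zero_species Include configured query genomes with no leaf
#'   in the clade as zeros in the median (default `TRUE`).
#' @return A one-row tibble: `multiplicity`, `x_value`,
#'   `median_query_copies`.
#' @export
ortho_multiplicity <- function(tree, query_leaf, reference_leaf, map,
                               events = NULL, count_zero_species = TRUE) {
  rel <- classify_relationship(tree, query_leaf, reference_leaf, events, map)
  if (rel != "ortholog") {
    og_abort("ortho_multiplicity called on a non-ortholog pair.",
             class = "orthograft_contract_error")
  }
  sp <- resolve_species(tree$tip.label, map)
  reference <- sp[tip_index(tree, reference_leaf)]
  clade <- smallest_containing_subtree(tree, query_leaf, reference, map)
  in_clade <- node_tipsets(tree)[[clade]]
  clade_sp <- sp[in_clade]
  q_species <- sp[tip_index(tree, query_leaf)]
  x <- sum(clade_sp == q_species)
  n_ref <- sum(clade_sp == reference)
  mult <- if (n_ref == 1L) {
    paste0("one-to-", num_word(x))
  } else if (x >= 2L) {
    "many-to-many"
  } else {
    "many-to-one"
  }
  counts <- vapply(map$query_species, function(s) sum(clade_sp == s),
                   integer(1))
  if (!count_zero_species) counts <- counts[counts > 0L]
  tibble(
    multiplicity = mult,
    x_value = as.integer(x),
    median_query_copies = stats::median(as.numeric(counts))
  )
}

empty_call <- function(query_leaf, family, reference) {
  tibble(
    query_gene = query_leaf,
    family = family,
    reference_species = reference,
    relationship = "no_homolog",
    closest_reference_protein = NA_character_,
    closest_reference_symbol = NA_character_,
    distance = NA_real_,
    multiplicity = NA_character_,
    x_value = NA_integer_,
    median_query_copies = NA_real_
  )
}

#' Classify one query gene against every reference species
#'
#' The full per-gene analysis: the family tree is midpoint rooted (unless
#' `root = "keep"` preserves an existing root), internal nodes are labelled
#' by species overlap, and for each configured reference species the
#' smallest containing subtree is found, the closest homolog identified by
#' patristic distance, the pair classified as ortholog or paralog, and, for
#' orthologs, the one-to-X multiplicity and median query copy number
#' computed. A tree with no leaf of a reference species yields a
#' `no_homolog` record with all reference fields absent.
#'
#' @param tree A `phylo` (rooted or not).
#' @param query_leaf Leaf label of the query protein.
#' @param map A [species_map()].
#' @param family Optional family id carried into the output.
#' @param root `"midpoint"` (default; re-roots even pre-rooted input) or
#'   `"keep"`.
#' @param count_zero_species Passed to [ortho_multiplicity()].
#' @return A tibble with one row per reference species (a homology call).
#' @export
#' @examples
#' tr <- parse_newick("((q_MZE:1,h1_HSA:1):1,h2_HSA:5);")
#' call_gene(tr, "q_MZE", species_map("MZE"))
call_gene <- function(tree, query_leaf, map, family = NA_character_,
                      root = c("midpoint", "keep"),
                      count_zero_species = TRUE) {
  root <- match.arg(root)
  if (root == "midpoint") tree <- midpoint_root(tree)
  events <- label_events(tree, map)
  rows <- lapply(map$reference_species, function(ref) {
    node <- smallest_containing_subtree(tree, query_leaf, ref, map)
    if (is.na(node)) return(empty_call(query_leaf, family, ref))
    hit <- closest_homolog(tree, query_leaf, ref, map, subtree_node = node)
    rel <- classify_relationship(tree, query_leaf, hit$leaf, events, map)
    if (rel == "ortholog") {
      m <- ortho_multiplicity(tree, query_leaf, hit$leaf, map,
                              events = events,
                              count_zero_species = count_zero_species)
    } else {
      m <- tibble(multiplicity = NA_character_, x_value = NA_integer_,
                  median_query_copies = NA_real_)
    }
    tibble(
      query_gene = query_leaf,
      family = family,
      reference_species = ref,
      relationship = rel,
      closest_reference_protein = hit$leaf,
      closest_reference_symbol = NA_character_,
      distance = hit$distance,
      multiplicity = m$multiplicity,
      x_value = m$x_value,
      median_query_copies = m$median_query_copies
    )
  })
  bind_rows(rows)
}

#' Classify every query gene in a set of family trees
#'
#' @param trees Named list of `phylo` objects (names are family ids), or a
#'   single `phylo`.
#' @param map A [species_map()].
#' @param queries Optional character vector restricting which leaves are
#'   classified; by default every leaf of a query species in each tree.
#' @inheritParams call_gene
#' @return A tibble of homology calls, one row per (gene, reference
#'   species), ordered by family then gene.
#' @export
call_genes <- function(trees, map, queries = NULL,
                       root = c("midpoint", "keep"),
                       count_zero_species = TRUE) {
  root <- match.arg(root)
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  if (is.null(names(trees))) {
    og_abort("`trees` must be a named list (names are family ids).")
  }
  out <- lapply(sort(names(trees)), function(fam) {
    tree <- trees[[fam]]
    if (root == "midpoint") tree <- midpoint_root(tree)
    sp <- resolve_species(tree$tip.label, map)
    qs <- sort(tree$tip.label[sp %in% map$query_species])
    if (!is.null(queries)) qs <- intersect(qs, queries)
    bind_rows(lapply(qs, function(q) {
      call_gene(tree, q, map, family = fam, root = "keep",
                count_zero_species = count_zero_species)
    }))
  })
  bind_rows(out)
}
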