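#' Label internal nodes as speciation or duplication (species overlap)
#'
#' The species-overlap rule: an internal node is a duplication if at least
#' two of its child subtrees share a species, otherwise a speciation. For
#' multifurcations any pairwise intersection marks a duplication (the
#' conservative generalisation of the binary rule). The tree must already be
#' rooted the way the caller intends; [call_gene()] midpoint-roots first.
#'
#' @param tree A rooted `phylo`.
#' @param map A [species_map()] resolving every leaf.
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `event` (`"speciation"` or `"duplication"`) and `overlap_size`, the
#'   number of species shared between child subtrees (0 for speciations).
#' @export
#' @examples
#' tr <- parse_newick("((g1_SPA:1,g2_SPA:1):1,g3_SPB:2);")
#' label_events(tr, species_map("SPA", "SPB"))
label_events <- function(tree, map) {
  validate_gene_tree(tree)
  sp <- resolve_species(tree$tip.label, map)
  tips <- node_tipsets(tree)
  kids <- node_children(tree)
  nodes <- internal_nodes(tree)
  ev <- character(length(nodes))
  ov <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    ch <- kids[[nodes[i]]]
    sets <- lapply(ch, function(c) unique(sp[tips[[c]]]))
    shared <- character(0)
    if (length(sets) >= 2L) {
      for (a in seq_len(length(sets) - 1L)) {
        for (b in seq(a + 1L, length(sets))) {
          shared <- c(shared, intersect(sets[[a]], sets[[b]]))
        }
      }
    }
    shared <- unique(shared)
    ov[i] <- length(shared)
    ev[i] <- if (length(shared) >= 1L) "duplication" else "speciation"
  }
  tibble(node = nodes, event = ev, overlap_size = ov)
}
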