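# Brute-force oracles and random-tree generators, independent of the
# package's own traversal code paths.

sim_map <- function() default_sim_species_map()

# random leaf-labelled tree with species suffixes; lengths U(0.1, 1)
rand_gene_tree <- function(n_leaves, seed,
                           species = c("MZE", "PNY", "ABU", "NBR",
                                       "HSA", "DRE", "MMU")) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, br = NULL)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.1, 1), 6)
    sp <- sample(species, n_leaves, replace = TRUE)
    tr$tip.label <- sprintf("t%03d_%s", seq_len(n_leaves), sp)
    tr
  })
}

# canonical structural form: children sorted by their smallest leaf label,
# lengths rounded to 1e-9 (recursion over the edge matrix, no Newick writer)
canonical_form <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  el <- tree$edge.length
  lens <- if (is.null(el)) NULL else {
    setNames(el, paste(tree$edge[, 1L], tree$edge[, 2L]))
  }
  fmt <- function(node, parent) {
    key <- paste(parent, node)
    len <- if (is.null(lens) || is.na(parent) || !key %in% names(lens)) {
      ""
    } else {
      l <- lens[[key]]
      if (is.na(l) || is.nan(l)) ":NA" else sprintf(":%.9f", l)
    }
    if (node <= ntip) return(paste0(tree$tip.label[node], len))
    ch <- sort(vapply(kids[[as.character(node)]], fmt, character(1),
                      parent = node))
    paste0("(", paste(ch, collapse = ","), ")", len)
  }
  root <- ntip + 1L
  fmt(root, parent = NA)
}

# all ancestors of a tip, walking the edge matrix
bf_ancestors <- function(tree, node) {
  out <- integer(0)
  repeat {
    p <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(p) == 0L) break
    out <- c(out, p)
    node <- p
  }
  out
}

bf_tipset <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  ch <- tree$edge[tree$edge[, 1L] == node, 2L]
  sort(unlist(lapply(ch, bf_tipset, tree = tree)))
}

# MRCA by filtering all nodes whose tip set contains the query set and
# taking the one with fewest leaves
bf_mrca <- function(tree, labels) {
  want <- match(labels, tree$tip.label)
  nn <- length(tree$tip.label) + tree$Nnode
  cand <- Filter(function(n) all(want %in% bf_tipset(tree, n)), seq_len(nn))
  sizes <- vapply(cand, function(n) length(bf_tipset(tree, n)), integer(1))
  cand[[which.min(sizes)]]
}

bf_pairwise <- function(tree) ape::cophenetic.phylo(tree)

# minimax root-to-leaf distance over a closed-form scan of every edge
bf_midpoint_minimax <- function(tree) {
  dn <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  best <- Inf
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    c <- tree$edge[i, 2L]
    len <- tree$edge.length[i]
    tips_c <- bf_tipset(tree, c)
    tips_c <- tips_c[tips_c <= ntip]
    tips_p <- setdiff(seq_len(ntip), tips_c)
    max_c <- max(dn[c, tips_c])
    max_p <- if (length(tips_p)) max(dn[p, tips_p]) else -Inf
    x <- (max_c + len - max_p) / 2 # distance from the p end
    x <- min(max(x, 0), len)
    best <- min(best, max(max_p + x, max_c + len - x))
  }
  best
}

max_root_to_leaf <- function(tree) {
  dn <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  max(dn[ntip + 1L, seq_len(ntip)])
}

# ancestor-scan oracle for the smallest containing subtree
bf_smallest_subtree <- function(tree, q_label, ref, map) {
  sp <- resolve_species(tree$tip.label, map)
  ref_tips <- which(sp == ref)
  if (length(ref_tips) == 0L) return(NA_integer_)
  anc <- bf_ancestors(tree, match(q_label, tree$tip.label))
  cand <- Filter(function(n) any(ref_tips %in% bf_tipset(tree, n)), anc)
  if (length(cand) == 0L) return(NA_integer_)
  sizes <- vapply(cand, function(n) length(bf_tipset(tree, n)), integer(1))
  as.integer(cand[[which.min(sizes)]])
}

# argmin over the brute-force all-pairs matrix restricted to the subtree
bf_closest <- function(tree, q_label, ref, map) {
  node <- bf_smallest_subtree(tree, q_label, ref, map)
  if (is.na(node)) return(NULL)
  sp <- resolve_species(tree$tip.label, map)
  tips <- bf_tipset(tree, node)
  cand <- tips[tips <= length(tree$tip.label)]
  cand <- cand[sp[cand] == ref]
  labs <- sort(tree$tip.label[cand])
  d <- bf_pairwise(tree)[q_label, labs]
  list(leaf = labs[which.min(d)], distance = min(d))
}

# expected number of duplication nodes per family under a pure-birth gene
# process (loss 0): sum over species-tree branches of
# E[lineages entering] * (e^(rate * len) - 1), by recursion from the root
bf_expected_dups <- function(sp_tree, dup_rate) {
  ntip <- length(sp_tree$tip.label)
  total <- 0
  recurse <- function(node, entering) {
    ch_edges <- which(sp_tree$edge[, 1L] == node)
    for (i in ch_edges) {
      len <- sp_tree$edge.length[i]
      total <<- total + entering * (exp(dup_rate * len) - 1)
      child <- sp_tree$edge[i, 2L]
      if (child > ntip) recurse(child, entering * exp(dup_rate * len))
    }
  }
  recurse(ntip + 1L, 1)
  total
}

# simulated families with a usable gene tree (>= 2 leaves)
usable_families <- function(sim, max_leaves = Inf) {
  Filter(function(f) {
    !is.null(f$gene_tree) && length(f$gene_tree$tip.label) <= max_leaves
  }, sim$families)
}
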