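#' @noRd
n_tips <- function(tree) length(tree$tip.label)

#' @noRd
root_node <- function(tree) n_tips(tree) + 1L

#' @noRd
internal_nodes <- function(tree) root_node(tree) + seq_len(tree$Nnode) - 1L

# children of each node as a list indexed by node id
#' @noRd
node_children <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

# tip descendants (tip indices) of every node
#' @noRd
node_tipsets <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  phangorn::Descendants(tree, seq_len(nn), type = "tips")
}

# length of the edge joining two adjacent nodes, NA when stored absent
#' @noRd
edge_length_between <- function(tree, a, b) {
  hit <- which((tree$edge[, 1L] == a & tree$edge[, 2L] == b) |
                 (tree$edge[, 1L] == b & tree$edge[, 2L] == a))
  if (length(hit) == 0L) og_abort("nodes are not adjacent.")
  el <- tree$edge.length
  if (is.null(el)) return(NA_real_)
  len <- el[hit[1L]]
  if (is.nan(len)) NA_real_ else len
}

#' @noRd
tip_index <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (any(is.na(i))) {
    og_abort(sprintf(
      "leaf label(s) not in tree: %s.",
      paste(label[is.na(i)], collapse = ", ")
    ))
  }
  i
}

#' @noRd
has_all_lengths <- function(tree) {
  el <- tree$edge.length
  !is.null(el) && length(el) == nrow(tree$edge) &&
    !any(is.na(el) | is.nan(el))
}

#' Most recent common ancestor of a set of leaves
#'
#' The deepest node whose leaf set contains all the given leaves.
#'
#' @param tree A rooted `phylo`.
#' @param leaves Character vector of leaf labels (one or more).
#' @return Integer node id (in ape numbering: tips are `1..Ntip`, the root is
#'   `Ntip + 1`). For a single leaf, the tip itself.
#' @export
tree_mrca <- function(tree, leaves) {
  validate_gene_tree(tree)
  idx <- tip_index(tree, unique(leaves))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path joining two leaves. Errors if
#' any edge on that path has no stored branch length (never silently
#' zero-filled).
#'
#' @param tree A `phylo`.
#' @param a,b Leaf labels.
#' @return Non-negative numeric distance; `0` when `a == b`.
#' @export
patristic_distance <- function(tree, a, b) {
  validate_gene_tree(tree)
  ia <- tip_index(tree, a)
  ib <- tip_index(tree, b)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, ia, ib)
  total <- 0
  for (k in seq_len(length(path) - 1L)) {
    len <- edge_length_between(tree, path[k], path[k + 1L])
    if (is.na(len)) {
      og_abort(sprintf(
        "missing branch length on the path between %s and %s.", a, b
      ))
    }
    total <- total + len
  }
  total
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, the
#' position that minimises the maximum root-to-leaf distance. Leaf set,
#' topology (up to root placement) and total branch length are preserved.
#' When several diameter paths tie, the path whose (sorted) endpoint label
#' pair is lexicographically smallest is used, so the result is deterministic
#' across runs and platforms. When the midpoint falls exactly on an existing
#' node, that node becomes the root and no zero-length edge is inserted.
#'
#' @param tree A `phylo` with at least 2 leaves and all branch lengths
#'   present.
#' @return A rooted `phylo`.
#' @export
#' @examples
#' tr <- midpoint_root(parse_newick("(A:1,B:3);"))
#' patristic_distance(tr, "A", "B")
midpoint_root <- function(tree) {
  validate_gene_tree(tree)
  if (n_tips(tree) < 2L) og_abort("midpoint rooting needs at least 2 leaves.")
  if (!has_all_lengths(tree)) {
    og_abort("midpoint rooting needs a branch length on every edge.")
  }
  dmat <- ape::cophenetic.phylo(tree)
  labs <- rownames(dmat)
  diam <- max(dmat)
  if (diam <= 0) return(tree) # all-zero lengths: any rooting is a midpoint
  idx <- which(dmat == diam, arr.ind = TRUE)
  pairs <- cbind(
    pmin(labs[idx[, 1L]], labs[idx[, 2L]]),
    pmax(labs[idx[, 1L]], labs[idx[, 2L]])
  )
  ord <- order(pairs[, 1L], pairs[, 2L])[1L]
  p1 <- pairs[ord, 1L]
  p2 <- pairs[ord, 2L]

  half <- diam / 2
  path <- ape::nodepath(tree, tip_index(tree, p1), tip_index(tree, p2))
  lens <- vapply(seq_len(length(path) - 1L), function(k) {
    edge_length_between(tree, path[k], path[k + 1L])
  }, numeric(1))
  cum <- c(0, cumsum(lens))
  tol <- 1e-12 * max(1, diam)
  # first path node at or beyond the midpoint
  k <- which(cum >= half - tol)[1L]
  if (abs(cum[k] - half) <= tol) {
    return(root_at_node(tree, path[k]))
  }
  k <- k - 1L # midpoint strictly inside the edge path[k] -- path[k+1]
  offset <- half - cum[k] # distance from path[k] towards path[k+1]
  a <- path[k]
  b <- path[k + 1L]
  # phytools::reroot positions are measured from the parent end of the edge
  if (is_parent_of(tree, a, b)) {
    out <- phytools::reroot(tree, node.number = b, position = offset)
  } else {
    len <- edge_length_between(tree, a, b)
    out <- phytools::reroot(tree, node.number = a, position = len - offset)
  }
  out
}

#' @noRd
is_parent_of <- function(tree, p, c) {
  any(tree$edge[, 1L] == p & tree$edge[, 2L] == c)
}

# root at an existing node; degree-2 old root is collapsed by ape::root
#' @noRd
root_at_node <- function(tree, node) {
  if (node == root_node(tree)) return(tree)
  if (node <= n_tips(tree)) {
    # midpoint on a leaf: only possible when the far side has length 0;
    # root on the leaf's (zero-length) position via its parent edge
    return(phytools::reroot(tree, node.number = node,
                            position = edge_length_between(
                              tree, parent_of(tree, node), node)))
  }
  ape::root(tree, node = node, resolve.root = FALSE)
}

#' @noRd
parent_of <- function(tree, node) {
  hit <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(hit) == 0L) og_abort("node has no parent.")
  hit
}

#' Total branch length of a tree
#'
#' @param tree A `phylo`.
#' @return Sum of all stored branch lengths (`NA` if any is missing).
#' @export
total_tree_length <- function(tree) {
  el <- tree$edge.length
  if (is.null(el)) return(NA_real_)
  el[is.nan(el)] <- NA_real_
  sum(el)
}

#' Prune a gene tree to a set of species
#'
#' Keeps only leaves whose species (via the species map) is in `keep`,
#' collapsing unary internal nodes with branch lengths summed, so patristic
#' distances between retained leaves are unchanged.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of species codes to retain.
#' @param species_map A [species_map()].
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep, species_map) {
  validate_gene_tree(tree)
  sp <- resolve_species(tree$tip.label, species_map)
  retain <- tree$tip.label[sp %in% keep]
  if (length(retain) == 0L) {
    og_abort("no retained leaves after pruning.")
  }
  if (length(retain) == n_tips(tree)) return(tree)
  ape::keep.tip(tree, retain)
}
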