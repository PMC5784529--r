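#' Default fixture species tree
#'
#' A 10-taxon ultrametric species tree mirroring the taxa of a typical
#' cichlid homology study: four query cichlids (`MZE`, `PNY`, `ABU`, `NBR`),
#' Nile tilapia (`ONI`), zebrafish (`DRE`), human (`HSA`), mouse (`MMU`),
#' fly (`DME`) and worm (`CEL`), with fixed arbitrary branch lengths (time
#' units).
#'
#' @return A rooted ultrametric `phylo`.
#' @export
default_species_tree <- function() {
  parse_newick(paste0(
    "(((((((MZE:0.04,PNY:0.04):0.04,ABU:0.08):0.04,NBR:0.12):0.04,",
    "ONI:0.16):0.54,DRE:0.7):0.3,(HSA:0.3,MMU:0.3):0.7):0.6,",
    "(DME:1.2,CEL:1.2):0.4);"
  ))
}

#' Default species map for the fixture species tree
#'
#' @inheritParams species_map
#' @return A [species_map()] with the four cichlids as query species.
#' @export
default_sim_species_map <- function(reference_species = c("HSA", "DRE")) {
  species_map(
    query_species = c("MZE", "PNY", "ABU", "NBR"),
    reference_species = reference_species
  )
}

#' Simulate gene families by duplication and loss along a species tree
#'
#' Standard birth-death gene-family evolution: a single gene lineage enters
#' the root of the species tree; along every species-tree branch it
#' duplicates (the lineage splits; the node is a true duplication) and is
#' lost (the lineage terminates) as independent Poisson processes with the
#' given per-unit-branch-length rates; at every species-tree node each
#' surviving lineage splits into the descendant branches (a true speciation
#' node); surviving lineages become leaves labelled `g<k>_<SPECIES>` at the
#' species-tree tips. Lineages with no surviving descendants are pruned and
#' the resulting unary nodes collapsed with branch lengths summed; event
#' labels of collapsed nodes are dropped from the truth set (no tree node
#' remains to compare against). Gene-tree branch lengths are evolutionary
#' time along the species tree, with no rate heterogeneity.
#'
#' @param n_families Number of independent families to simulate.
#' @param species_tree A rooted `phylo` with branch lengths; default
#'   [default_species_tree()].
#' @param dup_rate,loss_rate Poisson rates per unit branch length (>= 0).
#' @param seed Integer seed; identical configuration gives byte-identical
#'   output. The caller's RNG state is untouched.
#' @return An object of class `sim_families`: a list with `families` (each a
#'   list holding `gene_tree`, `true_events`, `copy_number`; `gene_tree` is
#'   `NULL` for families whose lineages were all lost) and `config`.
#' @export
#' @examples
#' sim <- simulate_gene_trees(3, dup_rate = 0.3, loss_rate = 0, seed = 7)
#' sim$families[[1]]$true_events
simulate_gene_trees <- function(n_families,
                                species_tree = default_species_tree(),
                                dup_rate = 0.1, loss_rate = 0.05,
                                seed = 1L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, n_families >= 1)
  validate_gene_tree(species_tree)
  if (!has_all_lengths(species_tree)) {
    og_abort("species tree must have all branch lengths.")
  }
  fams <- withr::with_seed(seed, {
    lapply(seq_len(n_families), function(i) {
      sim_one_family(species_tree, dup_rate, loss_rate)
    })
  })
  structure(
    list(
      families = fams,
      config = list(
        n_families = n_families, dup_rate = dup_rate,
        loss_rate = loss_rate, seed = seed,
        species = species_tree$tip.label
      )
    ),
    class = "sim_families"
  )
}

#' @noRd
sim_one_family <- function(sp_tree, dup_rate, loss_rate) {
  kids <- node_children(sp_tree)
  ntip <- n_tips(sp_tree)
  elen <- function(child) edge_length_between(sp_tree, parent_of(sp_tree, child), child)
  env <- new.env(parent = emptyenv())
  env$k <- 0L
  rate <- dup_rate + loss_rate

  at_node <- function(sp) {
    if (sp <= ntip) {
      env$k <- env$k + 1L
      return(list(kind = "leaf",
                  label = sprintf("g%d_%s", env$k, sp_tree$tip.label[sp]),
                  edge = 0))
    }
    res <- lapply(kids[[sp]], function(c) along_branch(c, elen(c)))
    surv <- res[!vapply(res, is.null, logical(1))]
    if (length(surv) == 0L) return(NULL)
    if (length(surv) == 1L) return(surv[[1L]]) # unary collapse: label dropped
    list(kind = "node", event = "speciation", edge = 0, children = surv)
  }

  along_branch <- function(sp, t) {
    w <- if (rate > 0) rexp(1L, rate) else Inf
    if (w >= t) {
      res <- at_node(sp)
      if (is.null(res)) return(NULL)
      res$edge <- res$edge + t
      return(res)
    }
    if (runif(1L) < dup_rate / rate) {
      c1 <- along_branch(sp, t - w)
      c2 <- along_branch(sp, t - w)
      surv <- Filter(Negate(is.null), list(c1, c2))
      if (length(surv) == 0L) return(NULL)
      if (length(surv) == 1L) {
        s <- surv[[1L]]
        s$edge <- s$edge + w
        return(s)
      }
      return(list(kind = "node", event = "duplication", edge = w,
                  children = surv))
    }
    NULL # loss
  }

  top <- at_node(root_node(sp_tree))
  species <- sp_tree$tip.label
  if (is.null(top)) {
    return(list(gene_tree = NULL,
                true_events = tibble(label = character(0),
                                     event = character(0)),
                copy_number = setNames(integer(length(species)), species)))
  }
  env$e <- 0L
  ev_labels <- character(0)
  ev_events <- character(0)
  to_newick <- function(nd, with_edge = TRUE) {
    suffix <- if (with_edge) sprintf(":%.10g", nd$edge) else ""
    if (nd$kind == "leaf") return(paste0(nd$label, suffix))
    env$e <- env$e + 1L
    lab <- sprintf("e%d", env$e)
    ev_labels <<- c(ev_labels, lab)
    ev_events <<- c(ev_events, nd$event)
    paste0("(",
           paste(vapply(nd$children, to_newick, character(1)),
                 collapse = ","),
           ")", lab, suffix)
  }
  nwk <- paste0(to_newick(top, with_edge = FALSE), ";")
  gt <- if (top$kind == "leaf") NULL else parse_newick(nwk)
  leaves <- if (is.null(gt)) top$label else gt$tip.label
  leaf_sp <- sub("^.*_", "", leaves)
  cn <- vapply(species, function(s) sum(leaf_sp == s), integer(1))
  list(
    gene_tree = gt,
    single_leaf = if (is.null(gt)) top$label else NULL,
    true_events = tibble(label = ev_labels, event = ev_events),
    copy_number = cn
  )
}

#' True event labels of a simulated family, in ape node numbering
#'
#' Joins a simulated family's ground-truth events onto its gene tree's
#' internal nodes so they can be compared directly with [label_events()].
#'
#' @param family One element of `simulate_gene_trees(...)$families` with a
#'   non-`NULL` `gene_tree`.
#' @return A tibble with `node` (ape node id) and `event`.
#' @export
sim_true_events <- function(family) {
  gt <- family$gene_tree
  if (is.null(gt)) og_abort("family has no gene tree.")
  labs <- gt$node.label %||% character(0)
  nodes <- internal_nodes(gt)
  hit <- match(labs, family$true_events$label)
  tibble(node = nodes, event = family$true_events$event[hit]) |>
    filter(!is.na(.data$event))
}

#' @export
print.sim_families <- function(x, ...) {
  n <- length(x$families)
  empty <- sum(vapply(x$families, function(f) is.null(f$gene_tree),
                      logical(1)))
  cat(sprintf(
    "<sim_families> %d families (dup %.3g, loss %.3g, seed %d); %d empty/single-leaf\n",
    n, x$config$dup_rate, x$config$loss_rate, x$config$seed, empty
  ))
  invisible(x)
}

#' @method tidy sim_families
#' @export
tidy.sim_families <- function(x, ...) {
  rows <- lapply(seq_along(x$families), function(i) {
    f <- x$families[[i]]
    tibble(
      family = i,
      n_leaves = if (is.null(f$gene_tree)) {
        as.integer(!is.null(f$single_leaf))
      } else length(f$gene_tree$tip.label),
      n_duplications = sum(f$true_events$event == "duplication"),
      n_speciations = sum(f$true_events$event == "speciation")
    )
  })
  bind_rows(rows)
}

#' @method glance sim_families
#' @export
glance.sim_families <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_families = nrow(td),
    n_empty = sum(td$n_leaves == 0L),
    mean_leaves = mean(td$n_leaves),
    mean_duplications = mean(td$n_duplications),
    dup_rate = x$config$dup_rate,
    loss_rate = x$config$loss_rate
  )
}
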