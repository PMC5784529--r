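sm2 <- function() species_map("MZE", c("HSA", "DRE"))

test_that("species overlap labels duplication iff child subtrees share species", {
  sm <- species_map("SPA", "SPB")
  ev <- label_events(parse_newick("(g1_SPA,g2_SPB);"), sm)
  expect_equal(ev$event, "speciation")
  expect_equal(ev$overlap_size, 0L)

  ev2 <- label_events(parse_newick("(g1_SPA,g2_SPA);"), sm)
  expect_equal(ev2$event, "duplication")
  expect_equal(ev2$overlap_size, 1L)

  # multifurcation: any pairwise child overlap marks duplication
  ev3 <- label_events(parse_newick("(g1_SPA,g2_SPB,g3_SPA);"), sm)
  expect_equal(ev3$event, "duplication")
})

test_that("species overlap reproduces simulator truth on loss-free families", {
  sim <- simulate_gene_trees(50, dup_rate = 0.3, loss_rate = 0, seed = 21)
  fams <- usable_families(sim)
  expect_equal(length(fams), 50L)
  for (f in fams) {
    ev <- label_events(f$gene_tree, sim_map())
    truth <- sim_true_events(f)
    expect_equal(nrow(truth), f$gene_tree$Nnode)
    expect_identical(ev$event[match(truth$node, ev$node)], truth$event)
  }
})

test_that("with losses, every duplication call is a true duplication", {
  sim <- simulate_gene_trees(60, dup_rate = 0.3, loss_rate = 0.15, seed = 22)
  n_called <- 0L
  for (f in usable_families(sim)) {
    ev <- label_events(f$gene_tree, sim_map())
    truth <- sim_true_events(f)
    joined <- merge(ev, truth, by = "node", suffixes = c("_called", "_true"))
    called_dup <- joined[joined$event_called == "duplication", ]
    n_called <- n_called + nrow(called_dup)
    expect_true(all(called_dup$event_true == "duplication"))
  }
  expect_gt(n_called, 0L)
})

test_that("smallest containing subtree walks to the first reference ancestor", {
  tr <- parse_newick("((q_MZE:1,h_HSA:1):1,x_DRE:1);")
  node <- smallest_containing_subtree(tr, "q_MZE", "HSA", sm2())
  expect_equal(node, tree_mrca(tr, c("q_MZE", "h_HSA")))
  expect_true(is.na(
    smallest_containing_subtree(parse_newick("(q_MZE:1,x_DRE:1);"),
                                "q_MZE", "HSA", sm2())
  ))
  expect_error(smallest_containing_subtree(tr, "nope", "HSA", sm2()),
               "not in tree")

  for (seed in 41:48) {
    tr <- rand_gene_tree(25, seed)
    sp <- resolve_species(tr$tip.label, sim_map())
    q <- tr$tip.label[sp == "MZE"][1]
    if (is.na(q)) next
    expect_equal(
      smallest_containing_subtree(tr, q, "HSA", sim_map()),
      bf_smallest_subtree(tr, q, "HSA", sim_map())
    )
  }
})

test_that("closest homolog minimises patristic distance with label tie-break", {
  tr <- parse_newick("((q_MZE:1,h1_HSA:1):1,h2_HSA:5);")
  hit <- closest_homolog(tr, "q_MZE", "HSA", sm2())
  expect_equal(hit$leaf, "h1_HSA")
  expect_equal(hit$distance, 2)

  # single reference leaf in the subtree wins regardless of distance
  tr2 <- parse_newick("((q_MZE:1,h1_HSA:99):1,x_DRE:1);")
  expect_equal(closest_homolog(tr2, "q_MZE", "HSA", sm2())$leaf, "h1_HSA")

  # exact tie inside the clade broken lexicographically
  tr3 <- parse_newick("((q_MZE:1,(hA_HSA:2,hB_HSA:2):1):1,d_DRE:1);")
  expect_equal(closest_homolog(tr3, "q_MZE", "HSA", sm2())$leaf, "hA_HSA")

  for (seed in 51:58) {
    tr <- rand_gene_tree(25, seed)
    sp <- resolve_species(tr$tip.label, sim_map())
    q <- tr$tip.label[sp == "MZE"][1]
    if (is.na(q)) next
    want <- bf_closest(tr, q, "HSA", sim_map())
    got <- closest_homolog(tr, q, "HSA", sim_map())
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$leaf, want$leaf)
      expect_equal(got$distance, want$distance, tolerance = 1e-9)
    }
  }
})

test_that("ortholog/paralog classification is symmetric and exhaustive", {
  tr <- parse_newick("((q_MZE:1,h_HSA:1):1,x_DRE:1);")
  expect_equal(classify_relationship(tr, "q_MZE", "h_HSA", map = sm2()),
               "ortholog")
  tr2 <- parse_newick("(q_MZE:2,(a_MZE:1,h_HSA:1):1);")
  expect_equal(classify_relationship(tr2, "q_MZE", "h_HSA", map = sm2()),
               "paralog")
  for (seed in 61:64) {
    tr <- rand_gene_tree(15, seed)
    labs <- tr$tip.label
    a <- labs[2]; b <- labs[9]
    r1 <- classify_relationship(tr, a, b, map = sim_map())
    r2 <- classify_relationship(tr, b, a, map = sim_map())
    expect_identical(r1, r2)
    expect_true(r1 %in% c("ortholog", "paralog"))
  }
})

test_that("classification agrees with simulator truth on loss-free families", {
  sim <- simulate_gene_trees(25, dup_rate = 0.3, loss_rate = 0, seed = 23)
  for (f in usable_families(sim)) {
    tr <- f$gene_tree
    truth <- sim_true_events(f)
    sp <- resolve_species(tr$tip.label, sim_map())
    qs <- tr$tip.label[sp %in% sim_map()$query_species]
    refs <- tr$tip.label[sp == "HSA"]
    if (length(refs) == 0L) next
    for (q in head(qs, 3)) {
      r <- refs[1]
      got <- classify_relationship(tr, q, r, map = sim_map())
      true_ev <- truth$event[truth$node == tree_mrca(tr, c(q, r))]
      expect_identical(got,
                       if (true_ev == "speciation") "ortholog" else "paralog")
    }
  }
})

test_that("one-to-X multiplicity and median copy number follow the clade", {
  # one-to-two: two query-species copies beside one human leaf
  tr <- parse_newick("((q_MZE:1,p_MZE:1):1,h_HSA:1);")
  m <- ortho_multiplicity(tr, "q_MZE", "h_HSA", sm2())
  expect_equal(m$multiplicity, "one-to-two")
  expect_equal(m$x_value, 2L)
  expect_equal(m$median_query_copies, 2) # MZE is the only configured genome

  m2 <- ortho_multiplicity(parse_newick("(q_MZE:1,h_HSA:1);"),
                           "q_MZE", "h_HSA", sm2())
  expect_equal(m2$multiplicity, "one-to-one")
  expect_equal(m2$x_value, 1L)
  expect_equal(m2$median_query_copies, 1)

  # four query genomes with two copies each: median 2
  sm4 <- default_sim_species_map()
  tr4 <- parse_newick(paste0(
    "((((a1_MZE:1,a2_PNY:1):1,(a3_ABU:1,a4_NBR:1):1):1,",
    "((b1_MZE:1,b2_PNY:1):1,(b3_ABU:1,b4_NBR:1):1):1):1,h_HSA:4);"
  ))
  m4 <- ortho_multiplicity(tr4, "a1_MZE", "h_HSA", sm4)
  expect_equal(m4$median_query_copies, 2)
  expect_equal(m4$x_value, 2L)

  # zeros for configured genomes absent from the clade are counted
  m0 <- ortho_multiplicity(parse_newick("(q_MZE:1,h_HSA:1);"),
                           "q_MZE", "h_HSA", sm4)
  expect_equal(m0$median_query_copies, 0) # counts {1,0,0,0}
  m0b <- ortho_multiplicity(parse_newick("(q_MZE:1,h_HSA:1);"),
                            "q_MZE", "h_HSA", sm4,
                            count_zero_species = FALSE)
  expect_equal(m0b$median_query_copies, 1)

  # contract: non-ortholog pair is an error
  trp <- parse_newick("(q_MZE:2,(a_MZE:1,h_HSA:1):1);")
  expect_error(ortho_multiplicity(trp, "q_MZE", "h_HSA", sm2()),
               class = "orthograft_contract_error")
})

test_that("call_gene composes the pipeline per reference species", {
  tr <- parse_newick("((q_MZE:1,h1_HSA:1):1,h2_HSA:5);")
  calls <- call_gene(tr, "q_MZE", sm2())
  expect_equal(nrow(calls), 2L)
  hsa <- calls[calls$reference_species == "HSA", ]
  expect_equal(hsa$relationship, "ortholog")
  expect_equal(hsa$closest_reference_protein, "h1_HSA")
  expect_equal(hsa$distance, 2)
  expect_equal(hsa$multiplicity, "one-to-one")
  dre <- calls[calls$reference_species == "DRE", ]
  expect_equal(dre$relationship, "no_homolog")
  # no-homolog rows carry no reference fields
  expect_true(all(is.na(dre$closest_reference_protein), is.na(dre$distance),
                  is.na(dre$multiplicity), is.na(dre$x_value),
                  is.na(dre$median_query_copies)))
})

test_that("call invariants hold over a simulated batch and are deterministic", {
  sim <- simulate_gene_trees(20, dup_rate = 0.3, loss_rate = 0.1, seed = 24)
  fams <- usable_families(sim)
  trees <- setNames(lapply(fams, `[[`, "gene_tree"),
                    paste0("fam", seq_along(fams)))
  calls <- call_genes(trees, sim_map())
  calls2 <- call_genes(trees, sim_map())
  expect_identical(calls, calls2)

  n_query_leaves <- sum(vapply(trees, function(t) {
    sum(resolve_species(t$tip.label, sim_map()) %in%
          sim_map()$query_species)
  }, integer(1)))
  expect_equal(nrow(calls), 2L * n_query_leaves)

  is_orth <- calls$relationship == "ortholog"
  expect_true(all(!is.na(calls$multiplicity[is_orth])))
  expect_true(all(is.na(calls$multiplicity[!is_orth])))
  no_hom <- calls$relationship == "no_homolog"
  expect_true(all(is.na(calls$closest_reference_protein[no_hom])))
  expect_true(all(!is.na(calls$closest_reference_protein[!no_hom])))
  expect_true(all(calls$distance[!no_hom] >= 0))
})
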