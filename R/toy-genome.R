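#' Generate a toy genome fixture set
#'
#' Writes a small, fully synthetic genome (about 20 genes for a single query
#' species) together with every input the pipeline consumes: a protein FASTA
#' with multi-isoform genes, a GFF3 annotation linking isoforms to genes, a
#' per-domain profile-search hit table, per-family Newick gene trees that
#' already contain the query proteins (so classification can run without
#' external grafting), a leaf-to-species map, an id-to-symbol map and a
#' pipeline config. The fixture engineers known truths used by end-to-end
#' tests: one gene with three isoforms of distinct lengths, exactly one
#' chimeric protein hitting two families in disjoint regions, and two genes
#' with no family hit.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the random amino-acid sequences.
#' @return Invisibly, a list with the file `paths` and a `manifest`
#'   describing the engineered structure (`genes`, `chimera_protein`,
#'   `no_hit_genes`, `families`).
#' @export
make_toy_genome <- function(dir, seed = 1L) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)

  n_genes <- 20L
  genes <- sprintf("tg%02d", seq_len(n_genes))
  # isoform counts: tg01 has 3, even-numbered genes 2, the rest 1
  n_iso <- ifelse(genes == "tg01", 3L,
                  ifelse(seq_len(n_genes) %% 2L == 0L, 2L, 1L))
  iso <- tibble(
    gene_id = rep(genes, n_iso),
    isoform = unlist(lapply(n_iso, seq_len))
  ) |>
    mutate(
      protein_id = sprintf("%s.t%d", .data$gene_id, .data$isoform),
      # longest isoform is always .t2 when present, .t1 otherwise;
      # tg01's three isoforms have pairwise distinct lengths
      length = 100L + 7L * rep(seq_len(n_genes), n_iso) +
        c(0L, 60L, 30L)[.data$isoform]
    )
  chosen <- iso |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$length), .by_group = TRUE) |>
    slice(1L) |>
    ungroup()

  aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  seqs <- withr::with_seed(seed, {
    vapply(iso$length, function(l) {
      paste(sample(aa_alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
  })

  paths <- list(
    proteins = file.path(dir, "proteins.fasta"),
    annotation = file.path(dir, "annotation.gff3"),
    hits = file.path(dir, "hits.domtbl"),
    trees_dir = file.path(dir, "trees"),
    species_map = file.path(dir, "species_map.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    config = file.path(dir, "config.yaml")
  )

  writeLines(
    as.vector(rbind(paste0(">", iso$protein_id), seqs)),
    paths$proteins
  )

  gff <- c("##gff-version 3")
  pos <- 1L
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    g_iso <- iso[iso$gene_id == g, ]
    span <- max(g_iso$length) * 3L
    gff <- c(gff, sprintf(
      "scf1\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s", pos, pos + span, g
    ))
    for (j in seq_len(nrow(g_iso))) {
      gff <- c(gff, sprintf(
        "scf1\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
        pos, pos + g_iso$length[j] * 3L, g_iso$protein_id[j], g
      ))
    }
    pos <- pos + span + 100L
  }
  writeLines(gff, paths$annotation)

  # family layout: F01..F08 hold two genes each (tg01..tg16); tg17 is the
  # engineered chimera (F09 + F10, disjoint regions, F10 scores higher);
  # tg18 -> F09; tg19, tg20 have no hits
  fam_of <- setNames(rep(sprintf("F%02d", 1:8), each = 2L), genes[1:16])
  fam_of["tg18"] <- "F09"
  no_hit_genes <- c("tg19", "tg20")
  chimera_gene <- "tg17"
  chimera_protein <- chosen$protein_id[chosen$gene_id == chimera_gene]

  dom_row <- function(fam, prot, qlen, score, evalue, from, to) {
    sprintf(paste0(
      "%s - 400 %s - %d %.1e %.1f 0.1 1 1 %.1e %.1e %.1f 0.1 ",
      "1 380 %d %d %d %d 0.95 -"
    ), fam, prot, qlen, evalue, score + 5, evalue, evalue, score, from, to,
      from, to)
  }
  hits <- c("# toy per-domain hit table", "#")
  for (g in names(fam_of)) {
    p <- chosen[chosen$gene_id == g, ]
    hits <- c(hits, dom_row(fam_of[[g]], p$protein_id, p$length,
                            score = 150 + p$length / 10, evalue = 1e-40,
                            from = 5L, to = p$length - 5L))
  }
  pch <- chosen[chosen$gene_id == chimera_gene, ]
  hits <- c(
    hits,
    dom_row("F09", pch$protein_id, pch$length, score = 200, evalue = 1e-45,
            from = 1L, to = 90L),
    dom_row("F10", pch$protein_id, pch$length, score = 250, evalue = 1e-60,
            from = 130L, to = pch$length)
  )
  writeLines(hits, paths$hits)

  # per-family trees already containing the chosen query proteins,
  # exercising the classification patterns: one-to-one, one-to-two,
  # paralog, many-to-many, and a family with no human leaf
  p_of <- setNames(chosen$protein_id, chosen$gene_id)
  fam_tree <- function(fam, members) {
    p1 <- p_of[[members[1L]]]
    p2 <- if (length(members) > 1L) p_of[[members[2L]]] else NA
    h <- sprintf("h_%s", fam)
    d <- sprintf("d_%s", fam)
    switch(fam,
      F02 = sprintf("((%s:0.05,%s:0.05):0.1,(%s:0.1,%s:0.1):0.05);",
                    p1, p2, h, d),                    # one-to-two
      F03 = sprintf("((%s:0.1,(%s:0.08,%s:0.08):0.02):0.1,%s:0.3);",
                    p1, p2, h, d),                    # p1 paralog, p2 ortholog
      F04 = sprintf("(%s:0.1,(%s:0.1,%s:0.1):0.05);",
                    p1, p2, d),                       # no human leaf
      F05 = sprintf(paste0(
        "(((((%s:0.02,pny_a_%s:0.02):0.02,(abu_a_%s:0.02,nbr_a_%s:0.02)",
        ":0.02):0.04,((%s:0.02,pny_b_%s:0.02):0.02,(abu_b_%s:0.02,",
        "nbr_b_%s:0.02):0.02):0.04):0.1,%s:0.2):0.05,%s:0.25);"),
        p1, fam, fam, fam, p2, fam, fam, fam, h, d),  # one-to-two, 4 genomes
      F07 = sprintf("((%s:0.05,%s:0.05):0.05,((%s:0.05,h2_%s:0.2):0.1,%s:0.2):0.02);",
                    p1, p2, h, fam, d),               # many-to-many
      F09 = sprintf("((%s:0.1,%s:0.1):0.1,%s:0.2);", p1, h, d),
      F10 = sprintf("((%s:0.1,%s:0.1):0.1,%s:0.2);", p1, h, d),
      # default: two independent one-to-one ortholog pairs
      sprintf("((%s:0.1,%s:0.1):0.2,((%s:0.1,h2_%s:0.1):0.1,%s:0.2):0.1);",
              p1, h, p2, fam, d)
    )
  }
  fams <- sort(unique(c(fam_of, "F10")))
  members_of <- lapply(fams, function(f) {
    if (f == "F10") chimera_gene else names(fam_of)[fam_of == f]
  })
  names(members_of) <- fams
  leaf_species <- character(0)
  for (f in fams) {
    nwk <- fam_tree(f, members_of[[f]])
    writeLines(nwk, file.path(paths$trees_dir, paste0(f, ".nwk")))
    tr <- parse_newick(nwk)
    sp <- dplyr::case_when(
      tr$tip.label %in% p_of ~ "MZE",
      startsWith(tr$tip.label, "h") ~ "HSA",
      startsWith(tr$tip.label, "d") ~ "DRE",
      startsWith(tr$tip.label, "pny") ~ "PNY",
      startsWith(tr$tip.label, "abu") ~ "ABU",
      startsWith(tr$tip.label, "nbr") ~ "NBR"
    )
    leaf_species <- c(leaf_species, setNames(sp, tr$tip.label))
  }
  # every chosen protein (including no-hit genes) must resolve to a species
  leaf_species <- c(leaf_species,
                    setNames(rep("MZE", nrow(chosen)), chosen$protein_id))
  leaf_species <- leaf_species[!duplicated(names(leaf_species))]
  writeLines(
    c("# leaf label\tspecies code",
      paste(names(leaf_species), leaf_species, sep = "\t")),
    paths$species_map
  )

  human_leaves <- sort(names(leaf_species)[leaf_species == "HSA"])
  writeLines(
    paste(human_leaves, paste0("SYM_", toupper(human_leaves)), sep = "\t"),
    paths$id_map
  )

  yaml::write_yaml(list(
    proteins = "proteins.fasta",
    annotation = "annotation.gff3",
    hits = "hits.domtbl",
    trees_dir = "trees",
    species_map = "species_map.tsv",
    id_map = "id_map.tsv",
    query_species = c("MZE", "PNY", "ABU", "NBR"),
    reference_species = c("HSA", "DRE"),
    prune_keep = c("MZE", "HSA", "DRE")
  ), paths$config)

  invisible(list(
    paths = paths,
    manifest = list(
      genes = genes,
      chosen = chosen,
      families = fam_of,
      chimera_gene = chimera_gene,
      chimera_protein = chimera_protein,
      no_hit_genes = no_hit_genes
    )
  ))
}
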