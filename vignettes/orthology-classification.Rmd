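---
title: "Gene-tree orthology classification: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-tree orthology classification: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthograft)
```

## The problem

When a genome is newly sequenced, the function of most of its genes can
only be inferred by homology to proteins characterised in reference
species. Homologs split into orthologs (diverged by speciation, expected to
retain function) and paralogs (diverged by gene duplication, free to
acquire new roles), so a useful annotation resource must not just find the
nearest reference protein but say *how* the two genes are related. In
teleost fish the distinction is especially loaded: an ancestral genome
duplication left many genes in duplicate, so a single human gene frequently
corresponds to two co-orthologous fish genes that may have partitioned the
ancestral function between them.

`orthograft` implements the family-tree route to this classification. Each
query protein is placed in a reference gene family; the family's gene tree
(containing the query leaves) is then analysed per query gene.

## The classification procedure

Given a family gene tree with branch lengths (substitutions/site) and a
species map resolving each leaf to a species code:

1. **Midpoint rooting.** The root is placed at the midpoint of the longest
   leaf-to-leaf path, which minimises the maximum root-to-leaf distance.
   Rooting always precedes event labelling, also for pre-rooted input
   (`root = "keep"` opts out), so every tree is treated identically.
2. **Species-overlap event labelling.** An internal node is a
   *duplication* iff at least two of its child subtrees share a species,
   else a *speciation*. The rule needs no species tree and no binary
   resolution; for multifurcations any pairwise overlap marks a
   duplication, the conservative generalisation.
3. **Smallest containing subtree.** Walking from the query leaf rootwards,
   the first ancestor whose subtree holds a reference-species leaf defines
   the scope of the comparison. If the root is reached without one, the
   call is `no_homolog` and all reference fields stay absent.
4. **Closest homolog.** Among reference leaves *inside that subtree*, the
   one at minimal patristic (path-sum) distance from the query leaf wins.
   We read "shortest branch length" as patristic distance: a terminal-edge
   length ignores the query entirely, whereas the path sum is the standard
   closeness measure on trees and the only reading that uses both leaves.
5. **Ortholog/paralog.** The event label at the MRCA of query and chosen
   reference leaf decides; the call is symmetric in the two leaves.
6. **Multiplicity and copy number.** For orthologs, the containing subtree
   from step 3 is the ortholog clade. `X` counts leaves of the query's own
   species there; with exactly one reference leaf the multiplicity is
   `one-to-X` (`one-to-two` marking the typical teleost-duplication
   pattern). With two or more reference leaves we report `many-to-many`
   (X ≥ 2) or `many-to-one` (X = 1); these labels are an extension — the
   one-to-X vocabulary cannot describe multi-reference clades — and are
   flagged as such here. The median copy number is the median of each
   configured query genome's leaf count in the clade.

### Numerical choices and tie-breaks

* Every tie-break is lexicographic on leaf labels: the diameter pair in
  midpoint rooting, and equidistant closest homologs. This makes
  `call_gene()` a pure function of its inputs — identical inputs give
  byte-identical records across runs and platforms.
* A midpoint that falls exactly on an existing node (tolerance 1e-12
  relative to the diameter) makes that node the root; no zero-length edge
  is inserted. Zero-length branches elsewhere are legal; only negative
  lengths are rejected at parse time.
* Branch lengths absent from a Newick string stay absent (`NA`); any
  distance computation whose path crosses such an edge errors rather than
  silently zero-filling.
* Newick support values are accepted both as numeric internal-node labels
  and as `)[90]`-style bracket annotations; the internal-label form is
  emitted. Lengths are written with 10 significant digits so parse/write
  round trips are structural identities well below the 1e-9 comparison
  tolerance.
* `median_query_copies` counts configured query genomes absent from the
  clade as zeros by default ("all query genomes" includes genomes that
  lost the gene); `count_zero_species = FALSE` restricts to genomes
  present.

## Family assignment and chimera detection

Upstream of the trees, proteins are assigned to families from per-domain
profile-search tables: the best family maximises the summed domain bit
score (robust for multi-domain proteins; `score = "max"` switches to
best-single-domain), with ties resolved by lower minimum e-value then
family id. A gene model is flagged as a possible fusion of two genes when
its two top families hit regions at least 50 aa long overlapping by at most
10% of the shorter region. Those defaults are permissive by design: real
fusion artefacts observed in draft annotations are long, well-separated
blocks, and the flag is an invitation to re-examine the model (the detail
string records both families and regions), not a verdict. Two families
hitting the *same* region are competing homology and never flagged;
flagging is monotone in the overlap threshold.

Alignment of new sequences into the family alignment and their placement
into the family tree are delegated to external tools; the package prepares
deterministic per-family bundles and consumes the resulting trees. This
keeps the tested surface at the contract boundary rather than wrapping
heavyweight inference.

## What the simulator emulates — and what it does not

`simulate_gene_trees()` generates ground truth for the classifier:
birth–death gene-family evolution along a fixed 10-taxon species tree
(four query cichlid genomes, tilapia, zebrafish, human, mouse, fly, worm;
arbitrary fixed branch lengths in time units). Duplications split a lineage
(a true duplication node), losses terminate it, speciations copy every
surviving lineage into both descendant branches. Extinct lineages are
pruned; unary nodes are collapsed with lengths summed, and their event
labels are dropped from the truth set because no tree node remains to
compare against.

Two properties make it a sharp oracle:

* With `loss_rate = 0`, species-overlap labelling is provably exact on
  simulator output, so the expected agreement is 100% of internal nodes —
  any mismatch is a bug, not noise.
* With losses, a true speciation node can never gain overlapping child
  species sets, so every duplication *call* remains correct (precision 1);
  duplications can be *missed* when loss hides the overlap, so recall is
  reported but not asserted.

Branch lengths are taken directly from time along the species tree with no
rate heterogeneity, so midpoint rooting recovers a root on the correct edge
in the no-loss case — a test aid, not a biological claim. The simulator
deliberately omits what real family trees contain: rate variation across
lineages (which can defeat midpoint rooting), alignment and placement
error, incomplete families, annotation errors, and incomplete lineage
sorting. Passing the simulator-based tests therefore validates the
*classification logic*, not the upstream tree quality; on real data the
dominant error source is the tree, as the chimeric-annotation examples
illustrate.

Default rates (`dup_rate = 0.1`, `loss_rate = 0.05` per unit branch
length) give moderately sized families with occasional turnover, the
regime the classifier targets. Validation runs use `dup_rate = 0.3`
(families of a few dozen leaves on this tree; the loss-free oracle and the
precision check use 200 families each, problem sizes of roughly 2,500–
3,000 internal nodes) — large enough to exercise multifurcating clades and
deep duplications while keeping the full test suite under a minute.

## Degenerate inputs

One-leaf trees cannot be midpoint rooted (error). Families whose simulated
lineages all die are recorded as empty, not errors. Proteins present in
the annotation but absent from the FASTA (and vice versa) are excluded and
counted, with a warning. An empty hit table, an empty id map, or a pruning
that would retain no leaves are explicit errors. Unresolvable leaf labels
always error — there is no silent "unknown species" bucket, since a
missing mapping would otherwise corrupt overlap sets invisibly.

## Known limitations

* Midpoint rooting is the only rooting offered; outgroup rooting on a
  user-chosen species would be a natural extension.
* The species-overlap rule over-calls duplications when a family tree is
  topologically wrong; no reconciliation against a dated species tree is
  attempted, and no duplication-time inference beyond the one-to-two
  label.
* `many-to-many`/`many-to-one` labels extend the one-to-X vocabulary; the
  category summary buckets both under `many_to_many_ortholog`.
* The report's column layout fixes symbol and copy-number columns to the
  first reference species, mirroring the per-species spreadsheet
  deliverable it reconstructs.
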