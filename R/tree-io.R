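#' Parse a Newick string into a gene tree
#'
#' Reads one tree in Newick format into an [ape::phylo] object and validates
#' it as a gene tree: unique non-empty leaf labels, non-negative branch
#' lengths, a single root. Two support-value dialects are accepted: internal
#' node labels that parse as numbers in `[0, 100]` (the form emitted by most
#' maximum-likelihood programs) and bracketed annotations directly after a
#' closing parenthesis, e.g. `")[90]:0.1"`, which are normalised to the
#' internal-label form. Branch lengths absent from the input are stored as
#' `NA`, never silently as zero.
#'
#' @param text A single Newick string. A trailing semicolon is tolerated
#'   absent.
#' @return A `phylo` object. Internal-node support values, when present, live
#'   in `node.label`; [node_supports()] extracts them numerically.
#' @seealso [write_newick()], [read_newick()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:2,C:4);")
#' node_supports(tr)
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    og_abort("`text` must be a single Newick string.")
  }
  s <- trimws(text)
  if (!nzchar(s)) og_abort("empty Newick string.")
  check_balanced_parens(s)
  # bracket-dialect supports: ")[90]" -> ")90"
  s <- gsub("\\)\\s*\\[([0-9eE.+-]+)\\]", ")\\1", s)
  if (!grepl(";\\s*$", s)) s <- paste0(s, ";")
  tr <- tryCatch(
    ape::read.tree(text = s),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    og_abort("malformed Newick string: could not be parsed.")
  }
  validate_gene_tree(tr)
  tr
}

check_balanced_parens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        og_abort(sprintf(
          "unbalanced parentheses: unmatched ')' at position %d.", i
        ))
      }
    }
  }
  if (depth > 0L) {
    og_abort(sprintf(
      "unbalanced parentheses: %d '(' never closed.", depth
    ))
  }
  invisible(TRUE)
}

#' Validate the gene-tree invariants of a phylo object
#'
#' Checks leaf-label uniqueness and non-emptiness and that every stored
#' branch length is non-negative (missing lengths are legal and kept as
#' `NA`). Called by [parse_newick()] and available for trees built by other
#' means.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, on success.
#' @export
validate_gene_tree <- function(tree) {
  if (!inherits(tree, "phylo")) og_abort("not a `phylo` tree.")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) og_abort("leaf with empty label.")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0L) {
    og_abort(sprintf(
      "duplicate leaf label(s): %s.", paste(dup, collapse = ", ")
    ))
  }
  el <- tree$edge.length
  if (!is.null(el)) {
    # ape encodes absent lengths in a mixed tree as NaN; keep them NA
    bad <- which(!is.nan(el) & !is.na(el) & el < 0)
    if (length(bad) > 0L) {
      child <- tree$edge[bad[1L], 2L]
      lab <- if (child <= length(labs)) labs[child] else paste0("node ", child)
      og_abort(sprintf(
        "negative branch length %g on the edge to %s.", el[bad[1L]], lab
      ))
    }
  }
  invisible(tree)
}

#' Serialize a gene tree to Newick
#'
#' Branch lengths are written with 10 significant digits so that a
#' parse/write round trip is a structural identity to well below 1e-9.
#' Internal-node labels (support values) are emitted in the plain-label
#' dialect. Trees without branch lengths produce Newick without `:` tokens.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_gene_tree(tree)
  s <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read Newick trees from a file
#'
#' One tree per line (blank lines and lines starting with `#` are skipped).
#'
#' @param path Path to a Newick file.
#' @return A single `phylo` if the file holds one tree, otherwise a list of
#'   `phylo` objects.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) og_abort(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) og_abort(sprintf("no trees in %s", path))
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1L]] else trees
}

#' Extract numeric support values from internal-node labels
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` with `NA` where a node has
#'   no numeric label, or all-`NA` when the tree has no node labels.
#' @export
node_supports <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & (sup < 0 | sup > 100)] <- NA_real_
  sup
}
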