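#' Parse a per-domain profile-search hit table
#'
#' Reads the whitespace-delimited per-domain tabular output of a profile-HMM
#' scan (the `domtblout` dialect: 22 fixed columns followed by a free-text
#' description, `#` comment lines). One hit row is produced per domain, with
#' the family profile as the target and the protein as the query; the
#' per-domain bit score, independent e-value and the alignment coordinates
#' on the protein are retained.
#'
#' @param file Path to the hit table.
#' @return A tibble of family hits: `protein_id`, `family_id`, `bit_score`,
#'   `e_value`, `query_start`, `query_end` (1-based inclusive amino-acid
#'   coordinates). Malformed rows are rejected with a warning naming their
#'   line numbers.
#' @export
parse_hit_table <- function(file) {
  if (!file.exists(file)) og_abort(sprintf("no such file: %s", file))
  lines <- readLines(file, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) og_abort("no parseable rows in hit table.")
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- integer(0)
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    p <- parts[[i]]
    if (length(p) < 22L) { bad <- c(bad, idx[i]); next }
    score <- suppressWarnings(as.numeric(p[14L]))
    eval_ <- suppressWarnings(as.numeric(p[13L]))
    qs <- suppressWarnings(as.integer(p[18L]))
    qe <- suppressWarnings(as.integer(p[19L]))
    if (anyNA(c(score, eval_, qs, qe)) || qs > qe || eval_ < 0) {
      bad <- c(bad, idx[i]); next
    }
    rows[[i]] <- tibble(
      protein_id = p[4L], family_id = p[1L],
      bit_score = score, e_value = eval_,
      query_start = qs, query_end = qe
    )
  }
  out <- bind_rows(rows)
  if (length(bad) > 0L) {
    warn(sprintf("rejected %d malformed hit row(s) at line(s): %s.",
                 length(bad), paste(bad, collapse = ", ")))
  }
  if (nrow(out) == 0L) og_abort("no parseable rows in hit table.")
  out
}

#' Assign each protein to its best-matching gene family
#'
#' The best family for a protein is the one with the highest total bit score
#' over that family's domains (`score = "sum"`, robust for multi-domain
#' proteins) or the single best domain (`score = "max"`). Ties go to the
#' lower minimum e-value, then to the lexicographically smallest family id.
#' Proteins listed in `all_proteins` but absent from the hits are returned
#' as unassigned.
#'
#' @param hits A tibble from [parse_hit_table()].
#' @param all_proteins Optional character vector of every protein scanned;
#'   proteins with no hit appear with `best_family_id = NA`.
#' @param score `"sum"` (default) or `"max"` domain-score aggregation.
#' @param max_overlap_frac,min_region Chimera-detection parameters passed to
#'   [flag_chimeric()].
#' @return A tibble with one row per protein: `protein_id`,
#'   `best_family_id` (`NA` when unassigned), `best_bit_score`, `e_value`,
#'   `chimera_flag`, `chimera_detail`.
#' @export
assign_families <- function(hits, all_proteins = NULL,
                            score = c("sum", "max"),
                            max_overlap_frac = 0.1, min_region = 50) {
  score <- match.arg(score)
  agg <- hits |>
    group_by(.data$protein_id, .data$family_id) |>
    summarise(
      fam_score = if (score == "sum") sum(.data$bit_score)
                  else max(.data$bit_score),
      fam_evalue = min(.data$e_value),
      .groups = "drop"
    )
  best <- agg |>
    group_by(.data$protein_id) |>
    arrange(dplyr::desc(.data$fam_score), .data$fam_evalue, .data$family_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    rename(best_family_id = "family_id", best_bit_score = "fam_score",
           e_value = "fam_evalue")
  chim <- flag_chimeric(hits, max_overlap_frac = max_overlap_frac,
                        min_region = min_region, score = score)
  out <- left_join(best, chim, by = "protein_id")
  if (!is.null(all_proteins)) {
    missing <- setdiff(all_proteins, out$protein_id)
    if (length(missing) > 0L) {
      out <- bind_rows(out, tibble(
        protein_id = missing, best_family_id = NA_character_,
        best_bit_score = NA_real_, e_value = NA_real_,
        chimera_flag = FALSE, chimera_detail = NA_character_
      ))
    }
    out <- out[out$protein_id %in% all_proteins, ]
  }
  arrange(out, .data$protein_id)
}

#' Flag proteins whose hits look like a fusion of two genes
#'
#' A predicted gene model that erroneously fuses two adjacent genes yields
#' one protein matching two unrelated families in disjoint regions. A
#' protein is flagged when its two top-scoring families hit regions that (a)
#' are both at least `min_region` amino acids long and (b) overlap by at
#' most `max_overlap_frac` of the shorter region. Two families hitting the
#' same region are competing homology, not fusion, and are not flagged. The
#' detail string records both families and regions so the call can be
#' re-examined (e.g. by sequence search).
#'
#' @inheritParams assign_families
#' @param max_overlap_frac Maximum allowed overlap, as a fraction of the
#'   shorter region, for the regions to count as disjoint. Default 0.1.
#' @param min_region Minimum region length in amino acids. Default 50.
#' @return A tibble with `protein_id`, `chimera_flag`, `chimera_detail`
#'   (e.g. `"FAM1:1-300 + FAM2:350-600"`, `NA` when not flagged).
#' @export
flag_chimeric <- function(hits, max_overlap_frac = 0.1, min_region = 50,
                          score = c("sum", "max")) {
  score <- match.arg(score)
  regions <- hits |>
    group_by(.data$protein_id, .data$family_id) |>
    summarise(
      fam_score = if (score == "sum") sum(.data$bit_score)
                  else max(.data$bit_score),
      start = min(.data$query_start),
      end = max(.data$query_end),
      .groups = "drop"
    )
  per_protein <- split(regions, regions$protein_id)
  rows <- lapply(per_protein, function(df) {
    flag <- FALSE
    detail <- NA_character_
    if (nrow(df) >= 2L) {
      df <- df |> arrange(dplyr::desc(.data$fam_score), .data$family_id)
      a <- df[1L, ]
      b <- df[2L, ]
      w_a <- a$end - a$start + 1L
      w_b <- b$end - b$start + 1L
      ov <- max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
      if (w_a >= min_region && w_b >= min_region &&
          ov <= max_overlap_frac * min(w_a, w_b)) {
        flag <- TRUE
        detail <- sprintf("%s:%d-%d + %s:%d-%d",
                          a$family_id, a$start, a$end,
                          b$family_id, b$start, b$end)
      }
    }
    tibble(protein_id = df$protein_id[1L], chimera_flag = flag,
           chimera_detail = detail)
  })
  arrange(bind_rows(rows), .data$protein_id)
}

#' Prepare per-family grafting bundles for external alignment/placement
#'
#' Alignment of new proteins into a family's reference alignment and their
#' placement into the family tree are delegated to external tools (e.g.
#' `mafft --add` followed by maximum-likelihood placement). This operation
#' defines that contract: for every family with at least one assigned
#' protein and an available reference tree it writes a bundle directory
#' containing the new sequences (`new_sequences.fasta`), the reference
#' alignment (`reference_alignment.fasta`, when available), the reference
#' tree (`reference.nwk`) and a `manifest.tsv`. Bundles are deterministic:
#' re-running on unchanged inputs reproduces byte-identical manifests.
#'
#' @param assignments Tibble from [assign_families()].
#' @param sequences `AAStringSet` (or FASTA path) holding every assigned
#'   protein's sequence.
#' @param family_trees Named character vector of Newick file paths (names
#'   are family ids), or a directory containing `<family>.nwk` files.
#' @param family_alignments Optional; same conventions, `<family>.fasta`.
#' @param out_dir Output directory for the bundles.
#' @return A tibble with one row per assigned family: `family_id`,
#'   `n_sequences`, `bundle_dir`, `status` (`"prepared"` or
#'   `"skipped_no_tree"`).
#' @export
prepare_graft_bundle <- function(assignments, sequences, family_trees,
                                 family_alignments = NULL, out_dir) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readAAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  lookup_files <- function(x, ext) {
    if (is.null(x)) return(character(0))
    if (length(x) == 1L && is.null(names(x)) && dir.exists(x)) {
      f <- list.files(x, pattern = paste0("\\.", ext, "$"),
                      full.names = TRUE)
      return(setNames(f, sub(paste0("\\.", ext, "$"), "", basename(f))))
    }
    x
  }
  trees <- lookup_files(family_trees, "nwk")
  alns <- lookup_files(family_alignments, "fasta")

  asg <- assignments |>
    filter(!is.na(.data$best_family_id)) |>
    arrange(.data$best_family_id, .data$protein_id)
  missing_seq <- setdiff(asg$protein_id, names(sequences))
  if (length(missing_seq) > 0L) {
    og_abort(sprintf("no sequence for assigned protein(s): %s.",
                     paste(missing_seq, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fams <- sort(unique(asg$best_family_id))
  rows <- lapply(fams, function(fam) {
    members <- asg$protein_id[asg$best_family_id == fam]
    if (!fam %in% names(trees)) {
      return(tibble(family_id = fam, n_sequences = length(members),
                    bundle_dir = NA_character_,
                    status = "skipped_no_tree"))
    }
    bdir <- file.path(out_dir, fam)
    dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sequences[members],
                                file.path(bdir, "new_sequences.fasta"))
    file.copy(trees[[fam]], file.path(bdir, "reference.nwk"),
              overwrite = TRUE)
    if (fam %in% names(alns)) {
      file.copy(alns[[fam]], file.path(bdir, "reference_alignment.fasta"),
                overwrite = TRUE)
    }
    readr::write_tsv(
      tibble(protein_id = members, family_id = fam),
      file.path(bdir, "manifest.tsv"), progress = FALSE
    )
    tibble(family_id = fam, n_sequences = length(members),
           bundle_dir = bdir, status = "prepared")
  })
  bind_rows(rows)
}
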