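# minimal domtblout-style row builder (22 columns + description)
dom_line <- function(fam, prot, score, evalue, from, to) {
  sprintf("%s - 400 %s - 700 %g %g 0.1 1 1 %g %g %g 0.1 1 380 %d %d %d %d 0.9 test",
          fam, prot, evalue, score + 1, evalue, evalue, score,
          from, to, from, to)
}

hits_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".domtbl", .local_envir = parent.frame())
  writeLines(c("# comment", lines), f)
  f
}

test_that("per-domain hit tables parse with coordinates and scores", {
  f <- hits_file(dom_line("F1", "prot1", 120.5, 1e-30, 10, 200))
  h <- parse_hit_table(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$family_id, "F1")
  expect_equal(h$protein_id, "prot1")
  expect_equal(h$bit_score, 120.5)
  expect_equal(h$query_start, 10L)
  expect_equal(h$query_end, 200L)

  f3 <- hits_file(c(
    dom_line("F1", "p", 50, 1e-10, 1, 100),
    dom_line("F1", "p", 40, 1e-8, 150, 250),
    dom_line("F2", "p", 60, 1e-12, 1, 240)
  ))
  h3 <- parse_hit_table(f3)
  expect_equal(nrow(h3), 3L)
  expect_equal(sort(unique(h3$family_id)), c("F1", "F2"))
})

test_that("comment-only and malformed tables are handled", {
  f <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c("# a", "# b"), f)
  expect_error(parse_hit_table(f), "no parseable rows")

  f2 <- hits_file(c(dom_line("F1", "p", 50, 1e-10, 1, 100), "garbage row"))
  expect_warning(h <- parse_hit_table(f2), "line")
  expect_equal(nrow(h), 1L)
})

test_that("best family maximises summed bit score with documented tie rules", {
  f <- hits_file(c(
    dom_line("F1", "p", 30, 1e-10, 1, 100),
    dom_line("F1", "p", 20, 1e-10, 150, 250), # F1 sums to 50
    dom_line("F2", "p", 80, 1e-5, 1, 250)
  ))
  a <- assign_families(parse_hit_table(f))
  expect_equal(a$best_family_id, "F2")
  expect_equal(a$best_bit_score, 80)

  # equal bits: lower e-value wins
  ft <- hits_file(c(
    dom_line("F1", "p", 50, 1e-10, 1, 100),
    dom_line("F2", "p", 50, 1e-5, 1, 100)
  ))
  expect_equal(assign_families(parse_hit_table(ft))$best_family_id, "F1")

  # max-domain mode uses the single best domain
  am <- assign_families(parse_hit_table(f), score = "max")
  expect_equal(am$best_family_id, "F2")

  # proteins without hits become unassigned
  a2 <- assign_families(parse_hit_table(f), all_proteins = c("p", "q"))
  expect_equal(nrow(a2), 2L)
  expect_true(is.na(a2$best_family_id[a2$protein_id == "q"]))
})

test_that("assignment is invariant under permutation of hit rows", {
  lines <- c(
    dom_line("F2", "a", 10, 1e-4, 1, 60),
    dom_line("F1", "a", 25, 1e-9, 1, 100),
    dom_line("F3", "b", 99, 1e-30, 5, 300),
    dom_line("F1", "b", 12, 1e-3, 5, 300)
  )
  a1 <- assign_families(parse_hit_table(hits_file(lines)))
  a2 <- assign_families(parse_hit_table(hits_file(rev(lines))))
  expect_identical(a1, a2)
})

test_that("chimera flagging fires on disjoint regions only", {
  # disjoint top-two families: the fusion signature
  f <- hits_file(c(
    dom_line("FA", "p", 200, 1e-40, 1, 300),
    dom_line("FB", "p", 250, 1e-50, 350, 600)
  ))
  ch <- flag_chimeric(parse_hit_table(f))
  expect_true(ch$chimera_flag)
  expect_match(ch$chimera_detail, "FA:1-300")
  expect_match(ch$chimera_detail, "FB:350-600")

  # full overlap: competing homology, not fusion
  f2 <- hits_file(c(
    dom_line("FA", "p", 200, 1e-40, 10, 290),
    dom_line("FB", "p", 250, 1e-50, 10, 290)
  ))
  expect_false(flag_chimeric(parse_hit_table(f2))$chimera_flag)

  # single family: never flagged
  f3 <- hits_file(dom_line("FA", "p", 200, 1e-40, 1, 300))
  expect_false(flag_chimeric(parse_hit_table(f3))$chimera_flag)

  # regions shorter than min_region are not flagged
  f4 <- hits_file(c(
    dom_line("FA", "p", 200, 1e-40, 1, 30),
    dom_line("FB", "p", 250, 1e-50, 50, 80)
  ))
  expect_false(flag_chimeric(parse_hit_table(f4))$chimera_flag)
})

test_that("shrinking max_overlap_frac can only reduce flags", {
  lines <- c(
    dom_line("FA", "p1", 200, 1e-40, 1, 300),
    dom_line("FB", "p1", 250, 1e-50, 280, 600), # 21 aa overlap
    dom_line("FA", "p2", 100, 1e-20, 1, 200),
    dom_line("FB", "p2", 110, 1e-22, 400, 650)
  )
  h <- parse_hit_table(hits_file(lines))
  fracs <- c(0.5, 0.1, 0.02, 0)
  flags <- vapply(fracs, function(fr) {
    sum(flag_chimeric(h, max_overlap_frac = fr)$chimera_flag)
  }, integer(1))
  expect_true(all(diff(flags) <= 0L))
})

test_that("graft bundles are deterministic and record missing trees", {
  d <- withr::local_tempdir()
  seqs <- Biostrings::AAStringSet(c(a = "MKV", b = "MLL", c = "MAA"))
  writeLines("(x:1,y:1);", file.path(d, "F1.nwk"))
  asg <- tibble::tibble(
    protein_id = c("a", "b", "c"),
    best_family_id = c("F1", "F1", "F2"),
    best_bit_score = c(10, 20, 30), e_value = c(1e-5, 1e-6, 1e-7),
    chimera_flag = FALSE, chimera_detail = NA_character_
  )
  out1 <- file.path(d, "out1")
  res <- prepare_graft_bundle(asg, seqs, family_trees = d, out_dir = out1)
  expect_equal(res$status, c("prepared", "skipped_no_tree"))
  expect_equal(res$n_sequences, c(2L, 1L))
  m1 <- readLines(file.path(out1, "F1", "manifest.tsv"))

  out2 <- file.path(d, "out2")
  prepare_graft_bundle(asg, seqs, family_trees = d, out_dir = out2)
  m2 <- readLines(file.path(out2, "F1", "manifest.tsv"))
  expect_identical(m1, m2)

  # families with no new proteins get no bundle
  expect_false(dir.exists(file.path(out1, "F3")))
})
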