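test_that("nucleotide edits apply with correct length bookkeeping", {
  expect_identical(
    apply_edit("ATGTGGTAA", edit_event("substitution", 5, bases = "T")),
    "ATGTTGTAA")
  expect_identical(
    apply_edit("ATGAAATAA", edit_event("insertion", 3, bases = "C")),
    "ATGCAAATAA")
  expect_identical(
    apply_edit("ATGAAATAA", edit_event("deletion", 4, 6)),
    "ATGTAA")
  expect_error(apply_edit("ATGTAA", edit_event("substitution", 99, bases = "A")),
               "out of bounds")
  expect_error(apply_edit("ATGAAATAA",
                          edit_event("deletion", 4, 6, bases = "CCC")),
               "do not match reference")
  # length bookkeeping over random edits
  set.seed(11)
  for (k in 1:50) {
    n <- sample(30:90, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                        replace = TRUE), collapse = "")
    at <- sample(n, 1)
    expect_identical(nchar(apply_edit(s, edit_event("insertion", at, bases = ins))),
                     n + nchar(ins))
    to <- min(n, at + sample(0:4, 1))
    expect_identical(nchar(apply_edit(s, edit_event("deletion", at, to))),
                     n - (to - at + 1L))
  }
})

test_that("reading-frame selection starts at the first ATG", {
  orf <- select_reading_frame("CCATGTGGTAA")
  expect_identical(as.character(orf), "ATGTGGTAA")
  expect_true(attr(orf, "stop_reached"))
  orf2 <- select_reading_frame("ATGTAA")
  expect_identical(as.character(orf2), "ATGTAA")
  # ATG found across offsets, not only in frame 0
  orf3 <- select_reading_frame("CATGGAATAAGG")
  expect_identical(as.character(orf3), "ATGGAATAA")
  expect_error(select_reading_frame("CCCCCC"), "no start codon")
})

test_that("translation follows the standard genetic code", {
  p <- translate_cds("ATGTGGTAA")
  expect_identical(as.character(p), "MW")
  expect_true(attr(p, "stop_reached"))
  p2 <- translate_cds("ATGGAAGAA")
  expect_identical(as.character(p2), "MEE")
  expect_false(attr(p2, "stop_reached"))
  expect_error(translate_cds("ATGTNGTAA"), "position 5")
  # cross-check against the Biostrings translator on random CDS
  set.seed(5)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    sp <- synthetic_spec(seed = k, n_residues = 60, signal_len = 17)
    cds <- generate_transcript(sp)$transcript$cds
    mine <- as.character(translate_cds(cds))
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(paste0(mine, "*"), ref)
  }
})

test_that("truncation extent arithmetic matches the removed-residue counts", {
  expect_identical(truncation_extent(879, 857)$removed_count, 22L)
  expect_identical(truncation_extent(100, 100)$removed_count, 0L)
  ext <- truncation_extent(10, 3)
  expect_identical(ext$removed_count, 7L)
  expect_equal(ext$retained_fraction, 0.3)
  expect_error(truncation_extent(10, 12), "exceeds")
})

test_that("active-site retention flags follow the truncation point", {
  as_def <- active_site_definition()
  k616 <- mutation_record("k", "human", "nonsense", protein = "K616X")
  mut <- truncation_from_record(k616, wt_len = 879, as_def = as_def)
  expect_false(mut$active_site_retained[["657"]])
  expect_true(all(mut$active_site_retained[c("190", "191", "192", "390",
                                             "457", "554")]))
  expect_false(mut$active_site_complete)
  y126 <- mutation_record("y", "human", "nonsense", protein = "Y126X")
  mut2 <- truncation_from_record(y126, wt_len = 879, as_def = as_def)
  expect_true(all(!mut2$active_site_retained))
  # full-length wild type: nothing truncated, everything retained
  full <- manbatools:::new_mutant_protein_result(
    mutant_seq = strrep("A", 879), wt_len = 879L, is_truncated = FALSE,
    stop_after_residue = 879L, wt_seq = strrep("A", 879))
  full <- active_site_retained(full, as_def)
  expect_true(full$active_site_complete)
})

test_that("mutant translation reproduces wild type and handles truncations", {
  for (seed in 1:10) {
    sp <- synthetic_spec(seed = seed, n_residues = 80, signal_len = 17)
    tp <- generate_transcript(sp)
    # translate . select_reading_frame reproduces the stored WT protein
    orf <- select_reading_frame(tp$transcript$cds)
    expect_identical(as.character(translate_cds(as.character(orf))),
                     tp$protein)
  }
  sp <- synthetic_spec(seed = 2, n_residues = 80, signal_len = 17)
  tp <- generate_transcript(sp)
  as_def <- synthetic_active_site(sp)
  # nonsense at residue 30 stops after residue 29
  ref30 <- substr(tp$protein, 30, 30)
  rec <- mutation_record("n30", "human", "nonsense",
                         protein_ref = ref30, protein_pos = 30,
                         protein_alt = "X")
  mut <- translate_mutant(tp$transcript, rec, as_def = as_def)
  expect_true(mut$is_truncated)
  expect_identical(mut$stop_after_residue, 29L)
  expect_identical(mut$removed_count, 80L - 29L)
  expect_identical(mut$mutant_seq, substr(tp$protein, 1, 29))
  # missense keeps full length, differs at exactly one position
  alt <- setdiff(c("A", "G", "V"), ref30)[1]
  rec2 <- mutation_record("m30", "human", "missense", protein_ref = ref30,
                          protein_pos = 30, protein_alt = alt)
  mut2 <- translate_mutant(tp$transcript, rec2, as_def = as_def)
  expect_false(mut2$is_truncated)
  diffs <- which(strsplit(mut2$mutant_seq, "")[[1]] !=
                   strsplit(tp$protein, "")[[1]])
  expect_identical(diffs, 30L)
})

test_that("frameshifting insertions truncate and diverge after the edit", {
  set.seed(99)
  for (seed in 1:10) {
    sp <- synthetic_spec(seed = seed + 100, n_residues = 100, signal_len = 17)
    tp <- generate_transcript(sp)
    at <- sample(30:150, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    rec <- mutation_record(paste0("fs", seed), "human", "insertion",
                           nt_start = at, inserted_bases = ins)
    mut <- translate_mutant(tp$transcript, rec)
    expect_true(mut$is_truncated || mut$non_stop)
    # identical up to the codon before the insertion
    keep <- (at %/% 3)
    if (keep >= 1 && nchar(mut$mutant_seq) >= keep)
      expect_identical(substr(mut$mutant_seq, 1, keep),
                       substr(tp$protein, 1, keep))
  }
})

test_that("earlier stops remove strictly more residues", {
  removed <- vapply(c(100, 300, 500, 700), function(p) {
    rec <- mutation_record(paste0("s", p), "human", "nonsense",
                           protein_ref = "W", protein_pos = p,
                           protein_alt = "X")
    truncation_from_record(rec, wt_len = 879)$removed_count
  }, integer(1))
  expect_true(all(diff(removed) < 0))
})
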