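toy_rows <- c(human = "ARNDCEQGH-IKWLMFPSTWYV",
              cow   = "ARNDCKQGH-IKWLMFPSTWYV",
              goat  = "ARNDCKQGHPIKWLMFPSTWYV",
              mouse = "ARNECEQGH-IKWLMFPSTWYV")

test_that("Clustal and aligned-FASTA encodings parse to equal alignments", {
  fa <- system.file("extdata", "toy_alignment.fasta", package = "manbatools")
  cl <- system.file("extdata", "toy_alignment.aln", package = "manbatools")
  a1 <- read_alignment(fa)
  a2 <- read_alignment(cl)
  expect_identical(a1$rows, a2$rows)
  expect_identical(a1$ncol, nchar(toy_rows[["human"]]))
  expect_identical(sort(names(a1$rows)), sort(names(toy_rows)))
  # ragged rows are rejected
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MWKD", ">b", "MWK"), bad)
  expect_error(read_alignment(bad))
  # unknown characters are rejected with their location
  expect_error(profile_alignment(c(a = "MW1D", b = "MWKD")), "column 3")
  expect_error(profile_alignment(c(a = "MWD", b = "MWKD")), "ragged")
})

test_that("signal-peptide trimming uses per-species lengths", {
  prec <- strrep("A", 40)
  expect_identical(nchar(trim_signal_peptide(prec, "human")), 40L - 17L)
  expect_identical(nchar(trim_signal_peptide(prec, "cow")), 40L - 17L)
  expect_identical(nchar(trim_signal_peptide(prec, "mouse")), 40L - 19L)
  expect_error(trim_signal_peptide(strrep("A", 10), "human"), "signal")
})

test_that("position mapping agrees with a brute-force column scan", {
  aln <- profile_alignment(toy_rows)
  # identity on an ungapped pair of rows
  expect_identical(as.integer(map_position(aln, "human", 5, "cow")), 5L)
  # goat has an extra residue at column 10: downstream human positions shift
  expect_identical(as.integer(map_position(aln, "human", 10, "goat")), 11L)
  expect_identical(as.integer(map_position(aln, "goat", 11, "human")), 10L)
  # human is gapped where goat has P10
  expect_true(is.na(map_position(aln, "goat", 10, "human")))
  expect_error(map_position(aln, "human", 99, "goat"), "outside")
  expect_error(map_position(aln, "alpaca", 1, "goat"), "alpaca")
  # brute-force oracle over every defined position and species pair
  for (from in names(toy_rows)) {
    for (to in names(toy_rows)) {
      n <- ungapped_length(aln, from)
      for (p in seq_len(n)) {
        expect_identical(as.integer(map_position(aln, from, p, to)),
                         brute_force_map(aln, from, p, to),
                         info = sprintf("%s:%d->%s", from, p, to))
      }
    }
  }
})

test_that("position maps are injective, order-preserving and reversible", {
  aln <- profile_alignment(toy_rows)
  for (from in names(toy_rows)) {
    for (to in names(toy_rows)) {
      pm <- position_map(aln, from, to)
      def <- pm[!is.na(pm$target_pos), ]
      expect_false(anyDuplicated(def$target_pos) > 0)
      expect_true(all(diff(def$target_pos) > 0))
      # round trip is the identity wherever both directions are defined
      for (k in seq_len(nrow(def))) {
        back <- map_position(aln, to, def$target_pos[k], from)
        expect_identical(as.integer(back), def$source_pos[k])
      }
    }
  }
})

test_that("column conservation follows the ClustalX group tables", {
  aln <- profile_alignment(c(a = "WIACE", b = "WVCPK", c = "WLSTE", d = "WVAGE"))
  expect_identical(column_conservation(aln, 1), "identical")
  expect_identical(column_conservation(aln, 2), "conservative")      # MILV
  expect_identical(column_conservation(aln, 3), "semi_conservative") # CSA
  expect_identical(column_conservation(aln, 4), "non_conserved")
  # group-table lookup oracle over random columns
  grp <- conservation_groups()
  set.seed(21)
  for (k in 1:40) {
    col <- sample(manbatools:::AA_LETTERS, 4, replace = TRUE)
    a2 <- profile_alignment(stats::setNames(col, c("w", "x", "y", "z")))
    got <- column_conservation(a2, 1)
    uniq <- unique(col)
    expected <- if (length(uniq) == 1) "identical"
    else if (any(vapply(grp$strong, function(g)
      all(uniq %in% strsplit(g, "")[[1]]), logical(1)))) "conservative"
    else if (any(vapply(grp$weak, function(g)
      all(uniq %in% strsplit(g, "")[[1]]), logical(1)))) "semi_conservative"
    else "non_conserved"
    expect_identical(got, expected, info = paste(col, collapse = ""))
  }
  # a gapped column is never conserved
  g <- profile_alignment(c(a = "W-", b = "WW"))
  expect_identical(column_conservation(g, 2), "non_conserved")
})

test_that("mutation extrapolation maps across species with flags", {
  aln <- profile_alignment(toy_rows)
  # catalogue positions are precursor-numbered; rows are mature sequences
  # human precursor 29 = mature 12, the W in alignment column 13
  rec <- mutation_record("t1", "human", "nonsense", protein = "W29X")
  ex <- extrapolate_mutations(rec, aln, "goat")
  expect_identical(ex$target_pos, 29L + 1L)  # goat insertion before col 13
  expect_identical(ex$target_ref, "W")
  expect_identical(ex$conserved, "identical")
  # extrapolating to the source species returns the original position
  self <- extrapolate_mutations(rec, aln, "human")
  expect_identical(self$target_pos, 29L)
  # mouse numbering differs by the signal-length difference
  mo <- extrapolate_mutations(rec, aln, "mouse")
  expect_identical(mo$target_pos, 29L + 2L)
  # records inside the signal peptide are flagged
  sig <- mutation_record("t2", "human", "nonsense", protein = "W10X")
  exs <- extrapolate_mutations(sig, aln, "goat")
  expect_true(is.na(exs$target_pos))
  expect_match(exs$note, "signal")
  # a record mapping onto a target gap is flagged
  gp <- mutation_record("t3", "goat", "nonsense", protein = "W27X")
  exg <- extrapolate_mutations(gp, aln, "human")
  expect_true(is.na(exg$target_pos))
  expect_match(exg$note, "gap")
  # empty in, empty out
  expect_identical(nrow(extrapolate_mutations(manba_catalogue()[0, ], aln,
                                              "goat")), 0L)
})
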