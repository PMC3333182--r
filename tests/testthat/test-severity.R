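as_def <- active_site_definition()

trunc_mutant <- function(protein, wt_len = 879L) {
  rec <- mutation_record("tmp", "human", "nonsense", protein = protein)
  truncation_from_record(rec, wt_len = wt_len, as_def = as_def)
}

test_that("truncation severity follows active-site loss and domain rules", {
  # losing any active-site residue is severe
  rec <- mutation_record("a", "human", "nonsense", protein = "Y126X")
  call <- classify_truncation(rec, trunc_mutant("Y126X"))
  expect_identical(call$klass, "severe")
  expect_true("TRUNC_LOSES_ACTIVE_SITE" %in% call$rationale)
  # full active site but stopping before the last-domain boundary is severe
  rec2 <- mutation_record("b", "human", "nonsense", protein = "V720X")
  call2 <- classify_truncation(rec2, trunc_mutant("V720X"))
  expect_identical(call2$klass, "severe")
  expect_true("TRUNC_LAST_DOMAIN_LOSS" %in% call2$rationale)
  # a small C-terminal tail in a chitobiase species is moderate
  rec3 <- mutation_record("c", "human", "nonsense", protein = "W858X")
  call3 <- classify_truncation(rec3, trunc_mutant("W858X"))
  expect_identical(call3$klass, "moderate")
  expect_true("TRUNC_SMALL_TAIL" %in% call3$rationale)
  # the same small tail escalates to severe in a ruminant
  rec4 <- mutation_record("d", "cow", "nonsense", protein = "W858X",
                          zygosity = "homozygous")
  call4 <- classify_truncation(rec4, trunc_mutant("W858X"))
  expect_identical(call4$klass, "severe")
  expect_true("RUMINANT_NO_CHITOBIASE" %in% call4$rationale)
  # contract: non-truncating input is rejected
  ms <- mutation_record("e", "human", "missense", protein = "R182W")
  full <- manbatools:::new_mutant_protein_result(
    mutant_seq = strrep("A", 879), wt_len = 879L, is_truncated = FALSE,
    stop_after_residue = 879L)
  expect_error(classify_truncation(ms, full), "truncated")
})

test_that("zygosity attenuation rescues or steps down one level", {
  # heterozygote with a functional partner allele: rescued to mild
  het <- mutation_record("h", "human", "nonsense", protein = "K616X",
                         zygosity = "heterozygous")
  call <- classify_truncation(het, trunc_mutant("K616X"))
  expect_identical(call$klass, "mild")
  expect_true("HET_ATTENUATED" %in% call$rationale)
  # compound het with a second severe pathogenic allele: one level down
  ch <- mutation_record("i", "human", "nonsense", protein = "E83X",
                        zygosity = "compound_heterozygous")
  call2 <- classify_truncation(ch, trunc_mutant("E83X"),
                               partner_klass = "severe")
  expect_identical(call2$klass, "moderate")
  # attenuation with a pathogenic partner is exactly one level, floor mild
  for (base in c("mild", "moderate", "severe")) {
    rec <- mutation_record("j", "human", "missense", protein = "R182W",
                           zygosity = "compound_heterozygous")
    got <- classify_substitution(
      rec,
      close_to_as = base != "mild",
      direct_interaction = base == "severe",
      partner_klass = base)$klass
    want <- c(mild = "mild", moderate = "mild", severe = "moderate")[[base]]
    expect_identical(got, want, info = base)
  }
})

test_that("substitution severity reproduces the published rule table", {
  cat15 <- manba_catalogue()
  ev <- manba_substitution_evidence()
  expected <- c(Hs_R182W = "mild", Hs_G392E = "moderate",
                Hs_S505P = "severe", Hs_R641H = "moderate")
  for (id in names(expected)) {
    rec <- cat15[cat15$id == id, ]
    call <- do.call(classify_substitution, c(list(record = rec), ev[[id]]))
    expect_identical(call$klass, expected[[id]], info = id)
  }
  # rationale codes name the driving evidence
  s505 <- do.call(classify_substitution,
                  c(list(record = cat15[cat15$id == "Hs_S505P", ]),
                    ev$Hs_S505P))
  expect_true("SUBST_DIRECT_AS_INTERACTION" %in% s505$rationale)
  r641 <- do.call(classify_substitution,
                  c(list(record = cat15[cat15$id == "Hs_R641H", ]),
                    ev$Hs_R641H))
  expect_true("SUBST_FOLD_DESTABILIZING" %in% r641$rationale)
  # contract: truncating input is rejected
  tr <- cat15[cat15$id == "Hs_Y126X", ]
  expect_error(classify_substitution(tr), "substitution")
})

test_that("substitution severity is monotone in active-site distance", {
  rec <- mutation_record("m", "human", "missense", protein = "G392E")
  distances <- c(30, 12, 8, 6, 4.5, 2, 0.5)
  ranks <- vapply(distances, function(d)
    match(classify_substitution(rec, distance_A = d)$klass,
          c("mild", "moderate", "severe")), integer(1))
  expect_true(all(diff(ranks) >= 0))
  # boundary behaviour matches the thresholds
  expect_identical(classify_substitution(rec, distance_A = 8)$klass, "moderate")
  expect_identical(classify_substitution(rec, distance_A = 4.5)$klass, "severe")
})

test_that("every combination of evidence flags maps to exactly one class", {
  rec_hom <- mutation_record("e1", "human", "missense", protein = "R182W",
                             zygosity = "homozygous")
  flags <- expand.grid(direct = c(TRUE, FALSE), close = c(TRUE, FALSE),
                       destab = c(TRUE, FALSE))
  for (r in seq_len(nrow(flags))) {
    call <- classify_substitution(rec_hom,
                                  close_to_as = flags$close[r],
                                  direct_interaction = flags$direct[r],
                                  fold_destabilizing = flags$destab[r])
    expect_true(call$klass %in% c("mild", "moderate", "severe"))
    expect_gt(length(call$rationale), 0)
  }
  # heterozygous never exceeds homozygous for identical evidence
  for (r in seq_len(nrow(flags))) {
    rec_het <- mutation_record("e2", "human", "missense", protein = "R182W",
                               zygosity = "heterozygous")
    hom <- classify_substitution(rec_hom, close_to_as = flags$close[r],
                                 direct_interaction = flags$direct[r],
                                 fold_destabilizing = flags$destab[r])$klass
    het <- classify_substitution(rec_het, close_to_as = flags$close[r],
                                 direct_interaction = flags$direct[r],
                                 fold_destabilizing = flags$destab[r])$klass
    expect_lte(match(het, c("mild", "moderate", "severe")),
               match(hom, c("mild", "moderate", "severe")))
  }
})

test_that("classify_all is deterministic and handles degenerate input", {
  fx <- study_fixtures()
  a <- classify_all(fx$catalogue, evidence = fx$substitution_evidence,
                    partners = fx$partner_pairs)
  b <- classify_all(fx$catalogue, evidence = fx$substitution_evidence,
                    partners = fx$partner_pairs)
  expect_identical(a, b)
  expect_identical(nrow(a), 15L)
  # empty catalogue gives an empty table
  expect_identical(nrow(classify_all(fx$catalogue[0, ])), 0L)
  # a substitution without structural evidence falls back with a warning
  ms <- manba_catalogue()[manba_catalogue()$id == "Hs_R182W", ]
  expect_warning(out <- classify_all(ms), "sequence-only")
  expect_identical(nrow(out), 1L)
})

test_that("the severity configuration round-trips through YAML", {
  cfg <- severity_config(proximity_A = 9, last_domain_boundary = 700)
  path <- tempfile(fileext = ".yaml")
  write_severity_config(cfg, path)
  back <- read_severity_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(severity_config(proximity_A = -1), "positive")
  # the packaged default config parses
  pkg_cfg <- read_severity_config(system.file("extdata",
                                              "severity_config.yaml",
                                              package = "manbatools"))
  expect_equal(unclass(pkg_cfg), unclass(severity_config()))
})
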