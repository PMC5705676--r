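test_that("shared-peptide detection is exact set intersection across species", {
  a <- digestProteome(Proteome("A", c(p1 = "AAAAAAAK", p2 = "SSSSSSSK")))
  b <- digestProteome(Proteome("B", c(q1 = "SSSSSSSK", q2 = "TTTTTTTK")))
  sh <- findShared(list(a, b))
  expect_identical(peptides(sh), "SSSSSSSK")
  expect_identical(sh@membership$species, c("A", "B"))

  # identical proteomes under two labels share everything
  same <- Proteome("A", c(p = "AAAAAAAKSSSSSSSK"))
  same2 <- Proteome("B", proteinSequences(same))
  shAll <- findShared(list(digestProteome(same), digestProteome(same2)))
  expect_setequal(peptides(shAll), c("AAAAAAAK", "SSSSSSSK"))

  expect_error(findShared(list(a)), "at least 2")
  mismatched <- digestProteome(Proteome("C", c(r = "AAAAAAAK")),
                               DigestParams(minLen = 8))
  expect_error(findShared(list(a, mismatched)), "identical DigestParams")
  expect_error(findShared(list(a, digestProteome(Proteome("A", c(x = "CCCCCCCK"))))),
               "distinct")
})

test_that("I/L equivalence collapses isobaric peptides on request", {
  a <- digestProteome(Proteome("A", c(p = "IIIIIIIK")))
  b <- digestProteome(Proteome("B", c(q = "LLLLLLLK")))
  expect_length(peptides(findShared(list(a, b))), 0L)
  shIL <- findShared(list(a, b), ilEquivalent = TRUE)
  expect_identical(peptides(shIL), "LLLLLLLK")
})

test_that("overlap matrix counts are symmetric, percentages row-normalised", {
  a <- digestProteome(Proteome("A", c(p1 = "AAAAAAAK", p2 = "SSSSSSSK")))
  b <- digestProteome(Proteome("B", c(q1 = "SSSSSSSK", q2 = "TTTTTTTK")))
  om <- overlapMatrix(list(a, b))
  expect_identical(overlapCounts(om)["A", "B"], 1L)
  expect_identical(diag(overlapCounts(om)), c(A = 2L, B = 2L))
  expect_equal(overlapPercentages(om)["A", "B"], 50)
  expect_equal(overlapPercentages(om)["B", "A"], 50)

  # disjoint proteomes give a zero off-diagonal
  c2 <- digestProteome(Proteome("C", c(r = "VVVVVVVK")))
  om2 <- overlapMatrix(list(a, c2))
  expect_identical(overlapCounts(om2)["A", "C"], 0L)

  # asymmetric percentages from a symmetric count
  big <- Proteome("D", setNames(
    vapply(1:40, function(i) {
      set.seed(i + 500)
      randomSequence(120)
    }, ""), paste0("d", 1:40)))
  om3 <- overlapMatrix(list(digestProteome(big), a))
  expect_identical(overlapCounts(om3)["D", "A"], overlapCounts(om3)["A", "D"])
})

test_that("single-protein trimming excises shared fragments by coordinate", {
  tr <- trimProtein("AAAAAAAKSSSSSSSKCCCCCCCK", c("SSSSSSSK"))
  expect_identical(tr$sequence, "AAAAAAAKCCCCCCCK")
  expect_identical(tr$spans$start, 8L)
  expect_identical(tr$spans$end, 16L)

  # untouched protein comes back identical with empty spans
  tr0 <- trimProtein("AAAAAAAKCCCCCCCK", c("SSSSSSSK"))
  expect_identical(tr0$sequence, "AAAAAAAKCCCCCCCK")
  expect_identical(nrow(tr0$spans), 0L)

  # a protein that IS one shared peptide trims to the empty string
  trE <- trimProtein("SSSSSSSK", c("SSSSSSSK"))
  expect_identical(trE$sequence, "")

  # coordinate semantics: a shared string inside a longer peptide is kept
  trIn <- trimProtein("AASSSSSSSKK", c("SSSSSSSK"),
                      DigestParams("trypsin_p"))
  expect_identical(trIn$sequence, "AASSSSSSSKK")
})

test_that("community trimming removes shared peptides from all species", {
  tr <- trimProteomes(toyProteomes())
  expect_identical(proteinSequences(trimmedProteomes(tr)$A),
                   c(p = "AAAAAAAKCCCCCCCK"))
  expect_identical(proteinSequences(trimmedProteomes(tr)$B),
                   c(q = "TTTTTTTK"))
  expect_identical(peptides(sharedPeptides(tr)), "SSSSSSSK")
  expect_length(peptides(residualShared(tr)), 0L)

  rec <- trimRecords(tr)
  expect_identical(rec$n_peptides_removed, c(1L, 1L))
  expect_identical(rec$n_residues_removed, c(8L, 8L))
  expect_identical(rec$trimmed_length, rec$original_length - 8L)

  expect_error(trimProteomes(toyProteomes()[1]), "at least 2")
})

test_that("proteins trimmed to nothing are dropped from FASTA but reported", {
  a <- Proteome("A", c(gone = "SSSSSSSK", stays = "AAAAAAAK"))
  b <- Proteome("B", c(q = "SSSSSSSK"))
  w <- capture_warnings(tr <- trimProteomes(list(a, b)))
  expect_match(w, "zero length", all = FALSE)
  expect_identical(proteinIds(trimmedProteomes(tr)$A), "stays")
  rec <- trimRecords(tr)
  expect_true(rec$became_empty[rec$protein_id == "gone"])
  expect_identical(rec$trimmed_length[rec$protein_id == "gone"], 0L)
  expect_identical(nProteins(trimmedProteomes(tr)$B), 0L)
})

test_that("missed-cleavage junction peptides defeat single-pass but not fixpoint", {
  # After "SSSSSSSK" is excised, "AAAK"+"CCCK" concatenates into a new
  # 1-missed-cleavage peptide that species B already contains.
  a <- Proteome("A", c(pa = "AAAKSSSSSSSKCCCK"))
  b <- Proteome("B", c(qb1 = "AAAKCCCK", qb2 = "SSSSSSSKDDDK"))
  params <- DigestParams("trypsin_strict", missedCleavages = 1)

  expect_warning(single <- trimProteomes(list(a, b), params), "remain after")
  expect_identical(peptides(residualShared(single)), "AAAKCCCK")
  # oracle: re-run shared detection on the single-pass output
  reIdx <- lapply(trimmedProteomes(single), digestProteome, params = params)
  expect_identical(peptides(findShared(reIdx)), "AAAKCCCK")

  fix <- suppressWarnings(trimProteomes(list(a, b), params, mode = "fixpoint"))
  expect_length(peptides(residualShared(fix)), 0L)
  expect_gt(fix@nRounds, 1L)
  # length reconciliation still exact across rounds
  rec <- trimRecords(fix)
  expect_identical(rec$trimmed_length, rec$original_length - rec$n_residues_removed)
})

test_that("removed spans exactly reconstruct the trimmed sequences", {
  set.seed(77)
  sim <- simulateProteomes(3, nProteins = 8, lengthRange = c(80, 200),
                           plantedShared = list(
                             list(length = 9, species = c(1, 2)),
                             list(length = 12, species = c(1, 2, 3))),
                           seed = 101)
  tr <- suppressWarnings(trimProteomes(sim$proteomes, mode = "fixpoint"))
  spans <- removedSpans(tr)
  for (sp in names(trimmedProteomes(tr))) {
    orig <- proteinSequences(sim$proteomes[[sp]])
    trimmed <- proteinSequences(trimmedProteomes(tr)[[sp]])
    for (pid in names(orig)) {
      s <- spans[spans$species == sp & spans$protein_id == pid, , drop = FALSE]
      chars <- strsplit(orig[[pid]], "")[[1]]
      if (nrow(s)) {
        drop <- unlist(mapply(function(a, b) (a + 1L):b, s$start, s$end,
                              SIMPLIFY = FALSE))
        expect_identical(anyDuplicated(drop), 0L)   # non-overlapping spans
        chars <- chars[-drop]
      }
      rebuilt <- paste(chars, collapse = "")
      got <- if (pid %in% names(trimmed)) trimmed[[pid]] else ""
      expect_identical(got, rebuilt)
      expect_true(nchar(got) <= nchar(orig[[pid]]))  # never grows
    }
  }
})

test_that("trimming on a fixpoint output is the identity", {
  sim <- simulateProteomes(2, nProteins = 6, lengthRange = c(80, 160),
                           plantedShared = list(list(length = 10, species = 1:2)),
                           seed = 202)
  fix <- suppressWarnings(trimProteomes(sim$proteomes, mode = "fixpoint"))
  again <- suppressWarnings(trimProteomes(trimmedProteomes(fix), mode = "fixpoint"))
  expect_identical(lapply(trimmedProteomes(again), proteinSequences),
                   lapply(trimmedProteomes(fix), proteinSequences))
  expect_identical(sum(trimRecords(again)$n_peptides_removed), 0L)
})

test_that("species-unique peptides survive trimming verbatim", {
  sim <- simulateProteomes(3, nProteins = 6, lengthRange = c(80, 160),
                           plantedShared = list(list(length = 9, species = 1:2)),
                           seed = 303)
  idx <- lapply(sim$proteomes, digestProteome)
  shared <- peptides(findShared(idx))
  fix <- suppressWarnings(trimProteomes(sim$proteomes, mode = "fixpoint"))
  trIdx <- lapply(trimmedProteomes(fix), digestProteome)
  for (sp in names(idx)) {
    others <- unlist(lapply(idx[setdiff(names(idx), sp)], peptides))
    uniq <- setdiff(peptides(idx[[sp]]), c(others, shared))
    expect_true(all(uniq %in% peptides(trIdx[[sp]])))
  }
})

test_that("trim summary reports per-protein removals and species totals", {
  tr <- trimProteomes(toyProteomes())
  sm <- trimSummary(tr)
  expect_identical(nrow(sm), 2L)
  expect_identical(sm$n_residues_removed, c(8L, 8L))
  expect_equal(sm$fraction_removed, c(8 / 24, 8 / 16))
  tot <- attr(sm, "speciesTotals")
  expect_identical(tot$n_peptides_removed, c(1L, 1L))

  # untouched rows suppressed unless asked for
  a <- Proteome("A", c(p = "AAAAAAAK", u = "VVVVVVVK"))
  b <- Proteome("B", c(q = "AAAAAAAK"))
  tr2 <- suppressWarnings(trimProteomes(list(a, b)))
  expect_false("u" %in% trimSummary(tr2)$protein_id)
  expect_true("u" %in% trimSummary(tr2, all = TRUE)$protein_id)
})
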