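test_that("one-sided Fisher equals the enumeration oracle on known tables", {
  expect_equal(fisherOneSided(0, 2, 2, 0), 1)          # full tail
  expect_equal(fisherOneSided(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisherOneSided(5, 5, 10, 80),
               bruteFisherUpper(5, 5, 10, 80), tolerance = 1e-12)
  # and against R's own conditional exact test, as a second opinion
  ft <- fisher.test(matrix(c(5, 5, 10, 80), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(fisherOneSided(5, 5, 10, 80), ft$p.value, tolerance = 1e-12)
  expect_error(fisherOneSided(0, 0, 0, 0), "all-zero")
  expect_error(fisherOneSided(-1, 2, 3, 4), "non-negative")
})

test_that("one-sided Fisher matches enumeration on random tables", {
  set.seed(21)
  for (i in 1:200) {
    N <- sample(4:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    a <- sample(max(0, n + K - N):min(K, n), 1)
    tb <- c(a, n - a, K - a, N - K - n + a)
    expect_equal(fisherOneSided(tb[1], tb[2], tb[3], tb[4]),
                 bruteFisherUpper(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand step-up and stays monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-15)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))   # monotone in the sorted order
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment builds the 2x2 tables against the annotated universe", {
  ann <- data.frame(
    protein_id = c(paste0("p", 1:10), paste0("p", 1:4)),
    pathway_id = c(rep("PW1", 10), rep("PW2", 4)),
    pathway_name = c(rep("big", 10), rep("small", 4)))
  # p1..p10 annotated; p11 changed but unannotated
  res <- enrichPathways(increased = c("p1", "p2", "p3", "p11"),
                        decreased = character(), annotation = ann)
  expect_identical(res@universeSize, 10L)
  expect_identical(unname(res@nUnannotated["increased"]), 1L)
  tb <- resultTable(res)
  up <- tb[tb$direction == "increased", ]
  pw2 <- up[up$pathway_id == "PW2", ]
  expect_identical(pw2$a + pw2$b, 3L)            # |SCA in universe|
  expect_identical(pw2$a + pw2$c, 4L)            # pathway size
  expect_equal(pw2$p_raw, bruteFisherUpper(pw2$a, pw2$b, pw2$c, pw2$g))
  expect_equal(pw2$pathway_fraction_of_proteome, 0.4)
  expect_equal(pw2$sca_fraction_of_sca, 1)       # all 3 changed are in PW2
  expect_true(all(tb$p_adj >= tb$p_raw - 1e-15))

  # a pathway with zero changed members is never enriched
  down <- enrichPathways(character(), c("p9", "p10"), ann)
  pw2d <- resultTable(down)
  pw2d <- pw2d[pw2d$pathway_id == "PW2" & pw2d$direction == "decreased", ]
  expect_identical(pw2d$a, 0L)
  expect_equal(pw2d$p_raw, 1)
})

test_that("uniformly spread changed proteins are almost never called enriched", {
  # null behaviour: with no planted pathway, a BH-adjusted call below
  # 0.05 should be rare across seeded repetitions
  uni <- sprintf("u%03d", 1:200)
  hits <- 0L
  for (r in 1:20) {
    sim <- simulateAnnotation(uni, nPathways = 10, sizeRange = c(20, 40),
                              seed = 600 + r)
    set.seed(700 + r)
    sca <- sample(uni, 40)           # uniform sample: no signal
    tb <- resultTable(enrichPathways(sca, character(), sim$annotation))
    if (min(tb$p_adj[tb$direction == "increased"]) < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 1L)               # none enriched in >= 95% of repetitions
})

test_that("a planted enriched pathway ranks first by adjusted p", {
  uni <- sprintf("u%03d", 1:300)
  set.seed(25)
  sca <- sample(uni, 30)
  sim <- simulateAnnotation(uni, nPathways = 15, sizeRange = c(15, 30),
                            sca = sca, plantedExcess = 0.7, seed = 26)
  res <- enrichPathways(sca, character(), sim$annotation)
  tb <- resultTable(res)
  up <- tb[tb$direction == "increased", ]
  expect_identical(up$pathway_id[1], sim$groundTruth$plantedPathway)
  expect_lt(up$p_adj[1], 0.05)
})

test_that("enrichment is invariant to protein relabeling and pathway order", {
  uni <- sprintf("u%03d", 1:120)
  set.seed(27)
  sim <- simulateAnnotation(uni, nPathways = 8, sizeRange = c(10, 25), seed = 28)
  sca <- sample(uni, 25)
  base <- resultTable(enrichPathways(sca, character(), sim$annotation))

  # permute annotation row order
  shuf <- sim$annotation[sample(nrow(sim$annotation)), ]
  reord <- resultTable(enrichPathways(sca, character(), shuf))
  expect_equal(base, reord)

  # bijective renaming of proteins leaves every p-value unchanged
  map <- setNames(sprintf("v%03d", seq_along(uni)), uni)
  ann2 <- sim$annotation
  ann2$protein_id <- unname(map[ann2$protein_id])
  ren <- resultTable(enrichPathways(unname(map[sca]), character(), ann2))
  expect_equal(base$p_raw, ren$p_raw)
  expect_equal(base$p_adj, ren$p_adj)
})

test_that("the detected-proteins universe restricts the background", {
  ann <- data.frame(protein_id = paste0("p", 1:20),
                    pathway_id = rep(c("PW1", "PW2"), each = 10))
  res <- enrichPathways(c("p1", "p2"), character(), ann,
                        universe = "detected", detected = paste0("p", 1:12))
  expect_identical(res@universeSize, 12L)
  expect_error(enrichPathways("p1", character(), ann, universe = "detected"),
               "detected")
  expect_error(enrichPathways("p1", character(),
                              ann[0, ]), "empty annotation universe")
})
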