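test_that("element pair score is the weighted minimum length", {
  expect_equal(elementScore("H", 4, "H", 6), 4)
  expect_equal(elementScore("H", 4, "E", 9), 0)
  expect_equal(elementScore("C", 3, "C", 3), 3)
  expect_equal(elementScore("H", 4, "H", 6), elementScore("H", 6, "H", 4))
  sch <- scoringScheme(c("C:H" = 0.5))
  expect_equal(elementScore("C", 4, "H", 6, sch), 2)
})

test_that("scoring scheme validates weights and reads config files", {
  expect_equal(scoringScheme()@weights["H", "H"], 1)
  expect_equal(scoringScheme()@weights["H", "E"], 0)
  expect_error(scoringScheme(c("H:E" = 1.5)), "0, 1")
  expect_error(scoringScheme(c("H:X" = 0.5)), "pair")
  f <- withr::local_tempfile(lines = c("# partial coil credit",
                                       "C:H = 0.25", "C:E = 0.25",
                                       "gap_cost = 0.5"))
  sch <- readSchemeConfig(f)
  expect_equal(sch@weights["C", "H"], 0.25)
  expect_equal(sch@weights["E", "C"], 0.25)
  expect_equal(sch@gapCost, 0.5)
})

test_that("alignment reproduces the worked examples", {
  a <- compressSSE("HHHHCCCCCEEEEEHHHH")
  self <- sseaAlign(a, a)
  expect_equal(alignmentScore(self), 18)
  expect_equal(sseaScore(self), 1)
  expect_equal(alignedPairs(self)[, "a"], 1:4)

  allH <- compressSSE(strrep("H", 12L))
  allE <- compressSSE(strrep("E", 20L))
  expect_equal(alignmentScore(sseaAlign(allH, allE)), 0)
  expect_equal(sseaScore(sseaAlign(allH, allE)), 0)

  b <- ElementSequence("b", c("H", "E"), c(2L, 7L))
  r <- sseaAlign(a, b)
  expect_equal(alignmentScore(r), 7)          # H~H gives 2, E~E gives 5
  expect_equal(sseaScore(r), 7 / 13.5)
  expect_equal(unname(alignedPairs(r)), matrix(c(1L, 3L, 1L, 2L), ncol = 2L))
})

test_that("DP score equals exhaustive enumeration over monotone matchings", {
  set.seed(42)
  schemes <- list(scoringScheme(),
                  scoringScheme(c("C:H" = 0.3, "C:E" = 0.4, "H:E" = 0.1)),
                  scoringScheme(gapCost = 0.75))
  for (k in 1:500) {
    a <- randomElementSequence(sample.int(8L, 1L), id = "a")
    b <- randomElementSequence(sample.int(8L, 1L), id = "b")
    sch <- schemes[[1L + k %% length(schemes)]]
    expect_equal(alignmentScore(sseaAlign(a, b, sch)),
                 bruteForceAlignScore(a, b, sch))
  }
})

test_that("score bounds, identity and symmetry hold on random pairs", {
  set.seed(7)
  for (k in 1:300) {
    a <- randomSSEString(sample(5:120, 1L), "a")
    b <- randomSSEString(sample(5:120, 1L), "b")
    r <- sseaAlign(a, b)
    expect_lte(alignmentScore(r),
               min(residueLength(a), residueLength(b)) + 1e-12)
    expect_gte(sseaScore(r), 0)
    expect_lte(sseaScore(r), 1)
    expect_equal(sseaScore(r), sseaScore(sseaAlign(b, a)))
    expect_equal(sseaScore(sseaAlign(a, a)), 1)
  }
})

test_that("matched element pairs are strictly increasing in both sequences", {
  set.seed(11)
  for (k in 1:50) {
    a <- randomElementSequence(sample.int(10L, 1L), id = "a")
    b <- randomElementSequence(sample.int(10L, 1L), id = "b")
    p <- alignedPairs(sseaAlign(a, b))
    if (nrow(p) > 1L) {
      expect_true(all(diff(p[, 1L]) > 0))
      expect_true(all(diff(p[, 2L]) > 0))
    }
  }
})

test_that("padding one sequence with a type absent from the other never raises the score", {
  set.seed(13)
  for (k in 1:50) {
    a <- randomSSEString(sample(10:60, 1L), "a")
    b <- SSEString("b", paste0(strrep("H", 8L), strrep("C", 5L),
                               strrep("H", 8L)))
    ## append a strand element to b only: the partner has no strand to
    ## pair it with under the default scheme, so only the denominator grows
    bPad <- SSEString("b", paste0(sseStates(b), strrep("E", 10L)))
    aNoE <- SSEString("a", gsub("E", "C", sseStates(a)))
    expect_lte(sseaScore(sseaAlign(aNoE, bPad)),
               sseaScore(sseaAlign(aNoE, b)) + 1e-12)
  }
})

test_that("nonzero gap cost penalizes skipped elements", {
  a <- ElementSequence("a", c("E", "C", "E"), c(5L, 3L, 5L))
  b <- ElementSequence("b", "E", 5L)
  free <- sseaAlign(a, b)
  expect_equal(alignmentScore(free), 5)
  paid <- sseaAlign(a, b, scoringScheme(gapCost = 2))
  ## best matching pairs one strand, leaving two of a's elements
  ## unmatched at cost 2 each
  expect_equal(alignmentScore(paid), 5 - 4)
})
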