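test_that("confusion metrics reproduce the defining formulas", {
  perfect <- evalMetrics(confusionCounts(tp = 10, fp = 0, fn = 0, tn = 90))
  expect_equal(perfect, list(ac = 1, sn = 1, sp = 1, mcc = 1))

  chance <- evalMetrics(confusionCounts(tp = 25, fp = 25, fn = 25, tn = 25))
  expect_equal(chance$ac, 0.5)
  expect_equal(chance$mcc, 0)

  m <- evalMetrics(confusionCounts(tp = 275, fp = 18, fn = 102, tn = 924))
  expect_equal(round(m$sn, 3), 0.729)
  expect_equal(round(m$sp, 3), 0.981)
  expect_equal(round(m$ac, 3), 0.909)
  expect_equal(round(m$mcc, 3), 0.772)

  expect_error(evalMetrics(confusionCounts(0, 0, 0, 0)), "zero")
  expect_error(evalMetrics(confusionCounts(tp = 0, fp = 3, fn = 0, tn = 5)),
               "positives")
})

test_that("accuracy is the class-size weighted mix of Sn and Sp; degenerate MCC is 0", {
  set.seed(5)
  for (k in 1:50) {
    c <- confusionCounts(tp = sample(0:50, 1L), fp = sample(0:50, 1L),
                         fn = sample(0:50, 1L), tn = sample(0:50, 1L))
    nPos <- c$tp + c$fn; nNeg <- c$fp + c$tn
    if (nPos == 0 || nNeg == 0) next
    m <- evalMetrics(c)
    expect_equal(m$ac, (nPos * m$sn + nNeg * m$sp) / (nPos + nNeg))
  }
  ## proportional rows: classifier ignores the label, MCC exactly 0
  expect_equal(evalMetrics(confusionCounts(tp = 20, fp = 10, fn = 40,
                                           tn = 20))$mcc, 0)
})

test_that("ROC matches the rank-sum oracle and handles the toy cases", {
  sep <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)

  toy <- rocCurve(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(toy$auc, 0.75)

  expect_error(rocCurve(c(0.1, 0.2), c(TRUE, TRUE)), "negative")

  ## AUC == Mann-Whitney U / (n+ * n-), ties counted half
  set.seed(31)
  for (k in 1:50) {
    n <- sample(5:30, 1L)
    scores <- round(runif(n), 2)      # rounding forces some ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    u <- 0
    for (s1 in scores[labels])
      for (s0 in scores[!labels])
        u <- u + (s1 > s0) + 0.5 * (s1 == s0)
    expect_equal(rocCurve(scores, labels)$auc,
                 u / (sum(labels) * sum(!labels)))
  }

  ## chance limit for labels independent of scores
  set.seed(99)
  scores <- runif(4000)
  labels <- runif(4000) < 0.5
  expect_lt(abs(rocCurve(scores, labels)$auc - 0.5), 0.05)

  ## curve points are monotone in both coordinates
  pts <- rocCurve(scores, labels)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("global identity follows the Needleman-Wunsch convention", {
  expect_equal(globalIdentity("MKVLAT", "MKVLAT"), 1)
  expect_equal(globalIdentity("AAAA", "TTTT"), 0)
  expect_equal(globalIdentity("ACDEFG", "ACDEYG"), 5 / 6)
  expect_error(globalIdentity("", "ACD"), "empty")
})

test_that("homology filtering applies strict cutoffs and is idempotent", {
  set.seed(61)
  base <- randomAASequence(120L)
  seqs <- c(mutateSequence(base, 0.10), mutateSequence(base, 0.24),
            mutateSequence(base, 0.25), mutateSequence(base, 0.40))
  ## verify the constructed identities straddle the cutoff as intended
  ## (the most heavily mutated copy may measure above its target because
  ## the global alignment recruits gap-induced identities)
  ident <- vapply(seqs, function(s) globalIdentity(base, s), numeric(1L),
                  USE.NAMES = FALSE)
  expect_equal(ident[2:4], c(0.24, 0.25, 0.40), tolerance = 0.01)
  expect_lt(ident[1L], 0.25)
  lib <- referenceLibrary(
    list(SSEString("a", strrep("E", 10L)), SSEString("b", strrep("E", 11L)),
         SSEString("c", strrep("H", 10L)), SSEString("d", strrep("H", 11L))),
    c("OMP", "OMP", "non-OMP", "non-OMP"), sequences = seqs)
  test <- list(id = "t", sequence = base)

  kept <- filterLibrary(lib, test, filterPolicy(identityMax = 0.25))
  expect_equal(libIDs(kept), c("a", "b"))    # strict "<" keeps 0.10, 0.24
  ## idempotence
  again <- filterLibrary(kept, test, filterPolicy(identityMax = 0.25))
  expect_identical(libIDs(again), libIDs(kept))

  ## the test protein itself (identity 1) is always removed
  libSelf <- referenceLibrary(c(libElements(lib),
                                list(compressSSE(SSEString("t", strrep("E", 9L))))),
                              c(libLabels(lib), "OMP"),
                              sequences = c(seqs, base))
  keptSelf <- filterLibrary(libSelf, test, filterPolicy(identityMax = 0.25))
  expect_false("t" %in% libIDs(keptSelf))

  ## no enabled stages: library returned unchanged
  noop <- filterLibrary(lib, test, filterPolicy(stages = character(0)))
  expect_identical(libIDs(noop), libIDs(lib))

  ## identity stage without sequences is a configuration error
  bare <- referenceLibrary(libElements(lib), libLabels(lib))
  expect_error(filterLibrary(bare, test, filterPolicy()), "amino-acid")
})

test_that("e-value stages use strict '>' retention and fail open on hook errors", {
  lib <- toySeparableLibrary()
  tab <- data.frame(query = "t", subject = c("omp1", "omp2", "dec1"),
                    evalue = c(1e-5, 0.01, 0.5))
  hook <- evalueHookFromTable(tab)
  pol <- filterPolicy(stages = "search_evalue")
  kept <- filterLibrary(lib, list(id = "t", sequence = NA), pol,
                        evalueHook = hook)
  ## e-value 0.01 is not > 0.01, so omp2 is removed too; no hit passes
  expect_equal(libIDs(kept), c("dec1", "dec2"))

  broken <- function(test, entry) stop("boom")
  w <- capture_warnings(
    keptB <- filterLibrary(lib, list(id = "t", sequence = NA), pol,
                           evalueHook = broken))
  expect_true(length(w) == length(lib) && all(grepl("retained", w)))
  expect_equal(length(keptB), length(lib))

  ## missing hook skips the stage with a message
  expect_message(
    keptM <- filterLibrary(lib, list(id = "t", sequence = NA), pol),
    "skipped")
  expect_equal(length(keptM), length(lib))
})

test_that("outfmt-6 style tables adapt to the hook contract", {
  f <- withr::local_tempfile(lines = paste(
    c("t\tomp1\t98.2\t100\t2\t0\t1\t100\t1\t100\t1e-30\t180",
      "omp2\tt\t40.0\t90\t50\t3\t1\t90\t5\t95\t0.2\t35"),
    collapse = "\n"))
  hook <- evalueHookFromTable(f)
  expect_equal(hook(list(id = "t"), list(id = "omp1")), 1e-30)
  ## symmetric lookup: the table row records omp2 as query
  expect_equal(hook(list(id = "t"), list(id = "omp2")), 0.2)
  expect_true(is.na(hook(list(id = "t"), list(id = "dec1"))))
})

test_that("leave-one-out on a separable toy is perfect and flags filtering losses", {
  lib <- toySeparableLibrary()
  ev <- looEvaluate(lib)
  expect_equal(ev$counts$tp, 2L)
  expect_equal(ev$counts$tn, 2L)
  expect_equal(ev$metrics$mcc, 1)
  expect_equal(ev$roc$auc, 1)
  expect_false(any(ev$report$unpredictable))

  ## an all-pass identity policy gives results identical to no policy
  set.seed(71)
  seqs <- vapply(1:4, function(i) randomAASequence(100L), "")
  libSeq <- toySeparableLibrary(sequences = seqs)
  evNone <- looEvaluate(libSeq, policy = filterPolicy(stages = character(0)))
  evAllPass <- looEvaluate(libSeq, policy = filterPolicy(identityMax = 1))
  expect_equal(evNone$counts, evAllPass$counts)
  expect_equal(evNone$report$pred_score, evAllPass$report$pred_score)

  ## filtering that removes each OMP's only partner degrades OMP scores
  ## and the report names the cause
  set.seed(72)
  base <- randomAASequence(100L)
  twins <- c(mutateSequence(base, 0.9), mutateSequence(base, 0.9),
             randomAASequence(100L), randomAASequence(100L))
  libTwin <- toySeparableLibrary(sequences = twins)
  evTwin <- looEvaluate(libTwin, policy = filterPolicy(identityMax = 0.25))
  full <- looEvaluate(libTwin, policy = filterPolicy(stages = character(0)))
  omp <- libLabels(libTwin) == "OMP"
  expect_true(all(evTwin$report$pred_score[omp] <
                  full$report$pred_score[omp]))
  expect_true(all(evTwin$report$n_lib_omp[omp] <
                  full$report$n_lib_omp[omp]))
})
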