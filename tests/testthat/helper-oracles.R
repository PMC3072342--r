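## Independent oracles and random-input generators shared by the tests.

## Exhaustive enumeration of all monotone (crossing-free) element
## matchings between two element sequences; returns the best total
## score. Deliberately NOT a dynamic program: each matching is built
## explicitly, so this is an independent check on the DP alignment.
bruteForceAlignScore <- function(a, b, scheme = scoringScheme()) {
  tA <- elementTypes(a); lA <- elementLengths(a)
  tB <- elementTypes(b); lB <- elementLengths(b)
  n <- length(tA); m <- length(tB)
  g <- scheme@gapCost
  w <- scheme@weights
  best <- -Inf
  recurse <- function(i, j, matched, score) {
    ## stopping here leaves everything from i/j onward unmatched
    total <- score - g * ((n - matched) + (m - matched))
    if (total > best) best <<- total
    if (i > n || j > m) return(invisible())
    for (j2 in j:m)
      recurse(i + 1L, j2 + 1L, matched + 1L,
              score + w[tA[i], tB[j2]] * min(lA[i], lB[j2]))
    recurse(i + 1L, j, matched, score)
    invisible()
  }
  recurse(1L, 1L, 0L, 0)
  best
}

## random H/E/C string of the given length
randomSSEString <- function(len, id = "rnd") {
  SSEString(id, paste(sample(c("H", "E", "C"), len, replace = TRUE),
                      collapse = ""))
}

## random element sequence with no adjacent equal types
randomElementSequence <- function(nElem, maxLen = 12L, id = "rnd") {
  types <- character(nElem)
  types[1L] <- sample(c("H", "E", "C"), 1L)
  if (nElem > 1L)
    for (k in 2:nElem)
      types[k] <- sample(setdiff(c("H", "E", "C"), types[k - 1L]), 1L)
  ElementSequence(id, types, sample.int(maxLen, nElem, replace = TRUE))
}

## tiny hand-built separable library: two mutually similar barrels,
## two mutually similar helix bundles
toySeparableLibrary <- function(sequences = NULL) {
  barrel1 <- SSEString("omp1", strrep("CCEEEEEECC", 10L))
  barrel2 <- SSEString("omp2", strrep("CCCEEEEEEC", 10L))
  helix1 <- SSEString("dec1", strrep("CHHHHHHHHHHHHCC", 6L))
  helix2 <- SSEString("dec2", strrep("CCHHHHHHHHHHHHC", 6L))
  referenceLibrary(list(barrel1, barrel2, helix1, helix2),
                   c("OMP", "OMP", "non-OMP", "non-OMP"),
                   sequences = sequences)
}
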