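#' Build an element-pair scoring scheme
#'
#' The default scheme scores same-type element pairs with weight 1 and
#' every cross-type pair with weight 0, and charges nothing for skipped
#' elements (gap cost 0), so alignment reduces to a maximum-weight
#' non-crossing matching of elements. Cross-type weights can be raised,
#' e.g. to give partial credit for coil against helix or strand.
#'
#' @param pairWeights optional named numeric vector overriding cross-type
#'   weights; names are unordered type pairs written "H:E", "C:H", "C:E"
#'   (order within the name is irrelevant). Same-type weights may also be
#'   overridden ("H:H" etc.) but default to 1.
#' @param gapCost non-negative cost per unmatched element (residue
#'   units); the published method uses 0.
#' @return A \linkS4class{ScoringScheme}.
#' @examples
#' scoringScheme()                       # the default
#' scoringScheme(c("C:H" = 0.5, "C:E" = 0.5))
#' @export
scoringScheme <- function(pairWeights = NULL, gapCost = 0) {
  w <- diag(3)
  dimnames(w) <- list(SSE_ALPHABET, SSE_ALPHABET)
  if (length(pairWeights)) {
    if (is.null(names(pairWeights)))
      stop("'pairWeights' must be named, e.g. c(\"H:E\" = 0.2)")
    for (nm in names(pairWeights)) {
      pr <- toupper(strsplit(nm, ":", fixed = TRUE)[[1L]])
      if (length(pr) != 2L || any(!pr %in% SSE_ALPHABET))
        stop("bad pair name '", nm, "' (use e.g. \"H:E\")")
      w[pr[1L], pr[2L]] <- w[pr[2L], pr[1L]] <- pairWeights[[nm]]
    }
  }
  new("ScoringScheme", weights = w, gapCost = as.numeric(gapCost))
}

#' Read a scoring scheme from a flat config file
#'
#' Lines are "key = value"; keys are unordered type pairs ("H:E") or
#' "gap_cost". Blank lines and '#' comments are ignored.
#'
#' @param path config file path.
#' @return A \linkS4class{ScoringScheme}.
#' @export
readSchemeConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("malformed config line: '", lines[lengths(kv) != 2L][1L], "'")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for key '", keys[is.na(vals)][1L], "'")
  gap <- 0
  isgap <- tolower(keys) %in% c("gap_cost", "gapcost")
  if (any(isgap)) gap <- vals[isgap][1L]
  pw <- vals[!isgap]
  names(pw) <- keys[!isgap]
  scoringScheme(pairWeights = if (length(pw)) pw else NULL, gapCost = gap)
}

#' Score one element pair
#'
#' The score of two elements is the scheme weight of their type pair
#' times the shorter of the two residue lengths, so it never exceeds
#' min(Li, Lj) and is symmetric in its arguments.
#'
#' @param typeA,typeB element types (H/E/C).
#' @param lenA,lenB element residue lengths.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return numeric(1), the element alignment score.
#' @export
elementScore <- function(typeA, lenA, typeB, lenB,
                         scheme = scoringScheme()) {
  stopifnot(typeA %in% SSE_ALPHABET, typeB %in% SSE_ALPHABET,
            lenA >= 1, lenB >= 1)
  scheme@weights[typeA, typeB] * min(lenA, lenB)
}

## pairwise element score matrix, vectorized
elementScoreMatrix <- function(a, b, scheme) {
  W <- scheme@weights[elementTypes(a), elementTypes(b), drop = FALSE]
  M <- outer(elementLengths(a), elementLengths(b), pmin)
  W * M
}

#' Align two element sequences (SSEA)
#'
#' Global dynamic-programming alignment over whole elements (elements are
#' never split). With the default gap cost of 0 the recurrence
#' F(i,j) = max(F(i-1,j), F(i,j-1), F(i-1,j-1) + S(i,j)) finds the
#' maximum-weight non-crossing matching of elements. The total score is
#' bounded by the smaller residue length; dividing by the mean residue
#' length of the two proteins gives the normalized similarity
#' \code{sseaScore} in [0, 1] (1 exactly for self-alignment).
#'
#' Traceback ties prefer the diagonal, then the row step, then the
#' column step, so the reported element pairs are deterministic; the
#' score itself does not depend on the tie-break.
#'
#' @param a,b \linkS4class{ElementSequence} objects (or anything
#'   \code{\link{compressSSE}} accepts).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return An \linkS4class{AlignmentResult}.
#' @examples
#' a <- compressSSE("HHHHCCCCCEEEEEHHHH")
#' sseaScore(sseaAlign(a, a))            # 1
#' @export
setMethod("sseaAlign", signature("ElementSequence", "ElementSequence"),
          function(a, b, scheme = scoringScheme()) {
  stopifnot(is(scheme, "ScoringScheme"))
  S <- elementScoreMatrix(a, b, scheme)
  g <- scheme@gapCost
  F <- ssea_dp_fill(S, g)
  n <- nrow(S); m <- ncol(S)
  total <- F[n + 1L, m + 1L]
  ## traceback: diagonal > up > left
  pairs <- matrix(integer(0), ncol = 2L)
  i <- n; j <- m
  eps <- 1e-9
  while (i > 0L && j > 0L) {
    if (abs(F[i + 1L, j + 1L] - (F[i, j] + S[i, j])) < eps) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (abs(F[i + 1L, j + 1L] - (F[i, j + 1L] - g)) < eps) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  colnames(pairs) <- c("a", "b")
  norm <- (residueLength(a) + residueLength(b)) / 2
  new("AlignmentResult", idA = sseID(a), idB = sseID(b),
      score = total, sseaScore = total / norm, pairs = pairs)
})

#' @rdname sseaAlign
#' @export
setMethod("sseaAlign", signature("ANY", "ANY"),
          function(a, b, scheme = scoringScheme())
            sseaAlign(compressSSE(a), compressSSE(b), scheme))

#' @rdname AlignmentResult-class
#' @param x an \linkS4class{AlignmentResult}.
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @rdname AlignmentResult-class
#' @export
setMethod("sseaScore", "AlignmentResult", function(x) x@sseaScore)

#' @rdname AlignmentResult-class
#' @export
setMethod("alignedPairs", "AlignmentResult", function(x) x@pairs)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("SSEA alignment %s vs %s\n  total score: %g\n  SSEA score: %.3f\n  matched elements: %d\n",
              object@idA, object@idB, object@score, object@sseaScore,
              nrow(object@pairs)))
})

#' Render an element alignment as text
#'
#' Human-readable listing of the matched element pairs of an alignment.
#'
#' @param res an \linkS4class{AlignmentResult}.
#' @param a,b the aligned \linkS4class{ElementSequence} objects.
#' @return character vector of lines, invisibly printed.
#' @export
renderAlignment <- function(res, a, b) {
  p <- alignedPairs(res)
  if (!nrow(p)) return("(no matched elements)")
  lines <- sprintf("%3d %s%-4d ~ %3d %s%-4d",
                   p[, 1L], elementTypes(a)[p[, 1L]],
                   elementLengths(a)[p[, 1L]],
                   p[, 2L], elementTypes(b)[p[, 2L]],
                   elementLengths(b)[p[, 2L]])
  c(sprintf("%s vs %s: SSEA score %.3f", sseID(a), sseID(b),
            sseaScore(res)), lines)
}
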