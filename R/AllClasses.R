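#' Valid three-state secondary structure symbols
#'
#' Helix (H), strand (E) and coil (C); every per-residue secondary
#' structure handled by the package is drawn from this alphabet.
#' @export
SSE_ALPHABET <- c("H", "E", "C")

#' Per-residue three-state secondary structure of one protein
#'
#' Stores an identifier and one character per residue from the alphabet
#' \{H, E, C\}. Empty strings are rejected: downstream similarity
#' normalization divides by residue length.
#'
#' @slot id character(1), protein identifier.
#' @slot states character(1), the per-residue states as a single string.
#' @export
setClass("SSEString", representation(id = "character", states = "character"))

setValidity("SSEString", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@states) != 1L || is.na(object@states))
    return("'states' must be a single string")
  if (nchar(object@states) < 1L)
    return("empty secondary structure string")
  ch <- strsplit(object@states, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% SSE_ALPHABET)
  if (length(bad))
    return(sprintf("invalid secondary structure character '%s' at position %d (alphabet is H/E/C)",
                   ch[bad[1L]], bad[1L]))
  TRUE
})

#' Run-length encoded secondary structure elements
#'
#' An ordered sequence of maximal runs ("elements"), each a type in
#' \{H, E, C\} with a residue length. Adjacent elements always differ in
#' type, and the element lengths sum to the residue length of the
#' originating \linkS4class{SSEString}.
#'
#' @slot id character(1), protein identifier.
#' @slot types character vector of element types.
#' @slot lengths integer vector of element residue lengths (all >= 1).
#' @export
setClass("ElementSequence",
         representation(id = "character", types = "character",
                        lengths = "integer"))

setValidity("ElementSequence", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  n <- length(object@types)
  if (n < 1L) return("element sequence must contain at least one element")
  if (length(object@lengths) != n)
    return("'types' and 'lengths' must have equal length")
  if (any(!object@types %in% SSE_ALPHABET))
    return("element types must be H, E or C")
  if (any(is.na(object@lengths)) || any(object@lengths < 1L))
    return("element lengths must be positive integers")
  if (n > 1L && any(object@types[-1L] == object@types[-n]))
    return("adjacent elements must differ in type (maximal runs)")
  TRUE
})

#' Element-pair scoring scheme for SSEA
#'
#' A symmetric 3x3 weight matrix over the \{H, E, C\} alphabet with
#' entries in [0, 1] and a non-negative gap cost in residue units. The
#' default weights give 1 to same-type pairs and 0 to every cross-type
#' pair, and the default gap cost is 0 (skipping an element is free).
#'
#' @slot weights symmetric numeric 3x3 matrix, dimnames H/E/C.
#' @slot gapCost numeric(1), cost per unmatched element.
#' @export
setClass("ScoringScheme",
         representation(weights = "matrix", gapCost = "numeric"))

setValidity("ScoringScheme", function(object) {
  w <- object@weights
  if (!is.numeric(w) || !identical(dim(w), c(3L, 3L)) ||
      !identical(rownames(w), SSE_ALPHABET) ||
      !identical(colnames(w), SSE_ALPHABET))
    return("'weights' must be a numeric 3x3 matrix with dimnames H/E/C")
  if (any(is.na(w)) || any(w < 0) || any(w > 1))
    return("all weights must lie in [0, 1]")
  if (!isTRUE(all.equal(w, t(w))))
    return("'weights' must be symmetric")
  if (length(object@gapCost) != 1L || is.na(object@gapCost) ||
      object@gapCost < 0)
    return("'gapCost' must be a single non-negative number")
  TRUE
})

#' Result of aligning two element sequences
#'
#' @slot idA,idB character(1), identifiers of the aligned sequences.
#' @slot score numeric(1), total alignment score in residue units; bounded
#'   by the smaller residue length.
#' @slot sseaScore numeric(1), score normalized by the mean residue length
#'   of the two proteins, in [0, 1].
#' @slot pairs integer matrix with two columns, matched element indices in
#'   A and B, strictly increasing in both (crossing-free).
#' @export
setClass("AlignmentResult",
         representation(idA = "character", idB = "character",
                        score = "numeric", sseaScore = "numeric",
                        pairs = "matrix"))

setValidity("AlignmentResult", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("'pairs' must have two columns")
  if (nrow(p) > 1L &&
      (any(diff(p[, 1L]) <= 0L) || any(diff(p[, 2L]) <= 0L)))
    return("'pairs' must be strictly increasing in both coordinates")
  TRUE
})

#' Labeled reference library for nearest-neighbour classification
#'
#' A collection of element sequences labeled OMP or non-OMP, optionally
#' carrying amino-acid sequences for the identity-based homology filter.
#' Both classes must be represented, because prediction takes a maximum
#' over each.
#'
#' @slot ids character vector, unique entry identifiers.
#' @slot labels character vector, each "OMP" or "non-OMP".
#' @slot elements list of \linkS4class{ElementSequence}.
#' @slot sequences character vector of amino-acid sequences (NA where
#'   absent).
#' @export
setClass("ReferenceLibrary",
         representation(ids = "character", labels = "character",
                        elements = "list", sequences = "character"))

## The both-classes requirement is enforced where it matters -- at
## construction (referenceLibrary) and at prediction time -- rather than
## here, so that homology filtering may legitimately produce
## class-depleted subsets during leave-one-out evaluation.
setValidity("ReferenceLibrary", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("library ids must be unique")
  if (length(object@labels) != n || length(object@elements) != n ||
      length(object@sequences) != n)
    return("ids, labels, elements and sequences must have equal length")
  if (any(!object@labels %in% c("OMP", "non-OMP")))
    return("labels must be exactly \"OMP\" or \"non-OMP\"")
  if (!all(vapply(object@elements, is, logical(1L), "ElementSequence")))
    return("'elements' must all be ElementSequence objects")
  TRUE
})

#' Nearest-neighbour OMP prediction for one query
#'
#' @slot queryID character(1).
#' @slot scoreMaxOMP numeric(1), best similarity to any OMP entry.
#' @slot scoreMaxNonOMP numeric(1), best similarity to any non-OMP entry.
#' @slot predScore numeric(1), their difference, in [-1, 1].
#' @slot call character(1), "OMP" or "non-OMP".
#' @slot topOMPHit character(1), id of the OMP entry achieving the
#'   maximum (first such entry in library order on ties).
#' @export
setClass("PredictionResult",
         representation(queryID = "character", scoreMaxOMP = "numeric",
                        scoreMaxNonOMP = "numeric", predScore = "numeric",
                        call = "character", topOMPHit = "character"))

setValidity("PredictionResult", function(object) {
  if (!object@call %in% c("OMP", "non-OMP"))
    return("call must be \"OMP\" or \"non-OMP\"")
  d <- object@scoreMaxOMP - object@scoreMaxNonOMP
  if (!isTRUE(all.equal(d, object@predScore)))
    return("predScore must equal scoreMaxOMP - scoreMaxNonOMP")
  TRUE
})
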