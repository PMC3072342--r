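#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment of two amino-acid sequences
#' (BLOSUM62, gap open 11, extend 1 -- the common BLAST-like defaults)
#' with identity defined as the number of identical aligned positions
#' divided by the alignment length including gap columns. The 25\%
#' homology cut is sensitive to these conventions, so the parameters
#' are exposed.
#'
#' @param a,b amino-acid sequences as plain strings.
#' @param gapOpening,gapExtension gap penalties (positive costs).
#' @param substitutionMatrix scoring matrix name or matrix.
#' @return numeric(1) identity in [0, 1].
#' @export
globalIdentity <- function(a, b, gapOpening = 11, gapExtension = 1,
                           substitutionMatrix = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  sum(s1 == s2 & s1 != "-") / length(s1)
}

#' Homology-filtering policy
#'
#' Describes the stringent two-procedure filtering applied to the
#' library before each leave-one-out prediction: entries are retained
#' only when their global identity to the test protein is strictly
#' below \code{identityMax} (default 25\%), their pairwise-search
#' e-value is strictly above \code{evalueMin} (default 0.01), and their
#' profile-search e-value is strictly above \code{evalueMin}. Each
#' stage is enabled through \code{stages}.
#'
#' @param identityMax maximum tolerated identity, in (0, 1].
#' @param evalueMin minimum tolerated e-value, > 0.
#' @param stages character subset of \code{c("identity",
#'   "search_evalue", "profile_evalue")}; empty means no filtering.
#' @return A list of class "FilterPolicy".
#' @export
filterPolicy <- function(identityMax = 0.25, evalueMin = 0.01,
                         stages = "identity") {
  stages <- as.character(stages)
  bad <- setdiff(stages, c("identity", "search_evalue", "profile_evalue"))
  if (length(bad)) stop("unknown filter stage(s): ", paste(bad, collapse = ", "))
  if (!(identityMax > 0 && identityMax <= 1))
    stop("'identityMax' must lie in (0, 1]")
  if (!(evalueMin > 0)) stop("'evalueMin' must be positive")
  structure(list(identityMax = identityMax, evalueMin = evalueMin,
                 stages = stages), class = "FilterPolicy")
}

#' Build an e-value hook from a tabular homology-search result
#'
#' Adapts the tab-separated output convention of standard homology
#' search tools to the hook contract used by \code{\link{filterLibrary}}.
#' A 12-column table is read as outfmt-6 (query id, subject id, ...,
#' e-value in column 11); otherwise the first three columns are taken as
#' query id, subject id, e-value. The returned function maps a
#' (test, entry) pair to the smallest recorded e-value in either
#' direction, or NA when the pair was never hit (treated as passing).
#'
#' @param x a file path or data.frame.
#' @param header logical; whether a file has a header row.
#' @return function(test, entry) -> numeric e-value or NA.
#' @export
evalueHookFromTable <- function(x, header = FALSE) {
  tab <- if (is.character(x))
    read.delim(x, header = header, stringsAsFactors = FALSE)
  else x
  if (ncol(tab) >= 12L) tab <- tab[, c(1L, 2L, 11L)]
  else if (ncol(tab) >= 3L) tab <- tab[, 1:3]
  else stop("e-value table needs at least 3 columns")
  names(tab) <- c("query", "subject", "evalue")
  tab$evalue <- as.numeric(tab$evalue)
  key <- c(paste(tab$query, tab$subject, sep = "\r"),
           paste(tab$subject, tab$query, sep = "\r"))
  ev <- rep(tab$evalue, 2L)
  best <- tapply(ev, key, min)
  function(test, entry) {
    v <- best[paste(test$id, entry$id, sep = "\r")]
    if (is.na(v)) NA_real_ else unname(v)
  }
}

#' Remove library entries homologous to a test protein
#'
#' Applies the enabled stages of a \code{\link{filterPolicy}} against a
#' test protein and keeps exactly the entries passing all of them:
#' global identity strictly below the cut, and search/profile e-values
#' strictly above the cut. E-value stages consult pluggable hooks
#' (see \code{\link{evalueHookFromTable}}); a hook returning NA means
#' "no hit", which passes. A hook that errors retains the entry with a
#' warning (fail-open), so a broken hook cannot silently shrink the
#' library. Filtering is idempotent.
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param test the test protein: a list with elements \code{id} and
#'   \code{sequence} (amino acids; required for the identity stage).
#' @param policy a \code{\link{filterPolicy}}.
#' @param evalueHook,profileEvalueHook functions (test, entry) ->
#'   e-value or NA, for the "search_evalue" and "profile_evalue"
#'   stages. When a stage is enabled but its hook is NULL the stage is
#'   skipped with a message (the identity-only variant of the
#'   protocol).
#' @return The filtered \linkS4class{ReferenceLibrary} (possibly
#'   class-depleted; see \code{\link{looEvaluate}}).
#' @export
filterLibrary <- function(lib, test, policy = filterPolicy(),
                          evalueHook = NULL, profileEvalueHook = NULL) {
  stopifnot(is(lib, "ReferenceLibrary"), inherits(policy, "FilterPolicy"))
  if (is.character(test)) test <- list(id = "test", sequence = test)
  keep <- rep(TRUE, length(lib))
  if ("identity" %in% policy$stages) {
    if (is.null(test$sequence) || is.na(test$sequence))
      stop("identity filtering requires the test protein's amino-acid sequence")
    seqs <- libSequences(lib)
    if (anyNA(seqs))
      stop("identity filtering requires amino-acid sequences for every library entry")
    idd <- vapply(seqs, function(s) globalIdentity(test$sequence, s),
                  numeric(1L), USE.NAMES = FALSE)
    keep <- keep & (idd < policy$identityMax)
  }
  applyHook <- function(hook, keep, stage) {
    if (is.null(hook)) {
      message("e-value hook for stage '", stage,
              "' not provided; stage skipped")
      return(keep)
    }
    for (k in which(keep)) {
      ev <- tryCatch(
        hook(test, list(id = libIDs(lib)[k],
                        sequence = libSequences(lib)[k])),
        error = function(e) {
          warning(sprintf("e-value hook failed for '%s' (%s); entry retained",
                          libIDs(lib)[k], conditionMessage(e)),
                  call. = FALSE)
          NA_real_
        })
      if (!is.na(ev) && ev <= policy$evalueMin) keep[k] <- FALSE
    }
    keep
  }
  if ("search_evalue" %in% policy$stages)
    keep <- applyHook(evalueHook, keep, "search_evalue")
  if ("profile_evalue" %in% policy$stages)
    keep <- applyHook(profileEvalueHook, keep, "profile_evalue")
  lib[keep]
}
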