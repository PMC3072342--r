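#' Leave-one-out evaluation with stringent homology filtering
#'
#' Runs the full benchmarking protocol: each library entry in turn is
#' held out as the test protein, the remaining entries are passed
#' through \code{\link{filterLibrary}} with the given policy, the test
#' protein is classified against the filtered library, and the
#' prediction is recorded. Results are aggregated into a confusion
#' matrix at the given threshold, the derived Ac/Sn/Sp/MCC metrics, and
#' an ROC curve over all thresholds.
#'
#' A test protein whose filtered library has lost an entire class
#' cannot be scored by the two-maximum rule; it is recorded as
#' unpredictable, counted conservatively as a non-OMP call (prediction
#' score -1, the minimum attainable), and flagged in the per-protein
#' report.
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param policy a \code{\link{filterPolicy}}; use
#'   \code{filterPolicy(stages = character(0))} for no filtering.
#' @param threshold decision threshold on the prediction score.
#' @param evalueHook,profileEvalueHook optional e-value hooks, as in
#'   \code{\link{filterLibrary}}.
#' @return list with \code{counts} (ConfusionCounts), \code{metrics}
#'   (from \code{\link{evalMetrics}}), \code{roc} (from
#'   \code{\link{rocCurve}}) and \code{report} (data.frame: id, label,
#'   pred_score, call, top_omp_hit, n_lib_omp, n_lib_nonomp,
#'   unpredictable).
#' @export
looEvaluate <- function(lib, scheme = scoringScheme(),
                        policy = filterPolicy(stages = character(0)),
                        threshold = 0,
                        evalueHook = NULL, profileEvalueHook = NULL) {
  stopifnot(is(lib, "ReferenceLibrary"))
  n <- length(lib)
  ids <- libIDs(lib)
  labels <- libLabels(lib)
  seqs <- libSequences(lib)
  predScores <- numeric(n)
  calls <- character(n)
  hits <- character(n)
  nOMP <- integer(n)
  nNon <- integer(n)
  unpred <- logical(n)
  for (i in seq_len(n)) {
    rest <- lib[-i]
    filtered <- filterLibrary(rest,
                              list(id = ids[i], sequence = seqs[i]),
                              policy, evalueHook, profileEvalueHook)
    nOMP[i] <- sum(libLabels(filtered) == "OMP")
    nNon[i] <- sum(libLabels(filtered) == "non-OMP")
    if (nOMP[i] == 0L || nNon[i] == 0L) {
      unpred[i] <- TRUE
      predScores[i] <- -1
      calls[i] <- "non-OMP"
      hits[i] <- NA_character_
      next
    }
    r <- predictOMP(libElements(lib)[[i]], filtered, scheme, threshold)
    predScores[i] <- predScore(r)
    calls[i] <- predCall(r)
    hits[i] <- r@topOMPHit
  }
  pos <- labels == "OMP"
  counts <- confusionCounts(tp = sum(pos & calls == "OMP"),
                            fp = sum(!pos & calls == "OMP"),
                            fn = sum(pos & calls == "non-OMP"),
                            tn = sum(!pos & calls == "non-OMP"))
  list(counts = counts,
       metrics = evalMetrics(counts),
       roc = rocCurve(predScores, pos),
       report = data.frame(id = ids, label = labels,
                           pred_score = predScores, call = calls,
                           top_omp_hit = hits, n_lib_omp = nOMP,
                           n_lib_nonomp = nNon, unpredictable = unpred,
                           stringsAsFactors = FALSE))
}
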