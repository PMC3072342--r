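#' Classify a query against a labeled library
#'
#' Computes the SSEA similarity of the query to every library entry,
#' records the best score within each class, and forms the prediction
#' score as their difference
#' \code{predScore = max(OMP scores) - max(non-OMP scores)}. The query
#' is called OMP when the prediction score strictly exceeds the
#' threshold (default 0); a tied score is a non-OMP call. Ties in the
#' arg-max are broken by library order.
#'
#' @param query an \linkS4class{ElementSequence} (or anything
#'   \code{\link{compressSSE}} accepts).
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param threshold decision threshold on the prediction score.
#' @return A \linkS4class{PredictionResult}.
#' @export
predictOMP <- function(query, lib, scheme = scoringScheme(),
                       threshold = 0) {
  stopifnot(is(lib, "ReferenceLibrary"))
  query <- compressSSE(query)
  iOMP <- libWhich(lib, "OMP")
  iNon <- libWhich(lib, "non-OMP")
  if (!length(iOMP) || !length(iNon))
    stop("library must contain both OMP and non-OMP entries")
  scores <- vapply(libElements(lib),
                   function(e) sseaScore(sseaAlign(query, e, scheme)),
                   numeric(1L), USE.NAMES = FALSE)
  kOMP <- iOMP[which.max(scores[iOMP])]
  sOMP <- scores[kOMP]
  sNon <- max(scores[iNon])
  d <- sOMP - sNon
  new("PredictionResult", queryID = sseID(query),
      scoreMaxOMP = sOMP, scoreMaxNonOMP = sNon, predScore = d,
      call = if (d > threshold) "OMP" else "non-OMP",
      topOMPHit = libIDs(lib)[kOMP])
}

#' @rdname PredictionResult-class
#' @param x a \linkS4class{PredictionResult}.
#' @export
setMethod("predScore", "PredictionResult", function(x) x@predScore)

#' @rdname PredictionResult-class
#' @export
setMethod("predCall", "PredictionResult", function(x) x@call)

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf(
    "OMP prediction for '%s': %s\n  best OMP hit: %s (SSEA %.3f)\n  best non-OMP SSEA: %.3f\n  prediction score: %.3f\n",
    object@queryID, object@call, object@topOMPHit, object@scoreMaxOMP,
    object@scoreMaxNonOMP, object@predScore))
})

#' Classify a batch of queries
#'
#' Applies \code{\link{predictOMP}} to each query, preserving input
#' order. A malformed query is skipped with a warning rather than
#' aborting the batch.
#'
#' @param queries list of queries.
#' @param lib,scheme,threshold as in \code{\link{predictOMP}}.
#' @return A list of \linkS4class{PredictionResult} (skipped queries
#'   omitted).
#' @export
predictBatch <- function(queries, lib, scheme = scoringScheme(),
                         threshold = 0) {
  out <- vector("list", length(queries))
  keep <- logical(length(queries))
  for (k in seq_along(queries)) {
    r <- tryCatch(predictOMP(queries[[k]], lib, scheme, threshold),
                  error = function(e) {
                    warning(sprintf("query %d skipped: %s", k,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) { out[[k]] <- r; keep[k] <- TRUE }
  }
  out[keep]
}

#' Tabulate prediction results
#'
#' @param results list of \linkS4class{PredictionResult}.
#' @return data.frame with one row per query: query_id, top_omp_hit,
#'   ssea_score_max_omp, ssea_score_max_nonomp, pred_score, call.
#' @export
predictionTable <- function(results) {
  data.frame(
    query_id = vapply(results, slot, "", "queryID"),
    top_omp_hit = vapply(results, slot, "", "topOMPHit"),
    ssea_score_max_omp = vapply(results, slot, 0, "scoreMaxOMP"),
    ssea_score_max_nonomp = vapply(results, slot, 0, "scoreMaxNonOMP"),
    pred_score = vapply(results, slot, 0, "predScore"),
    call = vapply(results, slot, "", "call"),
    stringsAsFactors = FALSE)
}

#' Calibrate a decision threshold at a target false positive rate
#'
#' Runs leave-one-out predictions over the library (each entry scored
#' against the remaining entries, no homology filtering) and returns the
#' smallest threshold alpha among the observed scores such that the
#' fraction of non-OMP entries with prediction score strictly above
#' alpha is at most \code{targetFPR}. This reproduces the workflow
#' behind a library-specific confidence cut (e.g. a 1\% false positive
#' rate for 99\% confidence).
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param targetFPR target false positive rate in (0, 1).
#' @return numeric(1), the calibrated threshold.
#' @export
calibrateThreshold <- function(lib, scheme = scoringScheme(),
                               targetFPR = 0.01) {
  stopifnot(is(lib, "ReferenceLibrary"),
            targetFPR > 0, targetFPR < 1)
  scores <- looPredScores(lib, scheme)
  nonScores <- scores[libLabels(lib) == "non-OMP"]
  cand <- sort(unique(scores))
  if (length(cand) == 1L) {
    warning("all leave-one-out scores are tied; returning the maximum")
    return(cand)
  }
  for (a in cand) {
    if (mean(nonScores > a) <= targetFPR) return(a)
  }
  max(cand)
}

## leave-one-out prediction scores without homology filtering; shared by
## calibrateThreshold and tests
looPredScores <- function(lib, scheme = scoringScheme()) {
  n <- length(lib)
  vapply(seq_len(n), function(i)
    predScore(predictOMP(libElements(lib)[[i]], lib[-i], scheme)),
    numeric(1L))
}
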