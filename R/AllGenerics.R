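#' @export
setGeneric("sseID", function(x) standardGeneric("sseID"))

#' @export
setGeneric("residueLength", function(x) standardGeneric("residueLength"))

#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @export
setGeneric("elementTypes", function(x) standardGeneric("elementTypes"))

#' @export
setGeneric("elementLengths", function(x) standardGeneric("elementLengths"))

#' @export
setGeneric("compressSSE", function(x) standardGeneric("compressSSE"))

#' @export
setGeneric("expandElements", function(x) standardGeneric("expandElements"))

#' @export
setGeneric("sseaAlign",
           function(a, b, scheme = scoringScheme())
             standardGeneric("sseaAlign"))

#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @export
setGeneric("sseaScore", function(x) standardGeneric("sseaScore"))

#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @export
setGeneric("libIDs", function(x) standardGeneric("libIDs"))

#' @export
setGeneric("libLabels", function(x) standardGeneric("libLabels"))

#' @export
setGeneric("libElements", function(x) standardGeneric("libElements"))

#' @export
setGeneric("libSequences", function(x) standardGeneric("libSequences"))

#' @export
setGeneric("predScore", function(x) standardGeneric("predScore"))

#' @export
setGeneric("predCall", function(x) standardGeneric("predCall"))
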