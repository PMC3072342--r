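#' Construct a labeled reference library
#'
#' @param elements list of \linkS4class{ElementSequence} (or objects
#'   acceptable to \code{\link{compressSSE}}).
#' @param labels character vector, "OMP" or "non-OMP", one per entry.
#' @param sequences optional character vector of amino-acid sequences
#'   (NA where unavailable); required only by the identity-based
#'   homology filter.
#' @param ids optional ids; default taken from the elements.
#' @return A \linkS4class{ReferenceLibrary}.
#' @export
referenceLibrary <- function(elements, labels, sequences = NULL,
                             ids = NULL) {
  elements <- lapply(elements, compressSSE)
  if (is.null(ids))
    ids <- vapply(elements, sseID, "")
  if (is.null(sequences))
    sequences <- rep(NA_character_, length(elements))
  labels <- as.character(labels)
  if (!any(labels == "OMP") || !any(labels == "non-OMP"))
    stop("library must contain at least one OMP and one non-OMP entry")
  names(elements) <- as.character(ids)
  new("ReferenceLibrary", ids = as.character(ids),
      labels = labels, elements = elements,
      sequences = toupper(as.character(sequences)))
}

#' @rdname ReferenceLibrary-class
#' @param x a \linkS4class{ReferenceLibrary}.
#' @export
setMethod("libIDs", "ReferenceLibrary", function(x) x@ids)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("libLabels", "ReferenceLibrary", function(x) x@labels)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("libElements", "ReferenceLibrary", function(x) x@elements)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("libSequences", "ReferenceLibrary", function(x) x@sequences)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("length", "ReferenceLibrary", function(x) length(x@ids))

#' @rdname ReferenceLibrary-class
#' @param i index vector (integer, logical or entry ids).
#' @param j,drop,... unused.
#' @export
setMethod("[", "ReferenceLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("ReferenceLibrary", ids = x@ids[i], labels = x@labels[i],
      elements = x@elements[i], sequences = x@sequences[i])
})

setMethod("show", "ReferenceLibrary", function(object) {
  cat(sprintf("ReferenceLibrary: %d entries (%d OMP, %d non-OMP)%s\n",
              length(object@ids), sum(object@labels == "OMP"),
              sum(object@labels == "non-OMP"),
              if (all(is.na(object@sequences))) ""
              else ", amino-acid sequences attached"))
})

## entry subsets used throughout
libWhich <- function(lib, label) which(libLabels(lib) == label)

## ---- manifest IO ---------------------------------------------------------

#' Read a reference library from a TSV manifest
#'
#' The manifest has a header and columns \code{id}, \code{label}
#' (exactly "OMP" or "non-OMP"), \code{sse} and optionally \code{fasta}.
#' The \code{sse} field is either a path (relative to the manifest) to a
#' FASTA-like SSE file, a PSIPRED .ss2/.horiz file, or a literal H/E/C
#' string. The \code{fasta} field, when present, points to the entry's
#' amino-acid sequence for homology filtering.
#'
#' @param path manifest path.
#' @return A \linkS4class{ReferenceLibrary}.
#' @export
readLibraryManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "label", "sse")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  elements <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    src <- tab$sse[k]
    if (grepl("^[HEChec]+$", src)) {
      elements[[k]] <- compressSSE(SSEString(tab$id[k], src))
    } else {
      f <- resolve(src)
      if (!file.exists(f))
        stop("SSE source for '", tab$id[k], "' not found: ", src)
      if (grepl("\\.(ss2|horiz)$", f)) {
        elements[[k]] <- compressSSE(readPsipred(f, id = tab$id[k]))
      } else {
        recs <- readSSEFasta(f)
        s <- if (tab$id[k] %in% names(recs)) recs[[tab$id[k]]]
             else recs[[1L]]
        elements[[k]] <- compressSSE(SSEString(tab$id[k], sseStates(s)))
      }
    }
  }
  sequences <- rep(NA_character_, nrow(tab))
  if ("fasta" %in% names(tab)) {
    for (k in seq_len(nrow(tab))) {
      src <- tab$fasta[k]
      if (is.na(src) || !nzchar(src)) next
      f <- resolve(src)
      if (!file.exists(f))
        stop("FASTA for '", tab$id[k], "' not found: ", src)
      aa <- Biostrings::readAAStringSet(f)
      hit <- match(tab$id[k], sub("\\s.*$", "", names(aa)))
      sequences[k] <- as.character(aa[[if (is.na(hit)) 1L else hit]])
    }
  }
  referenceLibrary(elements, tab$label, sequences, ids = tab$id)
}

#' Write a reference library as manifest plus SSE/FASTA files
#'
#' Writes \code{library.tsv} (columns id, label, sse, fasta),
#' \code{sse.fasta} and, when amino-acid sequences are attached,
#' \code{aa.fasta} under \code{dir}.
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeLibraryManifest <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ssePath <- file.path(dir, "sse.fasta")
  writeSSEFasta(lapply(libElements(lib), expandElements), ssePath)
  hasAA <- !is.na(libSequences(lib))
  fastaCol <- rep("", length(lib))
  if (any(hasAA)) {
    aa <- Biostrings::AAStringSet(libSequences(lib)[hasAA])
    names(aa) <- libIDs(lib)[hasAA]
    Biostrings::writeXStringSet(aa, file.path(dir, "aa.fasta"))
    fastaCol[hasAA] <- "aa.fasta"
  }
  tab <- data.frame(id = libIDs(lib), label = libLabels(lib),
                    sse = "sse.fasta", fasta = fastaCol,
                    stringsAsFactors = FALSE)
  manifest <- file.path(dir, "library.tsv")
  write.table(tab, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
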