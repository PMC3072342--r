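#' Construct a secondary structure string
#'
#' Validates the three-state alphabet strictly: lower-case letters are
#' accepted and upper-cased, but any character outside \{H, E, C\} is an
#' error naming the offending position -- there is no silent coercion.
#'
#' @param id protein identifier.
#' @param states per-residue states, either a single string or a character
#'   vector of single letters.
#' @return An \linkS4class{SSEString}.
#' @examples
#' s <- SSEString("demo", "HHHHCCCCCEEEEEHHHH")
#' compressSSE(s)
#' @export
SSEString <- function(id, states) {
  if (length(states) > 1L) states <- paste(states, collapse = "")
  new("SSEString", id = as.character(id), states = toupper(states))
}

#' Construct an element sequence directly
#'
#' Mostly useful in tests and simulations; ordinary use goes through
#' \code{\link{compressSSE}}. Adjacent same-type elements are rejected
#' because elements are by definition maximal runs.
#'
#' @param id protein identifier.
#' @param types character vector of element types (H/E/C).
#' @param lengths integer vector of element residue lengths.
#' @return An \linkS4class{ElementSequence}.
#' @export
ElementSequence <- function(id, types, lengths) {
  new("ElementSequence", id = as.character(id),
      types = toupper(as.character(types)),
      lengths = as.integer(lengths))
}

#' @describeIn SSEString-class identifier accessor
#' @param x an object.
#' @export
setMethod("sseID", "SSEString", function(x) x@id)

#' @rdname ElementSequence-class
#' @export
setMethod("sseID", "ElementSequence", function(x) x@id)

#' @rdname SSEString-class
#' @export
setMethod("residueLength", "SSEString", function(x) nchar(x@states))

#' @rdname ElementSequence-class
#' @export
setMethod("residueLength", "ElementSequence",
          function(x) sum(x@lengths))

#' @rdname ElementSequence-class
#' @export
setMethod("nElements", "ElementSequence", function(x) length(x@types))

#' @rdname ElementSequence-class
#' @export
setMethod("elementTypes", "ElementSequence", function(x) x@types)

#' @rdname ElementSequence-class
#' @export
setMethod("elementLengths", "ElementSequence", function(x) x@lengths)

#' Per-residue states of a secondary structure string
#' @param x an \linkS4class{SSEString}.
#' @return character(1) of H/E/C letters.
#' @export
sseStates <- function(x) {
  stopifnot(is(x, "SSEString"))
  x@states
}

setMethod("show", "SSEString", function(object) {
  n <- nchar(object@states)
  preview <- if (n > 50L) paste0(substr(object@states, 1L, 50L), "...")
             else object@states
  cat(sprintf("SSEString '%s' (%d residues)\n  %s\n",
              object@id, n, preview))
})

setMethod("show", "ElementSequence", function(object) {
  k <- length(object@types)
  head <- paste(sprintf("%s%d", object@types, object@lengths)[seq_len(min(k, 12L))],
                collapse = " ")
  if (k > 12L) head <- paste(head, "...")
  cat(sprintf("ElementSequence '%s': %d elements, %d residues\n  %s\n",
              object@id, k, sum(object@lengths), head))
})

#' Run-length encode a secondary structure string into elements
#'
#' Compresses maximal runs of identical state into typed elements whose
#' residue lengths are retained for scoring: "HHHHCCCCCEEEEEHHHH"
#' becomes the four elements H4 C5 E5 H4. Expanding the result with
#' \code{\link{expandElements}} reproduces the input exactly.
#'
#' @param x an \linkS4class{SSEString} (a plain string is also accepted
#'   and given the id "query").
#' @return An \linkS4class{ElementSequence}.
#' @export
setMethod("compressSSE", "SSEString", function(x) {
  r <- rle(strsplit(x@states, "", fixed = TRUE)[[1L]])
  new("ElementSequence", id = x@id, types = r$values,
      lengths = as.integer(r$lengths))
})

#' @rdname compressSSE
#' @export
setMethod("compressSSE", "character",
          function(x) compressSSE(SSEString("query", x)))

#' @rdname compressSSE
#' @export
setMethod("compressSSE", "ElementSequence", function(x) x)

#' Expand an element sequence back to its per-residue string
#' @param x an \linkS4class{ElementSequence}.
#' @return The originating \linkS4class{SSEString}.
#' @export
setMethod("expandElements", "ElementSequence", function(x) {
  new("SSEString", id = x@id,
      states = paste(rep(x@types, x@lengths), collapse = ""))
})

## ---- readers -------------------------------------------------------------

#' Read secondary structure strings from a FASTA-like file
#'
#' Records are ">id" headers followed by lines of H/E/C letters
#' (whitespace ignored, case-insensitive).
#'
#' @param path file path.
#' @return A named list of \linkS4class{SSEString} objects.
#' @export
readSSEFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers in ", path)
  if (length(trimws(lines[seq_len(hdr[1L] - 1L)])) &&
      any(nzchar(trimws(lines[seq_len(hdr[1L] - 1L)]))))
    stop("content before first '>' header in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr))
  nm <- character(length(hdr))
  for (k in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[k]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    body <- lines[seq(hdr[k] + 1L, length.out = ends[k] - hdr[k])]
    states <- gsub("\\s", "", paste(body, collapse = ""))
    if (!nzchar(states)) stop("empty record '", id, "' in ", path)
    out[[k]] <- SSEString(id, states)
    nm[k] <- id
  }
  names(out) <- nm
  out
}

#' Write secondary structure strings to a FASTA-like file
#' @param x list of \linkS4class{SSEString} objects.
#' @param path output path.
#' @param width line width for the states.
#' @return \code{path}, invisibly.
#' @export
writeSSEFasta <- function(x, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in x) {
    writeLines(paste0(">", sseID(s)), con)
    st <- sseStates(s)
    starts <- seq(1L, nchar(st), by = width)
    writeLines(substring(st, starts, pmin(starts + width - 1L, nchar(st))),
               con)
  }
  invisible(path)
}

#' Read a PSIPRED secondary structure prediction
#'
#' Supports both PSIPRED output dialects. In the vertical \code{.ss2}
#' format each data row is "index residue state pC pH pE"; the state
#' column is PSIPRED's own per-residue call and takes precedence over the
#' probability columns. In the \code{.horiz} format the per-residue states
#' are the concatenation of the "Pred:" lines.
#'
#' @param path file path.
#' @param dialect "auto" (by extension/content), "ss2" or "horiz".
#' @param id identifier for the resulting string; defaults to the file
#'   base name.
#' @return An \linkS4class{SSEString}.
#' @export
readPsipred <- function(path, dialect = c("auto", "ss2", "horiz"),
                        id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    ext <- tolower(sub("^.*\\.", "", basename(path)))
    dialect <- if (ext == "horiz" || any(grepl("^\\s*Pred:", lines)))
      "horiz" else "ss2"
  }
  if (dialect == "horiz") {
    pred <- grep("^\\s*Pred:", lines, value = TRUE)
    if (!length(pred)) stop("no 'Pred:' lines in horiz file ", path)
    states <- gsub("\\s", "",
                   paste(sub("^\\s*Pred:", "", pred), collapse = ""))
    return(SSEString(id, states))
  }
  ## .ss2: skip the "# PSIPRED ..." comment and blank lines
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(dat)) stop("no data rows in ss2 file ", path)
  fields <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed ss2 line ", which(nf < 3L)[1L], " in ", path)
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  if (any(is.na(idx)) || !identical(idx, seq_along(idx)))
    stop("residue indices in ", path, " are not consecutive from 1")
  states <- vapply(fields, `[`, "", 3L)
  SSEString(id, paste(states, collapse = ""))
}

#' Reduce an eight-state DSSP structure string to three states
#'
#' Maps the DSSP structure-summary codes to the H/E/C alphabet using the
#' PSIPRED-style convention: H, G and I (helices) to H; E and B
#' (extended/bridge) to E; T, S, blank and '-' to C. The bridge code B is
#' treated as strand, consistent with the strand-rich barrel topology the
#' alignment is meant to capture. Already-3-state letters pass through.
#'
#' @param states character: the per-residue DSSP codes as one string (or
#'   a character vector of single codes).
#' @param id identifier for the resulting string.
#' @return An \linkS4class{SSEString}.
#' @export
reduceDssp <- function(states, id = "dssp") {
  if (length(states) > 1L) states <- paste(states, collapse = "")
  ch <- strsplit(states, "", fixed = TRUE)[[1L]]
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", " " = "C", "-" = "C", C = "C")
  out <- map[ch]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown DSSP code '%s' at position %d", ch[bad], bad))
  }
  SSEString(id, paste(out, collapse = ""))
}
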