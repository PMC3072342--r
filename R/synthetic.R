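#' Topology profiles for synthetic secondary structure
#'
#' Describes the secondary-structure architecture of a protein class as
#' ranges: a number of core elements of a given type, core element
#' lengths, coil linker lengths and terminal coil lengths (all in
#' residues, all drawn uniformly). The built-in profiles encode the
#' topological contrast the classifier exploits:
#' \describe{
#'   \item{omp_barrel}{8-24 membrane-spanning strands of 6-14 residues
#'     with short linkers -- the beta-barrel architecture of OMPs.}
#'   \item{all_beta_globular}{fewer (4-12), shorter (3-8 residue)
#'     strands with longer loops, as in globular beta sandwiches.}
#'   \item{all_alpha}{4-12 helices of 8-20 residues.}
#'   \item{alpha_beta}{alternating helix/strand cores.}
#'   \item{helical_membrane}{6-12 long (17-25 residue) transmembrane
#'     helices.}
#' }
#' Only \code{omp_barrel} is labeled OMP downstream.
#'
#' @param classLabel one of the five class names above.
#' @param nCoreElements,coreLengthRange,linkerLengthRange,
#'   terminalCoilRange optional length-2 integer ranges overriding the
#'   class defaults.
#' @return A list of class "TopologyProfile".
#' @export
topologyProfile <- function(classLabel = c("omp_barrel", "all_alpha",
                                           "all_beta_globular",
                                           "alpha_beta",
                                           "helical_membrane"),
                            nCoreElements = NULL, coreLengthRange = NULL,
                            linkerLengthRange = NULL,
                            terminalCoilRange = NULL) {
  classLabel <- match.arg(classLabel)
  def <- switch(classLabel,
    omp_barrel = list(n = c(8L, 24L), type = "E", core = c(6L, 14L),
                      linker = c(2L, 10L), term = c(1L, 10L)),
    all_alpha = list(n = c(4L, 12L), type = "H", core = c(8L, 20L),
                     linker = c(2L, 10L), term = c(1L, 10L)),
    all_beta_globular = list(n = c(4L, 12L), type = "E", core = c(3L, 8L),
                             linker = c(5L, 15L), term = c(2L, 12L)),
    alpha_beta = list(n = c(6L, 14L), type = c("H", "E"),
                      core = c(4L, 12L), linker = c(3L, 10L),
                      term = c(1L, 10L)),
    helical_membrane = list(n = c(6L, 12L), type = "H", core = c(17L, 25L),
                            linker = c(3L, 15L), term = c(2L, 12L)))
  p <- list(classLabel = classLabel,
            nCoreElements = as.integer(nCoreElements %||% def$n),
            coreType = def$type,
            coreLengthRange = as.integer(coreLengthRange %||% def$core),
            linkerLengthRange = as.integer(linkerLengthRange %||% def$linker),
            terminalCoilRange = as.integer(terminalCoilRange %||% def$term))
  for (f in c("nCoreElements", "coreLengthRange", "linkerLengthRange",
              "terminalCoilRange")) {
    r <- p[[f]]
    if (length(r) != 2L || anyNA(r) || r[1L] > r[2L] || r[1L] < 1L)
      stop("invalid range for '", f, "'")
  }
  structure(p, class = "TopologyProfile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runifInt <- function(n, range) {
  as.integer(floor(runif(n, range[1L], range[2L] + 1L)))
}

#' Generate one synthetic secondary structure string
#'
#' Core elements alternate with coil linkers and are flanked by terminal
#' coils; all lengths are uniform draws from the profile's ranges.
#' Optional noise flips each residue independently, with the given
#' probability, to a uniformly chosen different state. Output is
#' deterministic given the R random number generator state (seed with
#' \code{set.seed} before calling).
#'
#' @param profile a \code{\link{topologyProfile}}.
#' @param id identifier for the string.
#' @param noise per-residue state-flip probability in [0, 1).
#' @return An \linkS4class{SSEString}.
#' @export
generateSSE <- function(profile, id = profile$classLabel, noise = 0) {
  stopifnot(inherits(profile, "TopologyProfile"), noise >= 0, noise < 1)
  nCore <- runifInt(1L, profile$nCoreElements)
  coreTypes <- rep_len(profile$coreType, nCore)
  coreLens <- runifInt(nCore, profile$coreLengthRange)
  linkLens <- runifInt(nCore - 1L, profile$linkerLengthRange)
  termLens <- runifInt(2L, profile$terminalCoilRange)
  parts <- character(2L * nCore + 1L)
  parts[1L] <- strrep("C", termLens[1L])
  for (k in seq_len(nCore)) {
    parts[2L * k] <- strrep(coreTypes[k], coreLens[k])
    parts[2L * k + 1L] <- if (k < nCore) strrep("C", linkLens[k])
                          else strrep("C", termLens[2L])
  }
  states <- strsplit(paste(parts, collapse = ""), "")[[1L]]
  if (noise > 0) {
    flip <- runif(length(states)) < noise
    if (any(flip))
      states[flip] <- vapply(states[flip], function(s)
        sample(setdiff(SSE_ALPHABET, s), 1L), "")
  }
  SSEString(id, paste(states, collapse = ""))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a random amino-acid sequence
#'
#' Uniform over the 20 standard residues; used to give synthetic
#' library entries sequences for exercising the identity filter.
#'
#' @param n sequence length.
#' @return character(1).
#' @export
randomAASequence <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

#' Mutate a sequence to a controlled identity level
#'
#' Substitutes a fixed number of uniformly chosen positions with a
#' different residue, so the unaligned (and, absent indels, the
#' aligned) identity to the input is approximately \code{identity}.
#'
#' @param seq amino-acid sequence.
#' @param identity target fraction of conserved positions.
#' @return character(1), the mutated copy.
#' @export
mutateSequence <- function(seq, identity) {
  stopifnot(identity >= 0, identity <= 1)
  ch <- strsplit(seq, "")[[1L]]
  nMut <- round((1 - identity) * length(ch))
  pos <- sample(length(ch), nMut)
  ch[pos] <- vapply(ch[pos], function(s)
    sample(setdiff(AA20, s), 1L), "")
  paste(ch, collapse = "")
}

#' Specification of a synthetic labeled library
#'
#' The defaults define the package's standard test conditions: 40 OMP
#' barrels against 60 decoys (20 all-alpha, 20 globular all-beta, 10
#' alpha/beta, 10 helical-membrane), 2\% per-residue state-flip noise,
#' and a fixed seed that fully determines the output.
#'
#' @param nPerClass named integer vector of library entry counts per
#'   class label.
#' @param nQueriesPerClass held-out query count per class (disjoint
#'   draws from the same profiles).
#' @param noise per-residue state-flip probability.
#' @param seed integer seed.
#' @param profiles optional named list of \code{\link{topologyProfile}}
#'   overrides.
#' @return A list of class "SyntheticLibrarySpec".
#' @export
syntheticLibrarySpec <- function(nPerClass = c(omp_barrel = 40L,
                                               all_alpha = 20L,
                                               all_beta_globular = 20L,
                                               alpha_beta = 10L,
                                               helical_membrane = 10L),
                                 nQueriesPerClass = 3L,
                                 noise = 0.02, seed = 1L,
                                 profiles = NULL) {
  if (any(nPerClass < 0)) stop("class counts must be non-negative")
  cls <- names(nPerClass)
  if (is.null(cls) || any(!nzchar(cls)))
    stop("'nPerClass' must be named by class label")
  structure(list(nPerClass = nPerClass,
                 nQueriesPerClass = nQueriesPerClass,
                 noise = noise, seed = as.integer(seed),
                 profiles = profiles),
            class = "SyntheticLibrarySpec")
}

#' Generate a synthetic labeled reference library and query set
#'
#' Draws every entry from its class profile under the spec's seed;
#' \code{omp_barrel} entries are labeled OMP and everything else
#' non-OMP. Each entry also receives an independent random amino-acid
#' sequence so the identity-based homology filter can run (synthetic
#' sequences are unrelated, so the filter passes them; tests construct
#' homologous pairs explicitly with \code{\link{mutateSequence}}). A
#' disjoint held-out query set is drawn from the same profiles.
#'
#' @param spec a \code{\link{syntheticLibrarySpec}}.
#' @return list with \code{library} (a
#'   \linkS4class{ReferenceLibrary}), \code{queries} (named list of
#'   \linkS4class{ElementSequence}) and \code{truth} (data.frame id,
#'   class, label for the queries).
#' @export
generateLibrary <- function(spec = syntheticLibrarySpec()) {
  stopifnot(inherits(spec, "SyntheticLibrarySpec"))
  if (sum(spec$nPerClass[names(spec$nPerClass) == "omp_barrel"]) == 0)
    stop("spec requests zero OMP barrels; library needs both classes")
  if (sum(spec$nPerClass[names(spec$nPerClass) != "omp_barrel"]) == 0)
    stop("spec requests zero decoys; library needs both classes")
  set.seed(spec$seed)
  elements <- list(); labels <- character(0); seqs <- character(0)
  queries <- list(); qID <- character(0); qClass <- character(0)
  for (cls in names(spec$nPerClass)) {
    prof <- spec$profiles[[cls]] %||% topologyProfile(cls)
    lab <- if (cls == "omp_barrel") "OMP" else "non-OMP"
    for (k in seq_len(spec$nPerClass[[cls]])) {
      id <- sprintf("%s_%03d", cls, k)
      s <- generateSSE(prof, id, spec$noise)
      elements[[id]] <- compressSSE(s)
      labels <- c(labels, lab)
      seqs <- c(seqs, randomAASequence(residueLength(s)))
    }
    for (k in seq_len(spec$nQueriesPerClass)) {
      id <- sprintf("query_%s_%03d", cls, k)
      queries[[id]] <- compressSSE(generateSSE(prof, id, spec$noise))
      qID <- c(qID, id)
      qClass <- c(qClass, cls)
    }
  }
  list(library = referenceLibrary(elements, labels, seqs),
       queries = queries,
       truth = data.frame(id = qID, class = qClass,
                          label = ifelse(qClass == "omp_barrel",
                                         "OMP", "non-OMP"),
                          stringsAsFactors = FALSE))
}

#' Write a synthetic library to disk
#'
#' Materializes \code{\link{generateLibrary}} output as the standard
#' manifest layout (library.tsv, sse.fasta, aa.fasta) plus
#' queries.fasta and truth.tsv. Identical specs produce byte-identical
#' files.
#'
#' @param spec a \code{\link{syntheticLibrarySpec}}.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeSyntheticLibrary <- function(spec, dir) {
  sim <- generateLibrary(spec)
  writeLibraryManifest(sim$library, dir)
  writeSSEFasta(lapply(sim$queries, expandElements),
                file.path(dir, "queries.fasta"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
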