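---
title: "Secondary structure element alignment for OMP discrimination: methods and design"
author: "sseaOMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary structure element alignment for OMP discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseaOMP)
```

# The model

β-barrel outer membrane proteins (OMPs) typically thread the membrane
with 8–24 antiparallel strands connected by short turns. Reduced to
three states per residue (H/E/C), this topology is a long, regular
alternation of strand elements and coil linkers — a pattern that
helical bundles, α-helical membrane proteins and even globular all-β
folds (fewer, shorter strands, longer loops) do not reproduce. The
classifier therefore never looks at amino acids at all (except in the
evaluation-time homology filter): its input is the secondary structure
string, predicted (PSIPRED) or derived from structure (DSSP, reduced
to three states).

## Element compression

A string is run-length encoded into *elements* — maximal runs of one
state — keeping each run's residue length:

```{r}
compressSSE("HHHHCCCCCEEEEEHHHH")
```

Compression is exactly invertible (`expandElements`), adjacent
elements always differ in type, and element lengths sum to the residue
length. Empty strings are rejected at construction because the
similarity normalization divides by residue length.

## Alignment and scoring

Two element sequences are aligned by a global dynamic program over
whole elements. Elements are never split; with the default gap cost of
0, skipping an element is free and the recurrence

$$F_{i,j} = \max\big(F_{i-1,j},\; F_{i,j-1},\; F_{i-1,j-1} + S_{i,j}\big)$$

computes the maximum-weight *non-crossing matching* of elements. The
element-pair score is

$$S_{i,j} = w(t_i, t_j)\,\min(L_i, L_j),$$

with default weights $w(t,t)=1$ and $w(t,u)=0$ for $t \ne u$. This is
the simplest form consistent with the constraints that define the
score: it is bounded by the shorter element, symmetric, and gives a
same-type pair full credit for the overlap it could achieve. Because
every pair scores at most $\min(L_i, L_j)$, the total is bounded by
the shorter protein's residue length, and

$$\mathrm{SSEA\_Score} = \frac{\text{total score}}{(L_A + L_B)/2} \in [0, 1],$$

reaching 1 exactly on self-alignment. Two deliberate readings are worth
stating because alternatives exist:

* **Normalization is in residue units**, not element counts: the total
  score is a residue count, so dividing by the mean residue length is
  the only choice that keeps the ratio dimensionless and bounded by 1.
* **Cross-type weights default to 0.** Classical element-alignment
  schemes sometimes give coil partial credit against helix or strand;
  the conservative default avoids rewarding topologically meaningless
  overlap. The weights (and the gap cost) are user-configurable
  (`scoringScheme`, `readSchemeConfig`), so partial-credit variants are
  one config line away.

The DP fill runs in compiled code (`src/ssea_dp.cpp`); the traceback
breaks ties deterministically (diagonal, then row step, then column
step), which fixes the reported element pairs but not the score —
the score is tie-independent, which the test suite verifies against
exhaustive enumeration of all monotone matchings for small inputs.

## Classification

Against a labeled reference library, the query's similarity to every
entry is computed and the two within-class maxima are retained:

$$\mathrm{Pred\_Score} = \mathrm{SSEA\_Score}_{\max,\mathrm{OMP}} -
  \mathrm{SSEA\_Score}_{\max,\mathrm{non\text{-}OMP}},$$

with an OMP call iff $\mathrm{Pred\_Score} > 0$ (strictly: a tie is a
non-OMP call). The difference form keeps the score in $[-1, 1]$ and
makes small positive calibrated thresholds meaningful.
`calibrateThreshold` derives a library-specific cut at a target false
positive rate by leave-one-out over the library, returning the smallest
observed-score threshold meeting the target — the workflow behind
running the classifier at, say, 99% confidence.

# Evaluation protocol

`looEvaluate` holds out each library entry, filters the remainder for
homology against it, classifies, and aggregates Ac/Sn/Sp/MCC plus an
ROC curve. Conventions that needed a decision:

* **Filtering is strict on both cutoffs**: entries survive with global
  identity $< 0.25$ and e-values $> 0.01$. Identity is computed by
  Needleman–Wunsch global alignment (Biostrings; BLOSUM62, gap open
  11 / extend 1 — the common BLAST-like convention) with identity =
  identical columns / alignment length including gaps. The 25% cut is
  sensitive to these conventions, so all of them are exposed as
  arguments.
* **E-value stages are hooks.** Homology-search tools are not bundled;
  the search and profile stages accept any function mapping a
  (test, entry) pair to an e-value, and `evalueHookFromTable` adapts
  the standard 12-column tabular search output. A missing hook skips
  its stage with a message (the identity-only protocol variant); a
  *failing* hook retains the entry with a warning. Failing open means
  a broken hook cannot silently shrink the library, at the price that
  an unfiltered homolog may slip through and flatter the benchmark —
  which is why every such retention is warned about individually.
* **Unpredictable cases.** If filtering empties one class for some
  test protein, the two-maximum rule is undefined. Such a protein is
  recorded as a non-OMP call with prediction score $-1$ (the minimum
  attainable) and flagged `unpredictable` in the report. This is a
  package choice, made conservative for sensitivity, and visible
  rather than silent.
* **MCC with a zero denominator is 0**, the standard convention for
  degenerate confusion matrices.
* **ROC** sweeps all distinct scores with the same strict `>` rule as
  the classifier; AUC is the trapezoidal area, which under this sweep
  equals the normalized Mann–Whitney statistic (ties counted half) —
  the test suite checks that identity on random inputs.

# The synthetic generator

`generateLibrary` emulates the topological contrast the method
exploits, so every stage is testable offline. Each class profile draws
a number of core elements, their lengths, coil linkers and terminal
coils uniformly from ranges:

| class | core | count | element length | linkers |
|---|---|---|---|---|
| omp_barrel | E | 8–24 | 6–14 | 2–10 |
| all_beta_globular | E | 4–12 | 3–8 | 5–15 |
| all_alpha | H | 4–12 | 8–20 | 2–10 |
| alpha_beta | H/E alternating | 6–14 | 4–12 | 3–10 |
| helical_membrane | H | 6–12 | 17–25 | 3–15 |

The barrel count range is the defining OMP property; the remaining
ranges are fixture choices picked once to preserve the qualitative
contrasts (globular strands are fewer and shorter with longer loops;
transmembrane helices are long). Uniform lengths are the simplest
distribution that preserves the contrast; real element-length
distributions are neither uniform nor independent. Noise flips each
residue independently to another state (default 2% in the standard
spec of 40 barrels vs 60 decoys, seed-determined end to end).
Amino-acid sequences attached to synthetic entries are uniform random
20-letter strings — unrelated by construction — with
`mutateSequence` available to build homologous pairs at controlled
identity for filter tests.

What passing tests on this fixture do **not** show: performance on
real proteins. Real secondary-structure predictions have structured,
correlated errors (not i.i.d. flips), real strand statistics differ
from uniform draws, and real libraries contain homology structure that
the random sequences lack. The fixture demonstrates that the machinery
is correct and that the topological signal, when present, is
recovered; calibration on real reference data is the user's task.

# Numerical choices and problem sizes

* Scores are kept at full double precision; rounding to 3 decimals
  happens only in CLI display output.
* Traceback comparisons use an absolute tolerance of $10^{-9}$ on DP
  cell equalities; with the default integer-weight scheme the
  comparisons are exact.
* The test suite uses 1000 random string pairs (5–500 residues) for
  the score-bound checks, 500 random element-sequence pairs of up to
  8 elements for the enumeration oracle (the exhaustive matcher is
  exponential, so inputs stay small), and the 100-entry standard
  synthetic library for end-to-end leave-one-out runs — sizes at
  which the full suite completes in about a minute.
* Heavily mutated sequence copies can measure a higher global identity
  than their construction target because the aligner recruits
  gap-induced identities; boundary tests therefore verify measured
  identities around the 25% cut rather than assuming the target.

# Limitations

* No secondary-structure prediction of its own: PSIPRED/DSSP output is
  consumed, never generated, and prediction quality bounds classifier
  quality.
* The element-alignment variant that splits elements (helix/strand
  against multiple coils) is intentionally excluded; whole elements
  only.
* Homology search tools are not bundled; without hooks the e-value
  filter stages are skipped, which reproduces only the identity-based
  variant of the stringent protocol.
* Nearest-neighbour classification inherits its library: an OMP family
  with no topologically similar library entry will be missed, and the
  shipped synthetic library is a test fixture, not a curated reference
  set.
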