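---
title: "Classifying Clp/Hsp100 unfoldase paralogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Clp/Hsp100 unfoldase paralogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClpTyper)
```

# The problem

Double-ringed Clp/Hsp100 unfoldases share a common body plan — an
N-terminal domain (NTD), two AAA+ ATPase modules (D1, D2) with Walker A/B
motifs, a helical M-domain inserted in D1 — yet split into functionally
distinct classes. In Actinomycetota, ClpB (disaggregase) and ClpC
(ClpP1P2 protease partner) are joined by a third class, ClpI, recognizable
by overall sequence similarity intermediate between the two canonical
classes and by a mosaic of their diagnostic features: a short ClpC-like
M-domain, a variable ClpB-like NTD, and an LGF peptidase-docking motif
present in one sub-lineage (ClpIa) and absent in the other (ClpIb).
ClpTyper packages the sequence-only workflow that separates these classes:
reference bit-score partitioning, feature annotation, profile-based
conservation comparison, taxonomic binning, and bootstrap phylogenetics.

# Reference bit-score partitioning

Each query is aligned to a ClpC-type and a ClpB-type reference by exact
Smith–Waterman local alignment under affine gaps (a gap of length $L$
costs $o + e(L-1)$), and the raw optimum $S$ is rescaled to bits,
$$S' = \frac{\lambda S - \ln K}{\ln 2}.$$

Defaults are the published gapped-BLAST protein settings: BLOSUM62,
$o = 11$, $e = 1$, $\lambda = 0.267$, $K = 0.041$. Absolute bit values
need not match any particular search engine — the classification consumes
scores only through their two-dimensional geometry, which is insensitive
to the monotone rescaling. Ambiguous residues (B, Z, U, O, J) are mapped
to X on input and score 0 against everything, so they carry no signal in
any scoring path.

Class assignment supports two modes:

* **Explicit gates** — closed rectangles in the
  (score-vs-ClpC, score-vs-ClpB) plane, validated to be mutually
  non-overlapping, with boundary points belonging to the gate. This mirrors
  drawing cluster boxes on a scatter plot, made reproducible as config
  values.
* **Relative rule** (`autoAssignClasses`) — the documented automatic
  stand-in for manual boxes: a sequence whose two scores both exceed a
  floor (default 50 bits) and differ by less than 10 % relative
  (`|S'_C - S'_B| / max < 0.1`) lies on the equal-similarity diagonal and
  is called ClpI; otherwise the larger score decides ClpB vs ClpC. The 10 %
  width is deliberately narrow: in synthetic cohorts the ClpB/ClpC
  off-diagonal clusters sit at 55–60 % relative difference, so the rule
  tolerates a wide band of intermediate geometries before misassigning.

PCA (`pcaEmbed`, 10 components by default) acts as an independent check on
the clustering; its feature vector is the vector of bit-scores against a
reference panel (the two class references plus up to eight panel sequences
drawn evenly from the input), so the embedding uses only machinery already
in the package.

# Feature annotation

Walker A is matched as `G..G.GK[ST]`, Walker B as `[ILVFM][ILVFM]..DE`,
and "LGF-like" motifs as `[LIVMF]G[FLY]` — the last being this package's
concrete reading of "Leu-Gly-Phe or similar", configurable as a pattern
string.

Region-level features are measured by projecting an annotated reference
coordinate frame (`RegionMap`: NTD, D1, M-domain nested in D1, D2,
LGF-loop within D2) through the local alignment. A region's query span
runs **between its flanking aligned anchor columns**, so insertions are
counted wherever the aligner placed the gap. One measurement deserves
emphasis: the M-domain length is inferred as the excess of the mapped D1
span over the reference's D1 core length
(`width(D1) - width(M_domain)` on the reference). The AAA+ core is
fixed-length across classes while the M-domain absorbs the length
variation, so this is robust; direct projection of a ~20 aa reference
M interval is not, because ~0.5-per-residue BLOSUM62 mismatch costs are
cheaper than 1-per-residue gap extension and unrelated M-domain residues
therefore align as mismatches into flanking core columns, eroding the
direct estimate by tens of residues.

The decision rule (`classifyByFeatures`) is: M-domain ≥ 60 aa → ClpB
(midway between the ~20 aa and ~90 aa class archetypes); else LGF motif
plus an NTD whose mapped length is within ±10 % of the reference NTD →
ClpC; else LGF motif → ClpIa; else ClpIb. The NTD test uses mapped-length
agreement rather than sequence identity because the ClpC NTD is
fixed-length and strongly conserved while ClpI NTDs vary in both length
and composition. The LGF search window is the mapped loop region padded by
3 residues on each side to absorb alignment slop. Regions that fall
outside the aligned span are reported absent, never guessed; queries
aligning below a 50-bit floor are refused as unalignable to the reference
frame.

# Profile conservation and cross-alignment

For every alignment column, a 20-member frequency profile
$P = (f_1, \dots, f_{20})$ is computed over the unambiguous, non-gap
residues and renormalized to sum to one. Gap handling had to be decided
here (the convention is not forced by the mathematics): gaps and X are
excluded from the counts, and an all-gap column carries a defined zero
profile that downstream consumers render as background.

Positional and cross-alignment scores are the BLOSUM-weighted expectations
$$S_x = \sum_y B(x,y)\,P(y), \qquad
  S_\mathrm{cross} = \sum_{x,y} B(x,y)\,P_t(x)\,P_b(y).$$

Two profiled alignments are merged by global dynamic programming over
columns with $S_\mathrm{cross}$ as the match score and a linear per-column
gap penalty, default 4 — the magnitude of the most negative BLOSUM62
entry, which keeps gap costs on the score scale. Traceback ties prefer the
diagonal, so self-comparison returns the identity correspondence. At
merged columns where exactly one side is gapped, $S_\mathrm{cross}$ is
reported as `NA`, not zero: heat strips must distinguish "no data" from
"dissimilar". Bitmaps clip scores to the BLOSUM62 extremes $[-4, 11]$ on a
diverging blue (conserved) to red (variable) scale.

# Phylogeny

Tree building follows the canonical distance recipe: subsample up to 5
sequences per taxonomic order (per class, when labels are supplied),
p-distance over mutually ungapped columns, neighbor-joining (exact on
additive matrices), and column bootstrap. Supports are the percentage of
replicate trees containing each internal bipartition of the full-data
tree; 100 replicates by default. Resampling is seeded on column indices
only, so supports are invariant to taxon input order. Clades with support
**strictly greater than 50 %** are called confirmed subgroups. Monophyly
is evaluated in the unrooted sense (bipartition test), and the
ClpIa/ClpIb signature is scored as: the combined ClpI tips form one side
of a bipartition, and the ClpIa and ClpIb tip sets are each confirmed
subgroups within it.

# The synthetic generator

`defaultTemplates()` encodes the class architecture as concrete sequences
on a fixed master coordinate frame (blocks NTD / D1a / M / D1b / D2a /
LGF / D2b of widths 190/110/100/100/95/12/93; D1 spans 230 aa, D2 200 aa,
the ClpC NTD 145 aa). Class-contrastive facts are hard constraints:

| feature | ClpB | ClpC | ClpIa | ClpIb |
|---|---|---|---|---|
| M-domain | 90 aa | 20 aa | 20 aa | 20–26 aa (tolerated inserts) |
| LGF loop | none (8 aa linker) | 12 aa with LGF | 12 aa with LGF | 5 aa, no motif |
| NTD | 150 aa, variable (rate 0.22) | 145 aa, fixed, conserved (0.02) | 175 aa, variable (0.18) | 175 aa, variable (0.18) |
| core rate (per seq) | 0.04 | 0.04 | 0.04 | 0.04 |

The D1/D2 cores descend from one ancestor: ClpB and ClpC each diverge at
rate 0.18, and the ClpI ancestor is built as a **balanced mosaic** of the
ClpB and ClpC cores (alternating between them at the sites where they
differ) plus 0.08 of its own divergence, with ClpIa and ClpIb adding 0.06
each from the common ClpI ancestor. The mosaic construction is the
package's way of making "moderate but approximately equal similarity to
both references" — the defining property of the ClpI cluster — true by
construction rather than by luck of a random draw; with ~400 core
positions, the residual score asymmetry is a few percent, well inside the
10 % diagonal band. Walker A/B motifs and LGF motifs are planted at fixed
positions and protected from mutation at every level, as are three guard
residues flanking the LGF block (so the motif-detection window is never
corrupted by core mutations).

Point substitutions follow a BLOSUM62-biased proposal
($P(y \mid x) \propto e^{B(x,y)/T}$, $T = 2$, $y \neq x$), so synthetic
divergence prefers conservative exchanges and the resulting bit-score
geometry resembles real protein families rather than uniform noise.
Indels are modelled as *occupancy-variable positions*: designated columns
of a deliberately wide template are deleted independently per sequence
(probability 0.35). This emulates tolerated indels (ClpB/ClpI NTDs, the
ClpIb M-domain) while keeping the ground-truth MSA exact and
deterministic — the price is that the generator never creates novel
insertion columns beyond the master frame. Per-order rate jitter
(±15 % on the divergence scale) coarsely emulates lineage effects. All
randomness flows from the single cohort seed; outputs are byte-identical
under it.

Default cohort conditions: four orders × (22 ClpB, 20 ClpC, 5 ClpIa,
3 ClpIb) = 200 sequences, matching the ~44/40/11/4 % class proportions of
the real Actinomycetota cohort.

**What passing tests do and do not show.** The generator reproduces the
class-contrastive architecture, realistic substitution structure, and
order-level bookkeeping, so recovery results demonstrate that the
pipeline's logic is correct and its thresholds coherent. It does not
reproduce genuine phylogenetic covariance within classes (sequences are
i.i.d. around class templates), multi-modal within-class score structure,
NTD-less ClpB sequences (~10 % in real data), or annotation artifacts
such as mis-annotated start sites — so quantitative accuracies on
synthetic cohorts are upper bounds, not field estimates.

# Numerical choices and degenerate inputs

* Local alignments floor at the empty alignment (raw 0); the bit
  conversion then gives $-\ln K / \ln 2 \approx 4.6$ bits.
* Traceback determinism for pairwise alignment is delegated to the
  underlying exact DP implementation; raw optima are checked against an
  independent chain-enumeration oracle in the tests.
* Percentage rows round half-up to one decimal (so 6.25 % prints 6.3),
  matching the convention of published occurrence tables.
* Duplicate ids, ragged alignments, gap characters in unaligned input,
  conflicting taxonomy rows, empty cohorts, sub-3-taxon distance
  matrices, and pairs with no comparable columns are all hard errors that
  name the offender.
* Problem sizes used by the test suite and the acceptance script — a
  200-sequence study cohort, 40-taxon trees with 100 bootstrap
  replicates, 10 seeded phylogeny repetitions, 200-instance oracle
  batches at length ≤ 5 — were chosen to exercise every code path at
  desk scale; all scale linearly upward via the config objects.

# Known limitations

* Exact DP pairwise scoring is quadratic; the package is meant for
  curated cohorts (hundreds to a few thousand sequences), not database
  search — there are deliberately no seeding heuristics or E-values.
* The profile–profile aligner uses a linear column gap penalty; affine
  column gaps would marginally change merged correspondences in long
  all-gap runs.
* Gate and feature thresholds (50-bit floor, 10 % diagonal, 60 aa
  M-domain cutoff, ±10 % NTD tolerance) are defaults tuned to the
  class-contrastive geometry described above; cohorts from other phyla
  (e.g. proteobacterial ClpA/ClpB/ClpV) should revisit them via the
  exposed parameters.
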