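---
title: "Mining disordered sequence patterns from clustered protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disordered sequence patterns from clustered protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrlib)
```

## The problem

Intrinsically disordered regions (IDRs) lack a fixed three-dimensional
structure.  In x-ray crystallography they leave no interpretable electron
density, so the residues of the declared chain sequence that are absent from
the deposited coordinates are a direct, large-scale experimental readout of
disorder.  idrlib turns a collection of x-ray structures into a library of
short sequence patterns whose occurrences are predominantly disordered —
patterns that can then be used to flag likely-disordered segments in any
protein sequence.

Two obstacles shape the whole design:

1. **Redundancy.**  Structure databases contain the same protein many times
   over.  Any statistic computed per chain would be dominated by
   heavily-deposited proteins, so all disorder statistics here are weighted
   through a nested cluster hierarchy.
2. **Expression artifacts.**  Purification tags (above all the histidine
   tag) are artificial, almost always unresolved, and would otherwise
   masquerade as natural disordered patterns; the library therefore carries
   a tag-proximity annotation per pattern.

## Disorder annotation

`parse_entry()` reads PDB-format text.  The full sequence of a chain comes
from its SEQRES records; a residue is **U** (unstructured) exactly when it
has no resolved coordinates — listed under REMARK 465 or absent from the
ATOM records — and **S** otherwise.  Residues with at least one resolved
atom count as structured; modified residues are mapped to their parent
amino acid via MODRES when possible, else to the unknown letter X, which
never matches a non-X pattern position.  When ATOM + REMARK 465 residue
numbering does not reconcile with the SEQRES length, the parser warns and
falls back to assuming numbering 1..L; real depositions with exotic
numbering schemes may need curation upstream, which is a known limitation.

`filter_chains()` applies the quality gate: x-ray entries only, resolution
at most 3.0 Å (inclusive — "better than 3 Å"), chain length at least 40
residues (inclusive).  Shorter chains and non-diffraction methods carry too
little or differently-defined disorder signal.

## The identity measure and the cluster hierarchy

Pairwise identity between chains is

$$Id = \frac{I}{L_1 + L_2 - I} \times 100\%$$

with $I$ the number of identical aligned residue pairs in the optimal local
alignment (BLOSUM62, gap open 11, gap extension 1 — the defaults of the
standard protein local-alignment search) and $L_1, L_2$ the full chain
lengths.  This union-style denominator penalises length mismatch: a perfect
5-residue fragment inside a 10-residue chain scores 50%, not 100%.  Because
co-optimal tracebacks can differ in identity count, the two sequences are
aligned in a fixed canonical order, making the measure exactly symmetric
and deterministic.

`build_clusters()` produces the nested hierarchy C100 ⊇ C75 ⊇ C50 ⊇ C25 ⊇
C5: C100 groups byte-identical sequences; each coarser level merges
clusters by **single linkage** (any cross-cluster pair at or above the
threshold merges, transitively, to a fixed point — connected components of
the thresholded identity graph).  Single linkage is the natural reading of
"clusters were combined" level by level, and it makes nesting automatic;
other linkages (complete, average) would not nest without extra machinery.
This is a deliberate, documented choice, as is comparing **all pairs**
rather than cluster representatives; a representative-based shortcut would
be faster but changes results near thresholds, so the exact mode is the
tested contract.

## Two-level weighted statistics

All disorder statistics use the same weighting (`two_level_average()`):
counts are first averaged over the chains of each C100 sub-cluster, then
averaged over the C100 sub-clusters of a C75 cluster.  Each C75 cluster
thus contributes a single unit of evidence no matter how many times its
member proteins were deposited.  For example, per-chain
(unstructured, structured) counts

```{r}
cluster <- list(rbind(c(23, 8), c(24, 7), c(31, 0), c(31, 0)),
                rbind(c(8, 0), c(6, 2)))
two_level_average(cluster)
```

give sub-cluster means (27.25, 3.75) and (7, 1) and the cluster value
(17.125, 2.375).  Values are kept exact internally; rounding happens only
at output.  The package's output convention is `round_half_up()` (ties away
from zero, the convention of most tabulation software); note that at two
decimals the pair above prints as (17.13, 2.38).

Positional statistics (`positional_disorder_frequencies()`) split each
chain into N-terminal, middle and C-terminal regions.  The region rule is a
design decision: the maximal disordered run touching residue 1 is the
N-terminal region, the maximal disordered run touching residue L the
C-terminal region, everything else (including all structured residues) is
middle.  Terminal missing density is overwhelmingly what "disordered ends"
means in crystal structures, so tying the region to the terminal U-run
itself, rather than to a fixed window, keeps the statistic sharp; a fully
disordered chain is assigned N-terminal as a whole (deterministic
tie-break).  All residues carry weight 1 — no reduced weight for terminal
matches is applied anywhere.

## Low-complexity segments: AC2 and homo-repeats

An **AC2 segment** uses exactly two amino-acid types (`GSGSGSGSGSSG`).
`find_ac2_runs()` reports all maximal such segments of length ≥
`min_length` (default 8 — the shortest length at which these segments are
predominantly disordered, and the basis length of the library); overlapping
maximal segments with different pairs are all reported, and X breaks
segments.  Re-encoding a segment over {0, 1} (first-seen type → 0) gives
its binary template, classified by `classify_ac2()` into:

* `homo_adjacent` — one symbol occurs exactly once, at a terminus;
* `internal_repeat` — the template satisfies `t[i] == t[i+p]` for period
  p = 2 or 4 (whole or truncated repeats of a 2- or 4-letter word);
* `other` — everything else, including period-3 templates such as
  `00100100`, which are deliberately excluded from the repeat class.

The null probability that a random length-L sequence uses exactly two types
is the inclusion–exclusion sum over unordered pairs

$$P_{AC2}(L) = \sum_{i<j}\left((p_i+p_j)^L - p_i^L - p_j^L\right),$$

which collapses to $190\,(0.1^L - 2\cdot 0.05^L)$ for uniform frequencies
(`prob_ac2_uniform()`; about 2·10⁻⁶ at L = 8).  Both forms are verified in
the tests against exhaustive enumeration on small alphabets.

## Candidate patterns, homologues and X-masking

`extract_candidates()` walks each C100 cluster (whose chains share one
sequence) and computes the per-position disorder fraction across member
chains.  Maximal stretches with fraction ≥ 0.5 — "disordered in half the
cases", inclusive — and length ≥ 3 become candidates; duplicates are
dropped keeping the first occurrence.  The minimum length 3 is the floor of
the shortest homologue band; candidate length is otherwise unlimited.

Near-identical candidates are merged by X-masking.  The substitution
budget keeps homologues above 80% identity: none for lengths 3–5, one for
6–10, two for 11–15, i.e. `ceiling(L/5) - 1` (`allowed_substitutions()`).
Homologues are searched **among the candidate fragments themselves**
(equal length, Hamming distance within budget) — a documented design
choice; scanning every sequence window for homologues is possible but not
the default contract.  For each homologue, `synthesize_xpatterns()` puts X
at the diverging positions, then closes the set of X-position sets under
pairwise union so that homologues diverging in different positions also
yield the joint template.  The full closure is generated (for three
divergence sets that is up to 2³ patterns); synthesis happens once, up
front, not again during selection.

## Scoring and greedy selection

`pattern_stats()` scores one pattern: within each C75 cluster, per-chain
counts of covered U and S residues are averaged the two-level way (chains
without a match contribute zero to their sub-cluster mean; residues claimed
by previously selected patterns are skipped).  Covered means **every**
position under a match, X positions included — a pattern claims the whole
segment it identifies.  Summing per-cluster means over all clusters with at
least one match gives $N_u$ and $N_f$; $C_u$/$C_f$ count matched clusters
with majority-disordered means ($N_u > N_f$ per cluster) and the rest; the
selection score is $D = N_u - N_f$.

`greedy_select()` iterates: keep candidates passing
**C1** $C_u \ge 5$, **C2** $C_u > C_f$, **C3** $N_u > N_f$;
select the maximal-D candidate (ties: greater effective length, then
lexicographically smaller — fully deterministic); mark all residues covered
by its matches as consumed; rescore and repeat until nothing passes.  The
returned library keeps selections with $D \ge 25$, the weight of five fully
disordered five-residue occurrences in five clusters.  Homo-repeat and
AC2-like candidates (at most two distinct non-X letters) are removed before
selection — they belong to the library's separate low-complexity sets.

`histag_proximity()` annotates each pattern with the percentage PC of its
occurrences lying within 40 residues of a histidine run of length ≥ 4,
binned as PC = 0, 0 < PC < 33, 33 ≤ PC ≤ 67, 67 < PC < 100, PC = 100.  The
boundary is exclusive: a separation of exactly 40 residues is "far".

## Null models

`expected_count()` gives the expected occurrences of a pattern in a corpus
of $n_{res}$ residues: $n_{res}(1/20)^L$ with $L$ the effective (non-X)
length, or the product of per-letter frequencies in frequency mode (the two
agree exactly under uniform frequencies).  For a 6.3·10⁸-residue corpus
this is about 200 occurrences at effective length 5 and about 10 at
length 6.  `random_proteome()` draws sequences of prescribed lengths from a
frequency vector with R's Mersenne-Twister under an explicit seed;
overlapping occurrences are counted (a documented choice — the closed-form
expectations count positions, which overlap too).

## What the synthetic generator emulates — and what it does not

The fixtures module generates three kinds of ground-truthed data:

* `make_pdb_fixture()` — toy PDB entries (CA-only ATOM records, REMARK 465
  lines) whose parse recovers a prescribed U/S mask exactly.  One resolved
  atom is all the disorder rule needs, so side-chain geometry is not
  emulated.
* `make_family()` — mutated copies of a base sequence with disjoint
  interior substitution sets, sized so each pair sits within about 3
  points of a target identity (with disjoint sets of size k,
  $Id = (L-2k)/(L+2k) \times 100$).
* `plant_motifs()` — chains with structured random backgrounds and planted
  motifs, disordered on demand, in a prescribed number of clusters, with a
  placement truth table.

Test problem sizes are deliberately small — tens to a couple of hundred
chains, motifs of 5–7 residues in 5–7 clusters, random proteomes of order
10⁵ residues — chosen so the whole suite exercises every code path in
seconds while keeping every expected value derivable by an independent
oracle (brute-force closure, window enumeration, naive counts).  Passing
these tests shows the machinery is correct, not that fixture-scale
statistics transfer to a full structure database: real data add
version-dependent composition, conflicting depositions of the same
crystal form, non-trivial residue numbering, and low-complexity sequence
far above the random baseline.  Absolute pattern counts therefore depend on
the database snapshot and are out of scope; the contracts tested here are
the formulas, the invariants (nesting, maximality, determinism,
consumption-disjointness) and recovery of planted signal.

## Numerical choices and degenerate inputs

* Fractional counts are kept as doubles throughout; rounding only at
  output via `round_half_up()`.
* Empty inputs: an empty candidate list, motif list or chain table flows
  through to empty (but well-formed) outputs; an empty sequence is an
  error.
* A pattern with zero occurrences has undefined PC, reported as
  `not_applicable` rather than 0.
* A fully disordered chain is one degenerate case of the region rule
  (assigned N-terminal); a chain with coordinates but no SEQRES is
  another (reconstructed, all S, with a warning).
* All cluster ids are renumbered by first occurrence, so equal inputs give
  byte-identical outputs everywhere.

## Limitations

* mmCIF is not parsed; PDB-format fixed columns only.
* Disorder is binary (U/S); B-factor-based or ensemble definitions of
  disorder are out of scope.
* The all-pairs identity computation is quadratic in the number of unique
  sequences; the intended scale is curated subsets and synthetic studies,
  not a full-database run in one R session.
* Candidate homologue search is restricted to the candidate pool by
  default (see above).
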