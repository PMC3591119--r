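---
title: "Methods: deep superposition search and alignment quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep superposition search and alignment quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepalign)
```

## The problem

A pairwise protein structure alignment has two coupled unknowns: a rigid
*superposition* (rotation plus translation placing one chain onto the
other) and an *alignment* (a sequential, one-to-one residue
correspondence computed on top of it). Practical aligners explore only a
small, heuristically chosen set of superpositions, computing an optimal
correspondence for each; how much alignment quality is lost to that
restricted search is an empirical question. `deepalign` makes the
question measurable on any chain pair: it implements three classical
heuristics (STRUCTAL-style iterative DP, TM-align-style affine-gap
scoring, LOCK2-style mutual-nearest-neighbour alignment), a much deeper
search of superposition space driven by a simple objective — the largest
number of residue pairs that fit under a distance cutoff `d` (the
"CA &le; d" measure) — and the standard battery of quality metrics, so
the heuristic-vs-deep-search gap can be quantified for both passes of a
two-step protocol:

1. each heuristic is run from its own seed superpositions;
2. the deep search supplies a (near-)optimal superposition for the
   CA &le; d measure, and each heuristic's *alignment step* is re-run on
   it.

All inputs are C-alpha traces (`structure3d`): everything here operates
on backbone geometry only.

## Scoring models

For aligned subchains with paired coordinates, the coordinate RMS is

$$\mathrm{cRMS} = \sqrt{\tfrac1k \sum_{r=1}^{k} \lVert a_{i_r} - \hat b_{j_r}\rVert^2}.$$

Three residue-pair score matrices are built from the inter-structure
distances $d_{ij}$ under the current superposition:

* **STRUCTAL**: $S(i,j) = 20 / (1 + d_{ij}^2/5)$, used with a linear gap
  penalty of 10 per skipped position;
* **TM-align**: $S(i,j) = 1 / (1 + (d_{ij}/d_0)^2)$ with the
  length-dependent scale $d_0 = 1.24\,(L-15)^{1/3} - 1.8$ (`L` the
  shorter length), used with affine penalties 0.6 (gap opening) and 0.0
  (gap extension);
* **threshold**: $S(i,j) = 1$ if $d_{ij} \le d$ and "never match"
  otherwise, with zero gap cost — its DP optimum is the maximum number
  of sequentially matchable pairs under `d` for that superposition.

`d0` is floored at 0.5 &Aring;: the raw formula is non-positive for
`L` &le; 18 and below 0.5 up to `L` = 21, and a non-positive scale would
make the score matrix meaningless on short chains. Chains that short are
outside the intended use of the scale, but the library must not crash on
them.

### Gap conventions

The classical zero-boundary recurrence
$D(i,j) = \max\{D(i-1,j-1)+S(i,j),\ D(i-1,j)-g,\ D(i,j-1)-g\}$ with
$D(i,0)=D(0,j)=0$ treats the two chain ends asymmetrically: leading
unmatched residues are free, trailing ones are charged. `dp_linear()`
therefore defaults to a symmetric semi-global formulation — end gaps
free at both ends, `g` charged per skipped position *strictly inside*
the aligned span — which is the convention classical structure aligners
actually use, and the only one under which the DP's reported score
equals `structal_total_score()` recomputed on its own output. The
literal recurrence remains available (`free_ends = FALSE`), and
`structal_total_score()` exposes the per-position vs per-run gap-count
ambiguity as an explicit `gap_count` switch (default `"positions"`,
consistent with the recurrence).

The free-end DP is implemented as a two-state match/gap recurrence with
a restart option rather than a plain zero-boundary table: with signed
score entries the plain table cannot represent an alignment that skips a
prefix of *both* chains for free, whereas the optimum over monotone pair
subsets (the semantics the exhaustive oracle scores) requires it. The
affine version (Gotoh, three states) charges `open + (g-1) * extend`
for an interior run of `g` skipped positions.

All tracebacks break ties in a fixed order (diagonal, then vertical,
then horizontal; match state before gap states), so every output is
bit-reproducible.

## The aligners

**STRUCTAL-style** (`structal_align`): from each seed superposition,
alternate score-matrix construction, linear-gap DP (gap 10), and
least-squares superposition on the aligned pairs until the pair list
repeats. A cycle guard hashes the pair list; the iteration cap is 100
(the original publications state no convergence rule). The same gap
constant 10 is used inside the loop and in the final total score. The
best seed by final total score wins.

**TM-align-style** (`tmscore_align`): builds the TM-align matrix and
runs affine-gap DP on a *given* superposition without re-estimating it —
matching the second-pass protocol, where the alignment step is run on an
externally supplied superposition. For use as a stand-alone first-pass
aligner, `refine = TRUE` iterates alignment and re-superposition from a
seed exactly like the STRUCTAL loop.

**LOCK2-style** (`lock2_refine` + `lock2_final_alignment`): refinement
alternates collecting mutual-nearest-neighbour pairs within 3 &Aring;
with least-squares superposition on them; the final alignment keeps the
maximum-cardinality subset of the mutual-NN pairs that is strictly
increasing in both indices. "Colinearity" is interpreted purely as this
sequential-order consistency (crossing matches violate it); geometric
collinearity of vectors is not involved. The subset is found by a
longest-increasing-subsequence DP with ties broken by smaller total
distance; equidistant nearest neighbours resolve to the lower index.
The published LOCK2 initializes from secondary-structure-element
vectors; that requires an SSE assignment and is out of scope here, so
all aligners share the same fragment-seed initialization (below), which
also keeps the three methods comparable.

**Seeding** (`seed_superpositions`): all pairs of length-`k` fragments
(default `k` = 8, stride 4) are least-squares superposed; transforms
within 5&deg; rotation *and* 2 &Aring; translation of a kept one are
deduplicated. This stands in for each published method's own
(unpublished) initial-superposition heuristics and is shared by all
three so that first-pass differences reflect the scoring schemes, not
the seeds.

Degenerate superposition inputs (fewer than 3 points, collinear or
coincident points) return a best-effort transform plus a `degenerate`
flag instead of failing, because the iterative loops may transiently
produce tiny pairings. The solver is Kabsch (SVD with determinant sign
correction); Horn's quaternion method is provided as an independent
route and the two are cross-checked in the tests, alongside a
rotation-grid oracle that scans SO(3) directly (a global 8&deg;
zyz-Euler grid with ten nested four-fold local refinements) and shares
no algebra with either solver.

## The deep search

`maxpairs_search()` maximizes the CA &le; d count by seed-and-refine:
fragment seeds at several lengths (default 6 and 12; for chains of
&le; 15 residues, lengths 3-4 at stride 1 are added, since long
fragments cannot cover a tiny superposition space), each refined by
alternating the threshold DP with least-squares superposition on the
matched pairs to a fixed point; the best seeds (default 8) are then
*annealed* — refined at the relaxed cutoff `d + epsilon` and tightened
back to `d` — which lets the search escape fixed points whose matched
set is too sparse. Ties between equal-count transforms go to the lower
cRMS of the matched set (the geometrically tighter certificate). The
search is fully deterministic given its parameters; `rng_seed` exists
only for optional randomized restarts and is not consumed by the
default configuration.

Defaults follow the study conditions `d` = 3 &Aring; and `epsilon` = 1
&Aring;. The search is a documented reconstruction of a deep
superposition scan — the reference enumeration algorithm with the
polynomial-time guarantee is published separately and its superposition
subset is not specified at this level of detail — so its quality is
validated empirically, at toy scale, against an exhaustive oracle:

`grid_oracle()` scans a zyz-Euler rotation grid crossed with a cubic
translation grid over the padded displacement bounding box, scoring
every superposition with the threshold DP (chains capped at 12 residues;
the cost is cubic in each grid). Because the grid is discrete, its
guarantee is expressed through a computed worst-case displacement bound
$\delta = 2\sin(1.5\,s/2)\,r_{\max} + \tfrac{\sqrt3}{2}\,t$ (rotation
step $s$, translation step $t$, $r_{\max}$ the moving chain's radius
about its centroid): the best grid count at cutoff `d` + &delta; is at
least the true optimum at `d`. Tests sandwich the deep search between
the grid's feasible best at `d` and that upper certificate.

## Quality metrics

For an alignment of `Nmat` pairs on chains of lengths `L(a)`, `L(b)`:

* `NumPairs(d)` — aligned pairs within `d` after superposition
  (method-specific; never exceeds the alignment-independent
  `pairs_under()` ceiling at the same transform);
* `SI = cRMS * min(L(a), L(b)) / Nmat` (lower is better; undefined, and
  reported absent, for empty alignments);
* `PSI(d) = NumPairs(d) / min(L(a), L(b))` in [0, 1];
* shift agreement `I_s / L_ref` against a reference alignment: the
  fraction of reference pairs whose `a`-residue the test alignment maps
  within `s` positions (on the `b` index) of the reference partner.
  Shifts are measured on the `b` side for test pairs whose `a`-residue
  occurs in the reference; other test pairs never count — the only
  reading under which the zero-shift value is the standard "percentage
  of correctly aligned residue pairs". The `a`-to-`b` direction is used
  throughout and documented rather than symmetrized.

Benchmark aggregates are arithmetic means over pairs (per method, pass
and metric), not pooled counts; failed pairs are excluded pairwise with
their counts reported.

## Synthetic fixtures

`make_chain()` produces protein-like C-alpha chains: ideal alpha-helix
geometry (rise 1.5 &Aring;, 100&deg; per residue, radius 2.3 &Aring;),
a persistent self-avoiding walk with fixed 3.8 &Aring; steps and a
3.5 &Aring; clash distance (rejection sampling; the persistence bias
keeps rejection rates low, mimicking real backbone continuity), or a
helix-walk hybrid. `make_pair()` derives a partner chain by deleting an
indel pattern, replacing the trailing `1 - f` fraction of residues with
decoy walk geometry (a contiguous terminal block, as in partially
shared domains), applying a planted rigid transform and adding
Gaussian coordinate noise.

The noise vector of each atom is radially truncated at `3 * sigma`
(resampled). Untruncated Gaussian noise exceeds that radius about 2.9%
of the time, which would make the fixture certificate — *applying the
planted transform places at least `f * n` pairs under
`max(3 sigma, 0.5)` &Aring;* — a probabilistic statement; truncation
makes it a deterministic guarantee, at the cost of a slightly
lighter-tailed error model. Every recovery test compares against this
certificate, never against an unproven optimum.

What the fixtures do *not* emulate: amino-acid-dependent local geometry,
Ramachandran statistics, secondary-structure annotations (so the
LOCK2-style aligner runs without its native SSE initialization on real
data too), side chains, and the long-range contact order of real folds.
Passing recovery tests therefore demonstrates correctness of the search
and scoring machinery under controlled rigid-motion-plus-noise
conditions, not benchmark-level accuracy on curated structure pairs;
the real-structure checks require user-supplied PDB files (see the
README).

## Numerical choices and problem sizes

* Tie-breaks: fixed traceback order (diagonal &gt; vertical &gt;
  horizontal), lower-index nearest neighbours, lower-cRMS transform
  ties, stable seed ordering — identical inputs reproduce every number
  bit for bit.
* Rotations are validated orthonormal with determinant +1 to 1e-8;
  reflections from the SVD are sign-corrected.
* Reference alignments are stored 0-based on disk (two whitespace
  columns, strictly increasing) and 1-based in memory; alignment
  indices always refer to residue order in the file, never to author
  residue numbering.
* Test and acceptance problem sizes were chosen once as the smallest
  that exercise each claim convincingly: 5x6 instances for exhaustive
  DP enumeration (all 462 monotone alignments), point sets of 4-6 for
  the superposition oracle, 80-residue chains with 60% overlap and
  0.5 &Aring; noise for recovery, chains of at most 6 residues for the
  superposition-space grid oracle, and a 9-pair synthetic benchmark
  (noise 0.3-1.0 &Aring;, overlap 0.6-0.9) for the two-step protocol.

## Known limitations

* Single rigid transform per alignment: flexible, multi-transform
  alignment is out of scope.
* Sequential (order-preserving) matching throughout; the CA &le; d
  search does not consider non-sequential bipartite matchings.
* The deep search is a strong heuristic validated against a toy-scale
  exhaustive oracle, not the polynomial-time approximation scheme with
  a proven epsilon guarantee.
* The grid oracle's certificate weakens quickly with its step sizes
  (delta grows with the chain radius), which is why it is confined to
  toy instances.
* mmCIF, multi-model NMR ensembles beyond the first model, and
  full-atom detail are not handled.
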