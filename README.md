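# deepalign

Pairwise protein structure alignment from C-alpha traces, built to
measure one thing: how much alignment quality classical heuristics leave
on the table by exploring only a sliver of superposition space.

A structure alignment couples a rigid **superposition** (rotation `R`,
translation `t` of chain *b* onto chain *a*) with a sequential
**alignment** (strictly increasing residue pairs `(i1,j1),...,(ik,jk)`).
`deepalign` provides:

* three classical aligners, assembled from shared dynamic-programming
  cores:
  * **STRUCTAL-style** iterative DP — score
    `S(i,j) = 20 / (1 + d_ij^2 / 5)`, linear gap penalty 10, alternated
    with least-squares superposition of the aligned pairs;
  * **TM-align-style** scoring — `S(i,j) = 1 / (1 + (d_ij/d0)^2)` with
    `d0 = 1.24 (L-15)^(1/3) - 1.8` (shorter length `L`), affine gaps
    0.6 / 0.0;
  * **LOCK2-style** — mutual-nearest-neighbour pairs within 3 A,
    iterative RMSD refinement, and a final colinear (order-consistent)
    subset of maximum size;
* a **deep search** of superposition space (`maxpairs_search()`)
  maximizing the CA &le; d measure — the largest number of residue pairs
  sequentially matchable within `d` Angstroms (defaults `d = 3`,
  annealing slack `epsilon = 1`) — plus an exhaustive toy-scale
  `grid_oracle()` with a computed displacement bound for validating it;
* the standard quality metrics: `NumPairs(d)`, `SI = cRMS * min(L) /
  Nmat`, `PSI(d) = NumPairs(d) / min(L)`, and shift-tolerant agreement
  `I_s / L_ref` against reference alignments;
* a synthetic generator of protein-like chains and decoy pairs with
  known ground truth and a machine-checkable recovery certificate, so
  everything is testable without downloads.

The package is aimed at structural bioinformatics method developers and
benchmarkers; all computation is C-alpha-only.

## Worked example

The two-step protocol on a synthetic pair: an 80-residue helix/coil
chain, a partner sharing 70% of its residues (the rest decoy geometry),
a random planted transform, and 0.5 A coordinate noise.

```r
library(deepalign)
p <- make_pair(n = 80, kind = "mixed", noise_sigma = 0.5,
               overlap_fraction = 0.7, rng_seed = 42)
row <- run_pair(p$a, p$b, ref = p$truth, pair_id = "demo")
row$table[, c("method", "pass", "nmat", "numpairs_d", "psi_d", "si",
              "agreement_s0")]
#>     method       pass nmat numpairs_d psi_d   si agreement_s0
#> 1 structal   original   76         38 0.475 6.04            0
#> 2 structal deepsearch   79         60 0.750 8.37            1
#> 3  tmalign   original   80         45 0.562 6.23            1
#> 4  tmalign deepsearch   79         60 0.750 8.37            1
#> 5    lock2   original   61         61 0.762 1.51            1
#> 6    lock2 deepsearch   61         61 0.762 1.51            1
row$search
#> maxpairs_result: 61 pairs under cutoff (643 seeds evaluated)
```

Reading the table: each method appears twice — `original` is the
aligner run from its own fragment seeds, `deepsearch` its alignment
step re-run on the deep-search superposition. On this pair the deep
search certifies 61 residue pairs under 3 A. First-pass STRUCTAL
converged to a superposition placing only 38 pairs under 3 A
(PSI 0.475) and agreeing with none of the ground-truth pairs at zero
shift; on the deep-search superposition it places 60 (PSI 0.750) with
perfect zero-shift agreement. TM-align gains 15 pairs; the LOCK2-style
aligner had already found the deep-search superposition on its own
(zero delta). `SI` rises with the extra coverage for the DP methods
because they align many decoy residues beyond the cutoff (`si` counts
all aligned pairs); LOCK2's 3 A threshold keeps its SI low. The
per-metric deltas are in `row$deltas`, agreement-vs-shift curves in
`row$agreement`.

Manifest-driven benchmarks (`run_benchmark()`) aggregate per-pair means
per method, pass, and manifest tag, and serialize to TSV/JSON. A thin
CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "deepalign", package = "deepalign"))')
Rscript $CLI fixtures --n 60 --pairs 3 --seed 1 --out-dir fx
Rscript $CLI align --pdb-a fx/fix01_a.pdb --chain-a A \
                   --pdb-b fx/fix01_b.pdb --chain-b A \
                   --method structal --ref-align fx/fix01_ref.txt --out-dir out
Rscript $CLI deepsearch --pdb-a fx/fix01_a.pdb --pdb-b fx/fix01_b.pdb --d 3
Rscript $CLI bench --manifest fx/manifest.txt --dir fx --out-dir bench-out
```

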