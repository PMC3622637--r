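# permalign

Short-read alignment by randomized nearest-neighbour search with random
permutations of sorted substring indexes.

## The problem and the idea

Aligning a sequencing read `Y` of length `M` to a reference genome `W` of
length `N` is a nearest-neighbour search in Hamming space over the
`N − M + 1` contiguous M-mers `X_i` of the reference. A single
lexicographically sorted array of M-mers finds `Y` in `O(log N)` string
comparisons — but only when `Y`'s mismatches occur late in the string.

permalign manufactures that luck. Reordering the characters of *all*
strings with one random permutation `π` preserves every Hamming distance
while relocating mismatch positions, so the package builds `J` sorted
arrays, each under its own uniform random permutation, and looks each read
up in all of them (binary search + the `2K + 1` surrounding entries).
A single iteration proposes the true origin with probability at least

    PrGoodPerm(p, L, M) = (M−L)!/(M−L−p)! · (M−p)!/M!

for a read with `p` mismatches whose origin has resolution length `L`
(the shortest permuted-prefix shared by at most `K` library strings), and
over `J` independent permutations

    PrSuccess(p, L, M, J) ≥ 1 − (1 − PrGoodPerm(p, L, M))^J .

Every candidate is then verified by exact Hamming distance, so extra
candidates cost time, never correctness. The package implements the full
pipeline — indexing, candidate collection, hit-count filtration, ranking —
plus the probability calculus as a parameter planner, paired-end alignment
with indel-tolerant mate rescue by banded edit distance, a wgsim-style
read simulator with ground truth, and SAM output. It is aimed at method
developers and teaching: everything runs at desk scale against exhaustive
oracles.

## A worked example

The permutation `(11, 2, 7, 13, 9, 15, 4, 5, 1, 12, 10, 14, 3, 8, 6)`
applied to the 15-base read `CTTGCCAAAGCCATG`, which differs from its true
reference M-mer `CTCGCCAAAGCCATG` only at position 3:

```r
library(permalign)
p <- asPermutation(c(11, 2, 7, 13, 9, 15, 4, 5, 1, 12, 10, 14, 3, 8, 6))
applyPermutation(p, "CTTGCCAAAGCCATG")
#> [1] "CTAAAGGCCCGTTAC"
applyPermutation(p, "CTCGCCAAAGCCATG")
#> [1] "CTAAAGGCCCGTCAC"
permutePosition(p, 3)
#> [1] 13
```

The early mismatch is moved to position 13: the two permuted strings now
share a 12-character prefix, so binary search in the permuted sorted array
lands on the read's true origin.

End to end on a simulated genome:

```r
g   <- generateGenome(20000, seed = 101)
lib <- buildLibrary(g, m = 15)          # 19986 M-mer positions
idx <- buildIndexes(lib, j = 8, seed = 202)
read <- substring(g, 10001, 10015)      # the M-mer at position 10000
alignRead(read, idx, lib, searchParams(j = 8, k = 20), id = "demo")
#> AlignmentResult 'demo': aligned
#>     pos strand distance hits
#> 1 10000      +        0    8
#> ...
```

The exact copy is proposed by all 8 indexes (`hits = 8`) and verified at
Hamming distance 0. `prSuccess(2, 5, 15, 8)` ≈ 0.989 predicts the recovery
rate for reads with two planted mismatches at this scale, and
`requiredIterations(2, 5, 15, 0.999)` returns the smallest `J` for a
sharper target.

A command-line interface wrapping these functions is installed as
`exec/permalign` (subcommands `index`, `align`, `align-pe`, `simulate`,
`evaluate`, `plan`).

See the vignette (`vignettes/permalign-methods.Rmd`) for the model, the
parameter defaults and their rationale, and known limitations.

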