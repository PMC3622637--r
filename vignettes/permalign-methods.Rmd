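---
title: "Randomized read alignment with permuted sorted indexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized read alignment with permuted sorted indexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permalign)
```

## The search problem

A reference genome is a long string $W$ of length $N$ over $\{A,C,G,T\}$
(possibly with N-masked stretches). For reads of fixed length $M$, the
relevant units of the reference are its $N - M + 1$ contiguous substrings
$X_i$ (the *M-mers*), identified by start position. Aligning a read $Y$
means finding the M-mer at minimal Hamming distance from it — a
nearest-neighbour search in Hamming space. Exhaustive scanning costs
$O(NM)$ per read; a plain sorted array of M-mers only helps when the read's
mismatches sit late in the string, because a mismatch near the front sends
binary search to a lexicographically distant region.

The randomized idea implemented here: shuffling the character positions of
*all* strings with one permutation $\pi$ preserves every pairwise Hamming
distance while relocating the mismatch positions. If, by luck, $\pi$ moves
all of a read's mismatches away from the string prefix, binary search in an
array sorted by *permuted* M-mers lands next to the read's true origin.
Luck is manufactured by repetition: $J$ independent random permutations
give $J$ independent chances, and every proposed candidate is verified
exactly by Hamming distance afterwards, so false candidates cost time but
never correctness.

## Data structures

- **`Permutation`** — a bijection on $\{1..m\}$, stored in the *gather*
  convention: output position $j$ receives the input character at
  `order[j]`. The convention is pinned down by a unit test against a
  worked example with a known printed outcome.
- **`ReferenceLibrary`** — $W$ plus the sorted start positions of all
  N-free M-mers. M-mers overlapping an N are excluded so masked regions
  never enter the search; multi-sequence FASTA input is concatenated with
  N-spacers at least $m$ long, which keeps M-mers from spanning two
  sequences, with a coordinate map back to per-sequence positions.
- **`PermutedIndex`** — one permutation plus the library positions sorted
  by permuted M-mer. Only the position array is kept; permuted strings are
  re-derived from $W$ and the permutation inside the comparator, so an
  index costs one integer per library position regardless of $m$, and the
  persisted form (a small plain-text container) stores only the header,
  the permutation and the order array, guarded by a reference checksum.

Ties between identical M-mers are broken by ascending genome position,
making every index, search and report deterministic. The lexicographic
order is $A < C < G < T$; `N` never occurs in the library, and in queries
it simply occupies a fixed slot in the comparator's order, which is
harmless because any consistent total order makes binary search correct.

## The search pipeline

For a read of length $m$ and parameters $J$ (indexes) and $K$
(neighbourhood half-width):

1. **Collect** (`collectCandidates`): for each index, and for each strand
   searched, permute the read, locate its *lexicographical position* (the
   leftmost insertion point) by binary search, and harvest the $2K + 1$
   sorted-array entries around it, clamped at the array ends. Clamping
   rather than wrapping is deliberate: wrap-around would join
   lexicographically unrelated strings. Each (position, strand) pair
   accumulates a *hit count* across searches.
2. **Filter** (`filterByHits`): keep candidates with at least `minHits`
   hits. With i.i.d. indexes a true near-neighbour tends to be proposed
   repeatedly while noise positions are proposed once, so this is a cheap
   coarse filter; the default is 1 (no filtering) because the toy-scale
   experiments in the test-suite are cheap to verify exhaustively.
3. **Rank** (`rankCandidates`): compute the exact Hamming distance of the
   strand-appropriate read against every surviving candidate M-mer, sort
   by (distance, hit count descending, position, forward strand first),
   report up to `maxReport` alignments, and keep all distance ties.

The per-read cost is $O(J(\log N + K))$ M-mer comparisons; both the sort
and the binary search count their comparisons, and tests assert the
budgets on instrumented runs.

Strand handling: indexes are forward-only, and each read is searched as
given and reverse-complemented (`strandMode = "both"`), with results
labelled by strand. Indexing the reverse complement instead would double
memory to halve search work; searching both orientations was chosen as the
default because it keeps the index minimal.

Reads shorter than $m$ are rejected. Longer reads use
`slidingWindowSearch`: length-$m$ windows at offsets $0, s, 2s, \dots$
(stride $s = \lfloor m/2 \rfloor$ by default, last window clamped to the
read end) are searched in a *single* index, and every hit votes for the
read-start position implied by its window offset, so one index behaves
almost like several. The reverse-strand offset adjustment is
$h + o + m - |Y|$ for a window hit at $h$ and offset $o$.

## Success probability and planning

Suppose a read has $p$ mismatches against its true nearest neighbour and
that neighbour's *resolution length* is $L$ — the shortest prefix of its
permuted M-mer shared by at most $K$ library strings (`resolutionLength`;
the sentinel $m + 1$ is returned for M-mers duplicated beyond $K$ copies,
since no prefix separates identical strings). A uniformly random
permutation moves all $p$ mismatches out of the first $L$ positions with
probability

$$\mathrm{PrGoodPerm}(p, L, M) =
  \frac{(M-L)!}{(M-L-p)!} \cdot \frac{(M-p)!}{M!},$$

in which case that iteration's neighbourhood contains the true neighbour.
Over $J$ independent permutations,

$$\mathrm{PrSuccess}(p, L, M, J) \ge 1 - (1 - \mathrm{PrGoodPerm})^J ,$$

and because every candidate is verified exactly, this bounds the
probability of reporting the correct alignment. `prGoodPerm` evaluates the
ratio in log-space (`lgamma`) so $M$ in the hundreds does not overflow,
and extends the formula by the pigeonhole-forced value $0$ when
$p > M - L$. `requiredIterations` inverts the bound for the smallest
sufficient $J$; `resolutionProfile` estimates the empirical distribution
of $L$ on a seeded sample of library positions, which is what a user feeds
into the planner. The bound is conservative in two ways it does not model:
the $2K+1$ window is usually larger than the prefix neighbourhood of
length $L$, and $L$ itself varies across permutations (tests use the
maximum $L$ over the indexes in play, which keeps the bound valid since
$\mathrm{PrGoodPerm}$ is nonincreasing in $L$).

## Default parameters

| parameter | default | role |
|---|---|---|
| $J$ (`j`) | 8 | independent permuted indexes per read |
| $K$ (`k`) | 20 | sorted-array neighbourhood half-width |
| `minHits` | 1 | hit-count filtration threshold |
| `maxReport` | 5 | reported alignments per read |
| `stride` | $\lfloor m/2 \rfloor$ | sliding-window step |

With $N = 10^6$ and $K = 20$, resolution lengths concentrate around
$L \approx \lceil \log_4 (N/K) \rceil \approx 8$, so for 100-base reads
with the typical 2 sequencing mismatches
$\mathrm{PrGoodPerm} \approx 0.85$ and $J = 8$ drives the failure bound
below $10^{-5}$; $J = 8, K = 20$ are kept as the package defaults for
exactly this kind of regime. All defaults are plain arguments and the
planner can replace $J$ for a stated target.

## Paired-end alignment and rescue

Mates are first aligned independently. A pair is **concordant** when some
combination of the two reported candidate lists has forward/reverse
orientation with the forward mate leftmost and an outer span inside
`[insertMin, insertMax]`; the combination with the smallest summed
distance wins. Only "reasonable" candidates — Hamming distance at most
$\lceil 0.1 \cdot |Y| \rceil$ by default — may form a concordant pair.
This threshold (the spec of a "plausible single-end hit") also guards the
rescue path: a mate carrying an indel has a large Hamming distance
everywhere, and without the plausibility cut its garbage candidates could
accidentally satisfy the insert geometry and mask the rescue.

When no concordant combination exists, the better-aligned mate anchors a
**rescue**: its reasonable candidates are processed by ascending distance,
and for each one the reference window implied by the insert bounds and FR
orientation is scanned for the position minimizing the *banded edit
distance* of the full (strand-oriented) mate. The scan is seeded by exact
occurrences of the mate's prefix and suffix halves — a single indel leaves
at least one half intact — and falls back to exhaustive window DP when no
seeded offset is acceptable. A rescue is accepted at edit distance at most
`maxRescueDistance` (default 10); the first acceptable rescue wins, and an
`exhaustiveRescue` flag forces the full scan instead.

`boundedEditDistance` is a unit-cost global DP restricted to a diagonal
band of half-width `band` (widened to the length difference so the final
cell is always reachable). It is exact whenever the true distance is
within the band — a global alignment path with cost $d$ never leaves the
$|i-j| \le d$ diagonal strip — and returns an M/X/I/D transcript plus the
folded CIGAR used in SAM output. Note that scanning same-length windows at
each offset makes a single interior indel cost 2 (the indel plus one
end-effect edit); the acceptance threshold is interpreted accordingly.

## The read simulator

The simulator exists so that every claim above is testable without any
external data, and mirrors the common wgsim model:

- `generateGenome`: i.i.d. uniform bases — the study condition for the
  package's own experiments.
- `mutateHaplotype`: each base is a variant site with probability
  `mutationRate` (default 0.001); a site is a substitution with
  probability `1 - indelFraction` (default `indelFraction = 0.15`),
  otherwise a single-base insertion or deletion with equal odds. The
  variant list and a haplotype-to-reference coordinate map are returned,
  and truth positions are mapped through it.
- `sampleReads` / `samplePairs`: uniform start positions and strands
  (pairs: FR orientation, insert $\sim$ round Normal(`insertMean = 300`,
  `insertSd = 30`) truncated at the read length, with the physical ends
  swapped with probability 1/2); per-base sequencing substitutions at
  `errorRate` (default 0.02). Qualities are a constant placeholder.
- `evaluateAlignments`: a read is *correct* when some reported alignment
  lies on the truth strand within a tolerance of the truth start
  (default ±5 positions, because planted indels shift coordinates);
  counting any reported candidate — not only the primary — mirrors how
  multi-report aligners are scored. Reads whose truth window overlaps an
  N-masked region are excluded from the denominator.

What the simulator does *not* emulate: real base-composition bias,
repetitive sequence families, quality-dependent error profiles,
multi-base indels (the indel model is single-base by design, matching the
simplest wgsim behaviour), or structural variation. Passing simulation
tests therefore demonstrates the algorithm's statistical behaviour under
its own stated model, not performance on real genomes, whose repeat
structure mainly inflates the multi-mapping rate.

## Numerical and degenerate-input choices

- Internally all positions are 0-based half-open; 1-based coordinates
  appear only in SAM, truth tables and permutation manifests.
- `N` mismatches everything, including another `N`, in Hamming and edit
  distance — masked sequence can never look similar to anything.
- Inputs are case-folded on read; characters outside ACGTN become `N`.
- Binary searches use leftmost-insertion semantics; all orderings have
  total, documented tie-breaks, so fixed seeds give byte-identical output.
- Degenerate parameters are honoured rather than rejected where they have
  a natural meaning: $J = 0$ yields an empty candidate set, $K = 0$ a
  single-entry neighbourhood, prefix length $l = 0$ the whole library,
  and an unattainable planner target ($p > M - L$) is an explicit error.

## Scale of the shipped experiments

The test-suite works at desk scale, chosen to keep the statistical checks
sharp while remaining quick to run: a 20 kb genome with 15-mers for the
exhaustive and planted-mismatch experiments (where every read can be
verified against a full scan), a 1 Mb genome with $10^4$ 100-base reads
at the simulator's default rates for the end-to-end recovery experiment,
and 2000 pairs on a 100 kb genome for the indel-rescue experiment. The
known-answer enumeration checks run every permutation up to $m = 7$.

## Known limitations

- Hamming-only verification for single-end reads: an indel-bearing read is
  only recovered via the paired rescue path (or by chance when the indel
  is near an end).
- One global insert-size window; the insert distribution is a parameter,
  never learned from data.
- No quality-aware scoring, no clipped/local alignment, no BAM/CRAM
  output (SAM only; downstream tools convert), single-threaded by design.
- The hit-count filter assumes i.i.d. indexes; with sliding-window reuse
  of one index the hit counts of overlapping windows are correlated, and
  the theory module does not model that correlation.
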