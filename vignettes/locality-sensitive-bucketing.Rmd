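---
title: "Locality-sensitive bucketing for the edit distance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locality-sensitive bucketing for the edit distance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsbucket)
```

## The problem

Bucketing is the standard way to avoid all-vs-all comparison of sequences:
assign every sequence to one or more buckets in a linear scan, then compare
only within buckets. With exact k-mer buckets this breaks down on long,
noisy reads (PacBio, Nanopore): at realistic error rates two overlapping
reads rarely share an identical k-mer of useful length, so similar
sequences land in disjoint buckets and sensitivity collapses.

A *locality-sensitive bucketing* (LSB) function addresses this
deterministically. Working in the metric space \(S_n = (\Sigma^n,
\mathrm{edit})\) of length-\(n\) sequences under the unit-cost Levenshtein
distance, a function \(f\) mapping each sequence to a *set* of buckets is
\((d_1, d_2)\)-sensitive when

1. \(\mathrm{edit}(s, t) \le d_1 \implies f(s) \cap f(t) \ne \emptyset\), and
2. \(\mathrm{edit}(s, t) \ge d_2 \implies f(s) \cap f(t) = \emptyset\).

Unlike locality-sensitive hashing, which sends each sequence to a single
bucket and can only offer probabilistic guarantees for the edit distance,
allowing multiple buckets per sequence makes *exact* guarantees
achievable. Two parameters measure the cost: \(|B|\), the total number of
buckets, and \(|f(s)|\), the number of buckets one sequence occupies.

This package implements the known constructions, verifies their claimed
sensitivities exhaustively, measures their behavior inside their gaps
(\(d_1 < d < d_2\), where no guarantee exists), and applies them to
length-\(n\) windows of FASTA records.

## The (1,2)-sensitive construction

The strongest ungapped result is an optimal \((1,2)\)-sensitive function:
sequences within one edit always share a bucket, sequences two or more
edits apart never do. Lower-bound arguments show any such \(f\) needs
\(|f(s)| \ge n\) and \(|B| \ge n\,m^{n-1}\) (with \(m = |\Sigma|\)); the
construction here meets both bounds.

Fix an order \(\sigma_1 < \dots < \sigma_m\) on the alphabet and process
all of \(\Sigma^n\) in the induced lexicographic order. Every occurrence
of the smallest character \(\sigma_1\) at position \(i\) of a processed
sequence opens a fresh bucket (ids are consecutive integers from 1)
containing the \(m\) sequences that agree with it everywhere except
position \(i\). Each bucket therefore holds \(m\) sequences pairwise one
substitution apart, and each sequence \(s\) lands in exactly \(n\)
buckets — one for each \(s^i\), the copy of \(s\) with position \(i\)
replaced by \(\sigma_1\).

```{r}
bt <- build_global(2, dna_alphabet())
bt$seq_to_buckets[["AT"]]
bt$bucket_to_seqs[[6]]
```

`build_global()` is exponential (\(O(n\,m^n)\)) and guarded by a safety
cap; it exists as the reference oracle. The production path is the O(n)
formula: the id of the bucket opened at position \(i\) of \(s^i\) is
\(\mathrm{count}(s^i) + \#^1_{i-1}(s) + 1\), where \(\mathrm{count}(t)\)
is the number of \(\sigma_1\)'s among all sequences lexicographically
before \(t\) and \(\#^1_{i-1}(s)\) counts \(\sigma_1\)'s in the length-
\((i-1)\) prefix of \(s\). `buckets_of()` computes all \(n\) ids from one
linear pass that records, per position, the suffix encoding
\(\nu_i(s) = |S_\sigma(s_i \dots s_n)|\) (the base-\(m\) numeral value of
the suffix), the prefix counts \(\#^1_i(s)\), and the per-position terms
\(\mu_i(s)\) with \(\mathrm{count}(s) = \sum_i \mu_i(s)\).

```{r}
buckets_of("AT", dna_alphabet())
```

One numerical note on \(\mu_i\): for \(t_i \ne \sigma_1\) we use
\[
\mu_i(t) = (\sigma^{-1}(t_i) - 1)\,(n-i)\,m^{n-i-1} + m^{n-i},
\]
with coefficient \(\sigma^{-1}(t_i) - 1\): unrolling the count recursion,
the non-\(\sigma_1\) branch descends through the \(\sigma^{-1}(t_i) - 1\)
complete character blocks *preceding* \(t_i\), each contributing
\((n-i)\,m^{n-i-1}\) smallest-character occurrences, plus the
\(m^{n-i}\) term for crossing into the current block. The test suite pins
this form against direct enumeration of the sequence space (for example
\(\mathrm{count}(\mathrm{CA}) = 5\) over the DNA 2-mers: two A's in AA and
one each in AC, AG, AT) and proves the O(n) formula identical to the
global-counter oracle on whole spaces up to \(m^n = 256\).

### Arithmetic contract

Bucket ids reach \(n\,m^{n-1}\). All id arithmetic is done in doubles,
which are exact integers up to \(2^{53}\); `buckets_of()` and friends
refuse inputs beyond that (for DNA, \(n \le 25\); the simulator's
\(n = 20\) is comfortably inside). This keeps the implementation
dependency-free; lengths beyond the exact range would need big-integer
arithmetic and are out of scope here.

## The (1,1)-guaranteed partition

For bucketing functions of the form \(f_B^r(s) = N_n^r(s) \cap B\) —
buckets labeled by sequences, a sequence mapped to the members of its
radius-\(r\) neighborhood that lie in a chosen subset \(B\) — the triangle
inequality gives disjointness at \(d_2 = 2r + 1\) for free, and the whole
design question is choosing \(B\) so that close pairs keep a common
neighbor inside \(B\). \(B\) is \((d_1, r)\)-guaranteed when every pair
within distance \(d_1\) has a common \(r\)-neighbor in \(B\);
equivalently \(f_B^r\) is \((d_1, 2r+1)\)-sensitive.

The space partitions into \(m\) blocks, each a *minimum*
\((1,1)\)-guaranteed subset of size \(m^{n-1}\), by a rotated-prepend
recursion from \(B_1^p = \{c_p\}\):
\[
B_n^i = (c_1 \circ B_{n-1}^i) \sqcup (c_2 \circ B_{n-1}^{i+1}) \sqcup
\dots \sqcup (c_m \circ B_{n-1}^{i-1}).
\]

```{r}
build_partition(2, dna_alphabet())[1:2]
```

Membership needs no construction: scanning \(s\) backwards, the last
character \(c_p\) gives the base-case index \(p\), and each preceding
character \(c_k\) maps the suffix's block index \(j\) to
\(\ell = (j + m + 1 - k) \bmod m\). The formula is stated with 1-based
block indices but a bare mod; we resolve the \(\ell = 0\) case to block
\(m\) (implemented as \(((j - k) \bmod m) + 1\), which is the same map),
the unique convention consistent with the reference length-2 and length-3
DNA partitions pinned in the test suite (e.g. TG must land in block 4). `partition_index()` is
vectorized over sequences; the backward scan runs across the rank matrix
one position at a time.

```{r}
partition_index(c("TAA", "GGG", "TG"), dna_alphabet())
```

Block intersections with radius-1 neighborhoods are exactly 1 for members
and \(n\) for non-members, which makes \(f^1_{B_n^i}\) an optimal
\((1,3)\)-sensitive function; the blocks are also \((r,r)\)-guaranteed
for every \(r \ge 1\) (giving \((r, 2r+1)\)), and for \(r = 2\) the
stronger \((3,5)\) holds.

## Scheme registry

| scheme | \(B\) | \((d_1, d_2)\) | \(|B|\) | \(|f(s)|\) |
|---|---|---|---|---|
| `lsb12` | integer ids | (1, 2) | \(n\,m^{n-1}\) | \(n\) |
| `full`, r odd | \(\Sigma^n\) | \((2r-1,\,2r+1)\) | \(m^n\) | \(|N_n^r(s)|\) |
| `full`, r even | \(\Sigma^n\) | \((2r,\,2r+1)\) | \(m^n\) | \(|N_n^r(s)|\) |
| `partition`, r = 1 | \(B_n^i\) | (1, 3) | \(m^{n-1}\) | 1 or \(n\) |
| `partition`, r = 2 | \(B_n^i\) | (3, 5) | \(m^{n-1}\) | \(\le |N_n^2(s)|\) |
| `partition`, r > 2 | \(B_n^i\) | \((r,\,2r+1)\) | \(m^{n-1}\) | \(\le |N_n^r(s)|\) |

For partition schemes with \(r \ge 2\) only upper bounds on \(|f(s)|\)
are known; `verify_sensitivity()` records the observed distribution
without asserting tightness. `full` additionally accepts \(r = 0\)
(identity bucketing, \((0,1)\)-sensitive), which the CLI uses as a
degenerate base case; `partition` does not, since \(f^0_{B}(s)\) would be
empty for sequences outside the block. All partition blocks carry the
same guarantees, so the block index is a free parameter (default 1).

## Exhaustive verification

`verify_sensitivity()` checks both sensitivity conditions over *every*
unordered pair of \(\Sigma^n\), materializing each bucket set and
intersecting — deliberately not using the triangle-inequality shortcut or
any other consequence of the theorems it is testing. Distances strictly
inside the gap carry no guarantee; their collision frequencies are
reported descriptively. The state-space cap (default \(m^n \le 10^6\))
keeps the quadratic pass honest about its intended scale.

Gap behavior is *edit-type dependent*. Categorize a pair at distance
\(d\) by the smallest number \(i\) of indel pairs (an insertion plus a
deletion, the length-preserving unit of non-substitution edits) in a
script with exactly \(i\) indel pairs and \(d - 2i\) substitutions;
category 0 means Hamming distance equals edit distance. At the gap
\(d = 2\) of the \((1,3)\)-sensitive full-neighborhood scheme,
category-0 pairs (two substitutions) always share a bucket — the midpoint
sequence after one substitution is a common 1-neighbor — while
category-1 pairs (one indel pair) never do: their radius-1 neighborhoods
are disjoint. Claiming (2,3) therefore fails verification, and the
violating pairs are exactly the category-1 pairs. `edit_type_category()`
computes the category by a DP over (position in s, position in t,
deletions used) that minimizes substitutions at each exact indel count;
where the definition's "exactly this composition" reading is ambiguous we
take the smallest \(i\) whose minimal substitution count equals
\(d - 2i\), which always exists because some optimal alignment realizes
the distance with equal insertions and deletions.

## The collision simulator

`run_experiment()` estimates collision frequencies on random pairs at
exact edit distances for realistic window lengths: by default length 20,
distances 1..6, and the three gapped schemes (full r=1, partition r=1,
partition r=2), with `pairs_per_d = 2000` as the desk-scale default
(`pairs_per_d = 100000` reproduces the full survey scale), and categories
broken down at gap distances with `"a+bx2"` labels (a substitutions, b
indel pairs).

Pair generation is rejection sampling: `s` uniform over \(\Sigma^n\);
`t` proposed by applying \(b\) indel pairs (b uniform over
\(0..\lfloor d/2 \rfloor\)) and \(d - 2b\) substitutions at distinct
positions; the pair is accepted only if the distance DP verifies exactly
\(d\). Conditioning on the exact distance pins down nothing about the
distribution over edit scripts, so gap-row frequencies are only
qualitatively comparable across implementations — the category mix at
the gap depends on the proposal — while rows at \(d \le d_1\) and \(d \ge d_2\) are
theorem consequences and must be exactly 1 and 0 at any sample size.
All randomness flows through one seed (`withr::with_seed`), recorded in
the output.

At \(n = 20\) only the non-materializing paths run: `buckets_of`,
`partition_index`, and radius-\(r\) neighborhood *generation* (for
\(r \le 2\), a few thousand candidates built by vectorized matrix
indexing). For the collision decision the candidate set is filtered by
block membership first and by distance to the partner second; candidates
carry at most \(r\) edit operations by construction, so the s-side check
is skipped. The equivalence of this fast path with the literal
intersection-of-assignments definition is itself a test (random pairs at
\(n = 8\)).

## What the synthetic data does and does not show

The simulator emulates a deliberately controlled setting: i.i.d. uniform
sequences and exact-distance pairs manufactured from random edit scripts. Real reads differ in every inconvenient way —
non-uniform base composition, bursty and non-independent errors,
repeats, and window pairs whose true distance is unknown rather than
conditioned on. Passing bounds here certifies the *combinatorial
guarantees* of the constructions, not end-to-end overlap-detection
performance on a sequencing dataset; the FASTA tool exists precisely so
the functions can be applied to real windows downstream.

## Degenerate inputs and numerical choices

* Alphabets need \(m \ge 2\) distinct single characters; sequences are
  validated eagerly, and comparing sequences over different alphabets is
  an error, not a coercion.
* Positions are 1-based in all documentation (\(s_1 \dots s_n\)); FASTA
  window offsets are 0-based half-open, BED-style, and say so.
* `neighborhood(s, 0)` is \(\{s\}\); `lex_rank("")` is 0.
* Bucket ids are doubles, exact below \(2^{53}\), guarded (see above).
* Ties cannot occur in `buckets_of` output: ids opened at distinct
  positions are distinct; output is in position order, and the CLI
  serializes sorted.
* Exponential builders (`build_global`, `build_partition`,
  `verify_sensitivity`, `all_sequences`) share one `max_space` cap,
  default \(10^6\), overridable explicitly.

## Problem sizes used by the shipped checks

Exhaustive checks run on the DNA space at \(n \le 3\) (plus \(n = 4\)
for partition agreement) and the binary space at \(n \le 5\); the
fast-vs-oracle identity covers all of \(\Sigma^n\) for
\((n, m) \in \{(2,4), (3,4), (4,2), (5,2)\}\). The collision experiment
ships at \(n = 20\), \(d = 1..6\), 2000 pairs per distance — large
enough that the gap frequencies stabilize to two digits while the
theorem rows stay exact by construction, and small enough for a desk
machine; the full 100,000-pair scale is one flag away.

## Known limitations

* No probabilistic (LSH-family) constructions or OR-amplification
  layering; the functions here are deterministic by design.
* No \((r,r)\)-guaranteed subsets smaller than \(B_n^i\) for \(r > 1\)
  (open problem territory), and no claim that the observed \(|f(s)|\)
  for partition \(r \ge 2\) is minimal.
* Fixed-length windows only: the metric space is \(\Sigma^n\), and the
  FASTA tool compares windows of one length at a time.
* Forward strand only; the constructions are not reverse-complement
  symmetric, and no canonicalization is attempted.
* Weighted or affine-gap costs, banded approximations, and alignments
  themselves (beyond distances and categories) are out of scope.
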