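---
title: "Sketching methods in genosketch: models, conventions and design choices"
author: "genosketch maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketching methods in genosketch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genosketch)
```

# The problem

Comparing genomes by alignment does not scale to collections of thousands of
assemblies or to metagenomic read sets. Sketching replaces each sequence by a
small, fixed-size summary of its k-mer content from which similarity — the
Jaccard index of the k-mer sets, and from it an evolutionary-distance-like
quantity — can be estimated in time that depends on the sketch size, not the
genome size. genosketch implements four complementary sketch families behind
one update/merge/compare surface, together with an inverted index for
all-vs-all comparison of many sketches. This vignette records the models, the
conventions that make sketches reproducible bit-for-bit, and the choices made
where the design was genuinely open.

# Shared ground: k-mers and hashing

**Canonical k-mers.** A window of length $k$ ($1 \le k \le 32$) is read from
both strands and represented by the lexicographic minimum of the forward
k-mer and its reverse complement, so sketches are strand-independent. Windows
containing any character outside A/C/G/T (N in particular) are skipped
entirely; lowercase input is uppercased. These follow the conventions of the
wider MinHash ecosystem so that the same genome yields the same k-mer set
everywhere. K-mers are packed 2 bits per base (A=0, C=1, G=2, T=3, leftmost
base most significant), which both bounds $k$ at 32 and makes the numeric
order of encodings equal to lexicographic order of the strings.

**Hashing.** All sketch families hash the ASCII string of the canonical
k-mer with MurmurHash3 x64_128 and keep the lower 64 bits of the digest;
the default seed is 42. Hashing the string form (rather than the packed
integer) keeps sketches comparable across any implementation that agrees on
the k-mer text. A Wang 64-bit invertible mix (`wangMix`) is provided as the
integer hash used in derived-seed plumbing. Because R has no unsigned 64-bit
integer type, hash values travel as decimal strings throughout the package
and in serialized sketches; conversion and ordering happen in C++, so no
precision is ever lost. `murmur64Batch` processes inputs in fixed-width
lanes and is contractually bit-identical to the scalar map — the batch
interface is an engineering contract, not an approximation.

**Reverse complement** uses a 256-entry lookup table applied per base with
no per-character branching; validity is checked afterwards so an invalid
character is reported with its position. The test-suite pins this to the
naive per-character implementation and to `Biostrings::reverseComplement`.

# Bottom-s MinHash (`minhashSketch`)

The sketch retains the $s$ smallest *distinct* hash values seen (set
semantics; duplicates are stored once). `updateSketch` streams sequences one
at a time and is guaranteed to give the sketch of the concatenated k-mer
multiset regardless of input order; `mergeSketches` takes the bottom-$s$ of
the union and is commutative, associative and idempotent.

Two sketches are compared with the Mash estimator: merge the two sorted hash
lists, take the $s' = \min(s, |A \cup B|)$ smallest values of the union, and
count how many occur in both sketches:
$$\hat J = \frac{|\mathrm{bottom}_{s'}(A \cup B) \cap A \cap B|}{s'}.$$
The $\min$ in the denominator handles genomes with fewer than $s$ distinct
k-mers, in which case the estimate is the exact Jaccard. The Jaccard
estimate converts to the Mash distance
$$D = -\frac{1}{k}\ln\frac{2\hat J}{1+\hat J},$$
clamped to $[0,1]$ (with $D = 1$ at $\hat J = 0$); under a Poisson model of
random site substitution $D$ estimates the per-base mutation rate. Defaults
$k = 21$, $s = 1000$ follow common practice for bacterial-genome
comparisons; at $s = 1000$ the sampling standard error of $\hat J$ is about
$\sqrt{J(1-J)/1000} \le 0.016$.

When two *empty* sketches are compared, the denominator is 0; the package
reports Jaccard 0 and distance 1 rather than an error, a deliberate
convention for degenerate inputs (an empty sketch carries no evidence of
similarity).

# OrderMinHash (`omhSketch`)

OrderMinHash makes the similarity sensitive to the *order* of k-mers, so it
acts as a proxy for edit distance rather than for k-mer content. The sketch
runs $m$ hash repetitions; repetition $i$ hashes every k-mer *occurrence*
and keeps the $\ell$ occurrences with the smallest hashes, stored in the
order they appear in the sequence. Two sketches' similarity is the fraction
of repetitions whose ordered selections match exactly (all-or-nothing tuple
match, the estimator of the OrderMinHash construction); partial credit per
element is out of scope.

Conventions fixed by this package:

* **Occurrence weighting.** The $j$-th occurrence (0-based) of an identical
  k-mer string hashes the bytes `kmer:j` — k-mer ASCII, a colon, and the
  decimal occurrence index. Appending the occurrence index distinguishes
  repeats; the textual encoding keeps the scheme reproducible from plain
  strings in any language.
* **Per-repetition seeds.** Repetition $i$ uses
  `seed XOR fold32(wangMix(i))`, where `fold32` xors the two 32-bit halves.
  `omhRepetitionSeed` exposes the derivation.
* **Forward-strand k-mers.** Positional order is only meaningful on the
  written strand, so OrderMinHash hashes forward k-mers, not canonical ones.
* **Per-sequence sketches.** One sketch per record; concatenating the
  records of a multi-FASTA would fabricate order across unrelated sequences,
  so multi-record inputs are sketched record by record (the command-line
  tool does this automatically).
* **Ties.** Equal hash values (vanishingly rare with 64-bit hashes) resolve
  to the earlier position, making the selection deterministic.
* **Traversal order.** The selection can be computed row-wise, column-wise
  or in blocks of repetitions over the position axis (the `block` argument
  controls how many repetition queues advance together, mirroring
  cache-blocked evaluation). Any traversal yields a bit-identical sketch,
  and the tests enforce this.

A sequence shorter than $k$, or with no valid window, is an error: an
OrderMinHash of an empty k-mer stream is undefined. With fewer than $\ell$
occurrences available, each repetition simply holds all of them.

# Kssd-style substring space sampling (`kssdDictionary`, `kssdSketch`)

Kssd samples a deterministic fraction of k-mer space: all genomes sketched
with the same dictionary keep exactly the same k-mers, so intersections are
set operations on *subsampled but aligned* universes. The dictionary is a
seeded Fisher–Yates shuffle of the $4^L$ codes of length-$L$ substrings
($L$ = `halfK`, default 6). A k-mer is kept iff the code of its central
length-$L$ substring has shuffled rank below $4^{L-d}$, where $d$ =
`drlevel` (default 3) — a fixed $4^{-d}$ fraction. Conventions:

* The shuffle PRNG is splitmix64 (64-bit state, golden-gamma increment,
  documented finalizer), seeded directly with the dictionary seed, so
  dictionaries are portable across platforms and versions.
* "Valid" codes are the *prefix* of the shuffled order. Any fixed
  $4^{L-d}$-subset would do; the prefix rule is pinned for reproducibility.
* The substring is taken from the centre of the k-mer,
  `start = (k - L) %/% 2`, requiring $k \ge L$.
* Sketches store the full 2-bit encoding of the selected canonical k-mer
  (not the reduced code); intersection semantics are identical for a fixed
  dictionary and the stored form is self-describing.
* A digest (`dictId`) of the parameters and the permutation binds every
  sketch to its dictionary; comparing or merging sketches from different
  dictionaries is an error, because their sampled universes differ.

The *map dictionary* (`kssdMapDictionary`) is the compact table of only the
valid codes — $4^{L-d}$ entries instead of $4^L$. Sketching through the map
is bit-identical to sketching through the full permutation array; the tests
check membership agreement exhaustively over the code space.

Kssd Jaccard is the plain set Jaccard of the two stored code sets (sorted
merge), and converts to a Mash distance with the same formula as MinHash.
Because the same fraction of every genome is kept, the estimator is close to
unbiased for the full-k-mer Jaccard; the tests hold the mean deviation at
$d=2$ under 0.02 across simulated pairs.

# HyperLogLog (`hllSketch`)

HyperLogLog estimates the *cardinality* of the k-mer set in $2^p$ one-byte
registers. For each 64-bit hash, the top $p$ bits select a register and the
register keeps the maximum of (leading-zero count of the remaining $64-p$
bits + 1). Insertions are idempotent and registers only grow, so
register-wise maximum merges two sketches exactly into the sketch of the
union — the tests verify register equality against a single-stream build.

The estimator is the bias-corrected original HyperLogLog: raw harmonic mean
$\alpha_m m^2 / \sum_j 2^{-M_j}$, replaced by linear counting
$m \ln(m/V)$ when empty registers remain and the raw estimate is below
$2.5m$; with 64-bit hashes no large-range correction applies. This variant
(among the several in the Dashing lineage) is pinned because it is simple,
well characterized, and calibrates to well under 2% mean relative error at
the default $p = 14$ (theoretical relative standard error
$1.04/\sqrt{2^p} \approx 0.81\%$). Jaccard between two HLL sketches uses
inclusion–exclusion on the three cardinality estimates, clamped into
$[0,1]$; it is a noisy estimator by nature and is intended for large sets.
The register-maximum kernel exists in a branch-free arithmetic form and a
branchy reference; both are exposed and tested to agree on all register
pairs — equivalence is the contract, not the instruction choice.

# All-vs-all comparison (`buildIndex`, `allVsAll`, `pairwiseDistances`)

For $n$ sketches, the naive loop runs $\binom{n}{2}$ sorted-list merges. The
inverted index (*index_dict*) instead maps each observed hash value to the
sorted ids of the sketches containing it and streams keys in ascending hash
order, incrementing per-pair shared counters. Only observed hashes get an
entry, so memory grows with the number of distinct observed values, never
with the $2^{64}$ hash space (the validity method enforces this
structurally).

One subtlety makes the MinHash case exact rather than approximate: the Mash
estimator counts shared hashes only among the bottom-$s'$ of each *pair's
union*. Because the stream visits hashes in ascending order, the engine
tracks each pair's union rank and stops crediting shared hashes once the
rank passes $s$; the denominator is $\min(s, |A \cup B|)$ as in the
two-sketch estimator. The result is therefore *bit-identical* to the
pairwise loop — enforced by tests on both MinHash and Kssd collections —
and the index is purely an acceleration. Evaluation is sequential and
deterministic; results cannot depend on worker count or scheduling, which is
the portable form of the thread-independence contract.

Distance tables have one row per unordered pair (self-pairs included, with
Jaccard 1 for non-empty sketches) in fixed lexicographic (ref, query) order,
so outputs are byte-comparable across engines and runs.

# The synthetic-genome generator

`randomGenome` draws i.i.d. uniform ACGT from a seeded splitmix64 stream —
deterministic, platform-independent, and decoupled from R's global RNG.
`mutateGenome` substitutes each base independently with probability `rate`,
always to a different base: exactly the divergence model under which the
Mash distance estimates the substitution rate, which is what makes the
mutate-and-recover calibration meaningful. `randomEdits` applies a given
number of random substitutions/insertions/deletions for the OrderMinHash
edit-load experiments. `exactJaccard` (hash-free, full enumeration) and
`editDistance` (Levenshtein via `utils::adist`) are the oracles.

What the generator does *not* emulate: repeats, GC skew, rearrangements,
indel-rich divergence, sequencing error profiles. Passing tests therefore
demonstrate estimator correctness and calibration under the stated models —
uniform composition and substitution-only divergence — not performance on
every pathology of real assemblies. On real data the estimators inherit the
known caveats of their families (e.g. Mash distance saturates for distant
genomes; repeat-induced k-mer multiplicity is collapsed by set semantics).

# Validation problem sizes

The shipped tests and the acceptance script use, as the package's chosen
study conditions: 100 kb genomes with $k=21$, $s=1000$ for estimator
calibration (200 pairs across a range of true Jaccard values; 20 replicates
per substitution rate $r \in \{0.01, 0.05\}$); 50 small-genome pairs in the
saturated regime where the KMV estimate must equal the exact Jaccard;
Kssd at $L=6$, $d=2$ on 100 kb genomes with exhaustive map-dictionary
checks; HyperLogLog at $p=14$ over $n \in \{10^2, 10^4, 10^5\}$ with 20
seeds each; OrderMinHash with $m=256$, $\ell=2$ on 1 kb sequences across
edit loads $\{1, 5, 10, 20, 50\}$; and 10-genome collections for the
index-vs-loop equality. These sizes give the statistical bounds quoted
above comfortable power while keeping a full run in tens of seconds.

# Numerical and degenerate-input choices

* 64-bit values as decimal strings at the R surface and in JSON; numeric
  conversion and comparison only in C++.
* Empty vs empty comparison: Jaccard 0, distance 1 (no evidence), except
  `exactJaccard` of two empty *sets*, which is 1 (equal sets) — the oracle
  follows set semantics, the estimator follows evidence semantics.
* `intersectCount` has a checked mode (rejects unsorted input, on by
  default) and a trusted fast mode; the block method's width (default 8) is
  a pure performance knob with an exact-equality obligation.
* Sketch files are JSON lines; writing the same sketch twice produces
  byte-identical files. Dictionary files embed the full permutation and are
  re-validated on read.

# Limitations

* $k \le 32$ (2-bit packing); amino-acid alphabets are out of scope.
* OrderMinHash sketches are per-sequence and do not merge.
* The HLL Jaccard is an inclusion–exclusion estimate without the joint-MLE
  refinements of newer estimators; its variance is large for small sets.
* The inverted index is in-memory; out-of-core and distributed operation
  are out of scope.
* Mash p-values and `.msh` file compatibility are not provided.

# Command-line interface

`inst/cli/genosketch.R` wraps the library for shell use: `sketch` (one
sketch per input file by default, per-record with `--per-sequence`, always
per-record for OrderMinHash), `dist` (all-vs-all for one input set with
`--engine index|pairwise`, query-vs-reference for two), and `info`. Only
parameters relevant to the chosen algorithm are accepted; logs go to
stderr and results to `-o`/stdout.
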