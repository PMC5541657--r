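---
title: "Alignment kernel, simulator and genetic-improvement methods"
author: "gibarra authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment kernel, simulator and genetic-improvement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibarra)
```

# Scope

`gibarra` is a desk-scale short-read alignment stack built around a
Burrows-Wheeler/FM index, with three unusual features for a package of its
size: a two-phase search kernel (a cheap exact pre-pass backed by a
k-difference backtracking fallback), a deterministic instrumented cost model,
and a genetic-improvement (GI) harness that evolves the kernel's declared
parameter and code-variant sites under an "equivalent answers, then faster"
fitness.  A read simulator with ground truth makes the whole stack testable
without external data.

# The index

The references are concatenated, a single sentinel (lexicographically
smallest) is appended, and the suffix array is built by prefix doubling —
an $O(n \log n)$ method whose constant factors are irrelevant at the genome
sizes this package targets (up to a few hundred kilobases).  From the suffix
array we derive the BWT, the cumulative symbol counts $C$, a checkpointed
occurrence table (stride `occ_stride`, default 64) and a sampled suffix
array (stride `sa_stride`, default 4, resolved by LF-walking).  The strides
are a conventional FM-index speed/memory trade-off; the test suite checks
that results are invariant to them.  `N` in the reference is a true fifth
symbol that search never extends into, so runs of `N` cannot anchor
spurious hits.  Coordinates are 0-based half-open everywhere inside the
package and become 1-based only when SAM records are written.

Exact backward search extends a suffix-array interval one query symbol at a
time from the query's end: the number of LF extension steps equals the
query length, i.e. lookup time is linear in the read and independent of
genome size.  An instrumented counter asserts this in the tests.

# The two-phase kernel

Reads longer than 150 bp keep their first 150 bases; the remainder is
ignored with one warning per read.  Reads that are more than half `N` are
reported unmapped without search.

The pre-pass tries the read and its reverse complement with plain exact
search — uniform control flow, a fixed number of LF steps per strand.  In
clean data this handles the large majority of reads.  Anything without an
exact placement falls back to the k-difference backtracking search, which
explores substitution, insertion and deletion extensions of backward
search, level-synchronously in ascending penalty.  The pre-pass is a pure
optimisation: the test suite asserts bit-identical output with the
pre-pass on and off, with strictly lower instrumented cost on
exact-matching reads.

## Differences and scoring

A placement is scored by accumulated penalty: `mismatch_pen` 3 per
substitution, `gap_open_pen` 11 per gap open, `gap_ext_pen` 4 per gap
extension (conventional short-read aligner defaults; all GI-tunable).
*Differences* are substitutions plus gap opens **plus gap extensions**,
charged against `max_diff`.  Charging extensions is a deliberate design
choice: the backtracking search is pruned by a per-prefix lower bound
(below), whose correctness argument needs every difference to occupy at
most one read position.  If a multi-base gap run cost a single difference,
one insertion run crossing the boundary between two exactly-unmatchable
read segments could repair both at unit cost and the bound would
over-prune.  A consequence worth knowing: a 3 bp indel consumes three
difference units, so it is only alignable when the budget allows
(`max_diff = "auto"` grants 2 below 64 bp, 4 for 64–122 bp, 5 for
123–150 bp).

## Pruning

Before the fallback runs, one backward pass of the read over an index of
the *reversed* reference computes `d[i]`, a lower bound on the differences
needed to align the read prefix of length `i` anywhere: each time the
exact interval empties, one more difference is forced and the interval
restarts.  States whose differences-so-far plus `d` of the remaining
prefix exceed the budget are cut.  The bound is computed on the whole
concatenated reversed text; exact stretches crossing reference boundaries
only weaken it (it stays a valid lower bound).  Additional pruning comes
from the seed constraint (`max_seed_diff`, default 2, within the first
`seed_len` bases, default 32 — at 36 bp with budget 2 it is inert, at
100 bp it meaningfully narrows the search), the gap caps, and a hard cap
`max_queue` on expanded states; an exhausted budget yields an unmapped
read, never an error.

## Determinism and tie-breaking

Children are generated in a fixed order (match, then substitutions in
symbol order, then deletions, then insertion), levels are processed in
ascending score and states within a level in creation order, and final
hits are sorted by reference position with the forward strand first and
deduplicated by (position, strand).  Identical inputs therefore give
bit-identical hit lists — this is what makes the GI fitness's
answer-equivalence well defined.

## Mapping quality

The scheme is deliberately simple and deterministic: unique placement 37;
unique inexact placement with a completed competitor within one mismatch
penalty of the best score 23; two or more co-optimal placements 0.
Competitor detection continues the level sweep to `best + mismatch_pen`,
which the search needs anyway to enumerate all co-optimal hits.  Two
refinements keep the two-phase contract intact: the competitor demotion
applies only when the best score is positive (probing for 1-mismatch
competitors of an *exact* hit would re-run the very backtracking the
pre-pass exists to avoid), and competitor detection is score-window based
rather than position based (at the default penalties an alternative path
to the same position always costs more than the window, so the
distinction is immaterial in practice).

# Paired-end combination

The `sampe` stage buffers both hit streams, fits the insert model from
confident pairs (both ends unique with MAPQ ≥ 20, forward-reverse
orientation), discarding template lengths more than 3 interquartile ranges
from the median and summarising the rest by mean and population sigma;
acceptance bounds are mean ± 4 sigma, falling back to a configured default
model (300 ± 100) with a warning when no pair qualifies.  Pair selection
enumerates cross-combinations (64 placements per end at most) and takes
the minimum combined-score proper pair — same reference, FR orientation,
leftmost end forward, template length within bounds — with ties broken on
the lower end-1 then end-2 position; when nothing is proper the
independently best hits are paired with the proper-pair bit clear.  There
is no Smith–Waterman mate rescue: an end the kernel cannot place stays
unmapped and is written at its mate's position per SAM convention.  Flags,
mate fields and signed template lengths are emitted cross-consistently and
the tests validate the output through an independent htslib parser.

# The read simulator

`simulate_reads` emulates the short-insert paired-end regimes the aligner
targets (36 bp and 100 bp ends): a donor genome with SNPs and 1–3 bp
indels at configurable per-base rates, fragments with Normal insert
lengths (truncated at the read length), end 1 forward from the fragment
start, end 2 reverse-complemented from the fragment end, per-base
substitution errors with downgraded quality symbols, and a configurable
fraction of duplicate pairs (re-emitted fragments with fresh errors and
distinct ids) emulating the few-percent duplicate fraction seen in real
runs.  Truth records carry the 0-based position on the *original*
reference frame (inserted donor bases take the coordinate of the leftmost
unaffected base), which is what the scorer compares against with a
positional tolerance (default 5 bp) because indels shift alignments.

What the simulator does not model: empirical quality profiles, indel
sequencing errors, structural variants, contamination, coverage bias.
Passing the no-noise closure (100% mapped, 100% accurate at tolerance 0 on
a repeat-free genome) and the noisy-regime bounds therefore demonstrates
algorithmic correctness of the stack, not performance claims on any real
library.

# The genetic-improvement loop

The grammar is generated from the kernel's declared tunable-site registry:
parameter sites map to `search_params()` fields, code-variant sites to
`kernel_variants()` toggles (pre-pass on/off, bound pruning on/off).  An
individual is an assignment of grammar-legal values; the empty assignment
reproduces the reference kernel bit-exactly.  Mutation changes exactly one
site; crossover draws each site from one of two parents uniformly.

Fitness runs the instantiated kernel over the training batch: an
individual is *equivalent* when its per-read answers (reference, position,
strand, score) are identical to the reference kernel's, and its cost is
the summed instrumented work (LF steps plus state expansions).  Cost is
deterministic by construction — wall-clock timing of an interpreted kernel
would be noisy and irreproducible — so fitness is memoised per distinct
assignment.  A kernel that raises an error scores non-equivalent with
infinite cost.

Selection follows the fastest-half / two-children scheme: equivalent
individuals ranked by cost form the parent pool, the top half get one
crossover child (partner drawn uniformly from the other parents) and one
mutation child each.  Two policies cover situations the scheme itself does
not: with elitism (default on) the last child slot carries the best parent
forward unchanged, which is what guarantees a non-increasing
best-of-generation cost under generational replacement; and when fewer
than two parents are eligible the population restarts deterministically
from the reference kernel and its single-step mutants rather than
aborting.  After the final generation, candidates are re-validated on a
held-out read batch (the train/holdout split is stratified by pre-pass
difficulty, so a mutant that only handles exact-matching reads cannot
win); a candidate whose holdout answers differ is rejected in favour of
the next, falling back to the reference kernel.  The returned individual
is therefore always holdout-equivalent with training cost never above the
reference.

Scaled-down defaults (population 20, 10 generations, 2000 training reads)
keep desk-scale runs interactive; the full-scale configuration (population
1000, 50 generations, on the order of 160,000 training strings, where
breeding produces exactly 500 parents with two children each) is available
through `gi_config()` and its arithmetic is exercised structurally in the
tests.

# Numerical and engineering choices

* **Problem sizes in the test suite** (chosen as representative desk-scale
  conditions): index/BWT oracles on 1000 random genomes up to 2 kb; exact
  search against a naive scan for every distinct substring of length 1–20
  of a 2 kb genome; k-difference search against a banded
  dynamic-programming oracle for 200 reads with up to two planted edits on
  a 5 kb genome; pipeline closures with 2000 simulated pairs on a 100 kb
  genome; GI optimum recovery on an exhaustively enumerable 16-variant
  grammar.
* **Degenerate inputs**: empty references, empty intervals, all-`N` reads,
  absent patterns, both-ends-unmapped pairs and version-mismatched
  containers all have defined, tested behaviour (empty results or typed
  errors, never silent corruption).
* **Serialisation**: the index container and the hits stream are versioned
  and carry the reference checksum, so a hits/index mismatch is an error
  rather than silently wrong coordinates.  The hits format is line-based
  text and works through pipes and process substitution; it makes no
  attempt at byte compatibility with any other tool's intermediate files.
* **RNG discipline**: every stochastic component (simulator, GI operators,
  splits) draws from R's RNG seeded once per run; identical seeds give
  byte-identical outputs, which the tests assert.

# Known limitations

The aligner is a reference implementation for desk-scale genomes: pure R,
no 2-bit packing, no compressed occurrence structures, no multi-threading.
There is no quality-aware scoring, no soft-clipping, no Smith–Waterman
extension, and MAPQ is a simplified scheme rather than a calibrated error
probability.  The GI harness mutates the declared parameter/variant
grammar of the kernel — it does not mutate source text, and it optimises a
deterministic work-unit proxy, not wall-clock time on any particular
hardware.
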