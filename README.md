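# gibarra

Desk-scale FM-index short-read alignment with a genetic-improvement harness
for the search kernel.

## What this is for

Short-read aligners in the BWA family compress the reference genome into a
Burrows-Wheeler/FM index and look each read up by *backward search* — O(n)
in the read length, independent of genome size.  Clean reads resolve with a
single uniform pass; noisy reads (sequencing errors, SNPs, indels) force a
backtracking *k-difference* search that dominates run time.  `gibarra`
implements this whole stack at desk scale, in R, for people who want to
study, test or tune the algorithmics without a cluster or external data:

* **`fm_index`** — suffix array (prefix doubling), BWT, checkpointed
  occurrence table, sampled suffix array; exact backward search and locate.
* **`align_core`** — the two-phase kernel: 150 bp truncation rule, a
  non-divergent exact pre-pass for the easy majority, and a k-difference
  backtracking fallback pruned by a per-prefix difference lower bound, a
  seed constraint and gap caps.  Deterministic hit ordering and a
  documented MAPQ scheme.
* **`paired_end`** — the `sampe` stage: insert-size model estimation
  (median/IQR outlier rejection, mean ± 4σ bounds), minimum-score proper
  pairing, cross-consistent SAM emission.
* **`read_sim`** — paired-end read simulation (donor SNPs/indels,
  sequencing errors, duplicate pairs) with per-read ground truth, and a
  mapped-% / accuracy-% scorer with a positional tolerance window.
* **`gi_harness`** — grammar-based genetic improvement of the kernel: a
  population of parameter/code-variant assignments evolved under an
  *equivalent answers, then faster* fitness, where cost is a deterministic
  instrumented work count (LF steps + search-state expansions), with
  fastest-half/two-children selection and held-out validation of the
  winner.

The model at the core of the search: a read placement is scored by
accumulated penalty (mismatch 3, gap open 11, gap extension 4), and
*differences* — substitutions plus gap opens plus gap extensions — are
capped by `max_diff` (auto: 2 for ≤63 bp, 4 for 64–122 bp, 5 for
123–150 bp).  The search is best-first in penalty and returns all
co-optimal placements; the per-prefix bound `d[i]` (computed against an
index of the reversed reference) prunes states that can no longer fit the
budget.

## Worked example

Simulate a noisy 36 bp paired-end run, align it, combine into SAM, score
against the simulator's ground truth:

```r
library(gibarra)
cfg <- sim_config(genome_len = 50000, read_len = 36, n_pairs = 500,
                  err_rate = 0.01, insert_mean = 300, insert_std = 30,
                  rng_seed = 7)
genome <- simulate_genome(cfg)
sim <- simulate_reads(genome, cfg)
idx <- index_reference(list(genome))

res1 <- aln(idx, sim$reads1)
res2 <- aln(idx, sim$reads2)
res1[[1]]$hits
#>   refname pos strand score n_mismatch n_gap_open n_gap_ext cigar interval_size
#> 1  simref 498      +     3          1          0         0   36M             1

recs <- sampe(res1, res2, sim$reads1, sim$reads2)
write_sam(recs, list(genome), "example.sam")
m <- evaluate_alignments("example.sam", sim$truth, tolerance = 5)
```

The first read carries one sequencing error: it aligns uniquely at
position 498 (0-based) with one mismatch, penalty 3, MAPQ 37.  The fitted
insert model recovers the simulated distribution (`mean 298.0 sd 30.9` from
493 confident pairs against the true 300 ± 30), and the run scores
`mapped 99.30%, accuracy 100.00%` at a 5 bp tolerance — the unmapped
fraction is the handful of reads whose error count exceeds the 2-difference
budget at 36 bp.  The SAM output is standard v1.6:

```
sim000001  99  simref  499  37  36M  =  760  297  AGCGCC...  III...  NM:i:1
```

For the genetic-improvement loop, see `run_gi()`: given a grammar over the
kernel's tunable sites (e.g. pre-pass on/off, bound pruning on/off, budgets
and penalties), it evolves assignments whose answers are bit-identical to
the reference kernel but cheaper in instrumented work, and validates the
winner on held-out reads.

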