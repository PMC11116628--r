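---
title: "Calling deletions from long reads by two-layer clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling deletions from long reads by two-layer clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A deletion structural variant removes a reference segment of 50 bp or more.
A long read (kilobases) that spans the deleted locus leaves one of two
footprints in a coordinate-sorted alignment file:

* **intra-read evidence** — the aligner represents a small deletion directly
  as a `D` run in the read's CIGAR string;
* **inter-read (split) evidence** — a large deletion makes the aligner split
  the read into a primary and a supplementary alignment on the same
  chromosome and strand, bracketing a reference gap.

`delclust` turns both footprints into per-read *deletion signatures*, groups
signatures that describe the same event, and reports one call per surviving
group. The pipeline is `collect_signatures()` →
`layer1()` → `layer2()` → `filter_candidates()` →
`select_representative()`, wrapped by `call_deletions()`.

## Signature extraction

Records that are unmapped, secondary, or below MAPQ 20 are discarded (the
MAPQ gate applies per record, so a poor supplementary alignment is dropped
even when its primary passes). Within a CIGAR, every `D` run strictly longer
than 30 bp becomes a signature `(chrom, start, svlen, end)`.

Sequencing errors can shatter one deletion into several nearby `D` runs on
the same read. A left-to-right pass merges an adjacent pair whose reference
gap `start2 − end1` lies in `(0, 30]`; the merged record is
`(chrom, start1, svlen1 + svlen2, end2)` and immediately eligible to merge
again. Note the merged record deliberately keeps `svlen` as the *sum of the
deleted bases*, so `end − start` can exceed `svlen` by the gap width; `svlen`
is the deletion length everywhere downstream. A gap of exactly 0 cannot
arise from a valid CIGAR, and overlapping signatures (gap < 0) are kept
separate as the conservative choice.

For split evidence, each alignment record of a read becomes a segment
`(chrom, ref_start, ref_end, read_start, read_end, orient)`; query intervals
of reverse-strand records are flipped with the full read length so segments
order meaningfully along the original read. For each *read-adjacent* pair on
one chromosome and strand, the implied deletion length is

```
Distance = (ref gap between the segments) − (read gap between the segments)
```

and a pair with `Distance` in `[50, 100000]` yields a signature at the
reference gap. Only consecutive segments are paired — pairing all segments
would double-count through-going middle segments when a read splits more
than once. For a minus-strand pair the read-earlier segment sits
reference-later, so the reference-gap roles swap; the emitted signature is
identical to the forward representation of the same deletion. The upper
bound of 100 kb balances recall (large true deletions) against the false
positives that unbounded gaps admit; it is the `max_split_del` knob.

## Layer 1: clustering by position

Signatures are partitioned at `size_split = 2000` bp. The tie (`svlen`
exactly 2000) goes to the large class, so borderline events get the
positionally tighter window method.

**Large events** are sorted by start and swept with a 1500 bp window: the
window opens at the first unclustered site, captures every site starting
inside it, and — while the window beginning at the previous window's end
still contains a site — keeps extending the *same* cluster. We read the
sweep rule as chained extension rather than one-cluster-per-window because
the alternative would split sites a hundred bp apart across a window
boundary; `cluster_sliding_window(extend = FALSE)` exposes the other reading
for ablation. Window membership uses the start coordinate only, half-open
`[w, w + 1500)`.

**Small events** are clustered through a per-base deletion-depth profile:
each signature increments its span `[start, end)`, and every maximal run of
positions with depth ≥ 1 — the "peak" over the locus — becomes one cluster.
Depth 1 is the weakest possible peak definition and makes the method exactly
the connected components of touching-or-overlapping spans, which is what the
oracle tests assert. The profile is materialised as a difference array over
the span of the sites, one chromosome at a time, to bound memory.

Chromosomes are independent work items. The implementation processes them
serially; `threads` is accepted for interface compatibility and results are
required (and tested) to be byte-identical regardless, so scheduling can
never change output.

## Layer 2: clustering by length

The two homologous chromosomes can carry *different-length* deletions at one
locus — e.g. alleles of 108 bp and 216 bp. Position-only clustering fuses
them and the reported length becomes a meaningless average. Layer 2
therefore agglomerates each layer-1 cluster on deletion length alone
(position is already constrained): every signature starts as a singleton, a
cluster's length is the mean of its members' `svlen`, and the pair with the
smallest mean difference merges until two clusters remain. The survivors
merge into one candidate cluster only when their length-difference rate

```
rate = |len1 − len2| / max(len1, len2)
```

is strictly below 0.20; otherwise both are kept, one per allele. Ties in the
minimum difference are broken by smaller combined size, then smaller
combined mean, then smaller leftmost member start — arbitrary but fixed, for
determinism under input permutation. At most two candidate clusters are ever
produced per locus (two haplotypes).

## Support filtering and the final call

Support is the number of signatures in a candidate cluster (optionally
distinct reads via `unique_reads`). With threshold `T` (`min_support`,
default 10, suited to ~69X noisy long reads; presets 10/5/3/2/2 for
69X/35X/20X/10X/5X CLR-style and 3/2/1 for 28X/10X/5X HiFi coverage):

* a locus with **one** candidate cluster keeps it iff support ≥ `T`;
* a locus with **two** candidate clusters keeps each iff support ≥ `T/2`
  (real-valued half, no rounding).

The halved threshold matters because a heterozygous locus splits its
spanning reads between two clusters; demanding the full `T` of each would
silently drop both alleles (this is asserted directly in the tests).

The call for a surviving cluster is the member closest to the cluster
average, minimising `|start − mean_start| + |svlen − mean_len|` (the L1
metric is our choice; ties resolve to smaller start, then length, then read
name). The representative is an observed signature, never a synthesised
coordinate. Output is VCF 4.2 with `SVTYPE=DEL`, negative `SVLEN`, `END`,
`SUPPORT`, a `./.` placeholder genotype (no genotyping is attempted), and
the anchor-base convention: `POS` is the base before the deletion, so `POS`
numerically equals the 0-based deletion start used internally.

## The synthetic-data generator

`simulate()` produces a uniform-random ACGT reference, implanted deletion
truth sets and directly synthesized alignments (CIGAR, flags and SA tags
computed from the implants, not an external aligner) so that every pipeline
property is testable hermetically and byte-reproducibly from a seed.
Defaults emulate a noisy long-read run: 8 kb reads (typical CLR average),
deletion lengths cycling the standard benchmarking bands
[50,200), [200,500), [500,1000), [1000,2000), [2000,10000), coverage split
across two haplotypes, loci spaced ≥ 4500 bp (three clustering windows) so
loci never interact. Deletions ≥ 2 kb are emitted as split primary +
supplementary records whose implied `Distance` equals the implanted length;
shorter ones as a `D` op, optionally fragmented (`frag_prob`) into two runs
separated by a 10 bp matched gap to exercise the merge rule (the 10 matched
bases are borrowed from the following match op so query-consuming ops still
sum to the read length).

What the generator does **not** emulate: base-level sequencing errors and
their effect on breakpoint jitter, alignment ambiguity in repeats, chimeric
artefacts, coverage fluctuation, or any non-deletion variation. Passing the
zero-noise fixed-point test therefore shows the machinery is exact on clean
evidence — it does not bound performance on real noisy data, where breakpoint
scatter and false signatures dominate.

## Evaluation

`match_calls()` scores calls against truth with a Truvari-style rule: same
chromosome, start distance ≤ 500 bp, size similarity
`min(len)/max(len)` ≥ 0.7, matched greedily one-to-one with the closest call
claiming each truth allele. Heterozygous different-length truth records
count as two alleles. Reciprocal overlap, sequence comparison and genotype
checks of the real Truvari are not emulated. Undefined ratios (no calls, or
no truth) are reported as `NA`, not 0.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; the SAM reader converts from
  1-based, the VCF writer converts back. All interval tests in the package
  are half-open.
* Empty inputs flow through: empty alignment file → empty signature table →
  zero clusters → header-only VCF.
* A signature span beyond the declared chromosome end is clipped with a
  warning (it can only arise from inconsistent headers).
* Unsorted inputs to order-sensitive steps (`merge_intra_read`,
  `cluster_sliding_window`, `write_vcf`) are contract violations and raise
  errors rather than being silently re-sorted.
* `collect_signatures()` sorts its output by content, so results are
  invariant under permutation of file record order.

## Problem sizes used in the test suite

The bundled tests run the full caller on simulations of one 2 Mb chromosome
at 20–30× with 5–20 implanted loci (a few thousand reads), and check the
clustering operations against brute-force oracles on hundreds of random
instances of ≤ 50 sites. These sizes exercise every code path — multi-band
lengths, both evidence classes, het loci, fragmentation — while keeping the
suite quick; the algorithms themselves stream per chromosome and have no
desk-scale assumptions baked in.

## Known limitations

* Deletions only: no insertions, inversions, duplications, translocations,
  and no inter-chromosomal split pairs.
* No genotyping; the sample column is a placeholder.
* No local realignment or consensus refinement of breakpoints; the call is
  always an observed signature.
* Calls from different layer-1 clusters are never merged, even when their
  coordinates overlap.
* At most two alleles per locus are representable.
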