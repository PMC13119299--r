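---
title: "Permutation tests for region-set overlap: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation tests for region-set overlap: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionperm)
```

## The model

`regionperm` treats a genome as an ordered list of chromosomes with lengths
and an optional exclusion mask, and a peak set as a list of intervals in
BED convention: 0-based starts, half-open ends, strand ignored.  Two
intervals overlap when they share at least one base; intervals that merely
abut (`end == start`) do not.  The overlap statistic is *count-once*: the
number of query records touching at least one reference interval, so a
query peak spanning three reference peaks contributes one, and duplicated
query records contribute once each.  Query sets are never merged before
counting — reported counts always refer to input records, the convention
under which published peak-set sizes are record counts.  Total-pairs
counting and a minimum-overlap width are available behind arguments
(`count = "pairs"`, `min_overlap_bp`), not defaults.

The permutation null models the question "how many overlaps would a peak
set of this size and length composition produce if it had nothing to do
with the reference?"  Each permutation re-places every query region
independently and uniformly over the feasible start positions, preserving
the region count and the exact multiset of region lengths.  Two strategies
are offered:

* `per_chromosome` (default): each region stays on its chromosome.  This
  conditions on the chromosome composition of the peak set, which in real
  data carries biology (chromosome-scale differences in gene and peak
  density) that a genome-wide null would wrongly count as signal.
* `genome_wide`: the chromosome is re-drawn with probability proportional
  to the number of feasible start positions for that region's length.  This
  is the null under which the closed-form expectation
  `E[overlaps] = n_query · coverage(reference) / G` holds exactly for
  point (length-1) queries, which the test suite exploits as an analytic
  cross-check.

The strategy used is recorded in every result object, so runs are
self-describing.  With a mask, placements intersecting it are rejected and
re-drawn up to `max_retries = 1000` times per region; rejection sampling is
exactly uniform over feasible placements, and a region that cannot be
placed is a named error rather than a silent omission.  Randomized regions
may overlap one another: the null is independent placement, and forbidding
self-overlap would make dense sets an intractable packing problem while
changing the null in a way that is hard to characterize.

## The tests

**Single-set enrichment** (`perm_test`): observed count `o`, null counts
`o_1 … o_N`, summarized by `z = (o − mean)/sd` (sd with denominator
`N − 1`) and the add-one empirical p-value `(1 + #{o_i ≥ o})/(N + 1)`.
The add-one estimator never returns zero — its floor is `1/(N + 1)`, e.g.
`1/501` at 500 permutations — and avoids the optimistic bias of `#/N`.
The result also carries the smallest count whose empirical p would be
≤ 0.05 under the realized null: the significance-threshold bar of the
standard enrichment plot, which `plot()` renders as a null histogram with
observed (green), null-mean (black) and threshold (red) lines.

**Differential test** (`diff_perm_test`): statistic
`o(Q1, R) − o(Q2, R)`; per permutation *both* query sets are independently
randomized and the difference of their null counts recorded.  Randomizing
both sets is the symmetric choice and makes the null exactly exchangeable
with the observed statistic when neither set is associated with the
reference; a `randomize = "first_only"` variant (second count held fixed)
exists for the asymmetric question "is Q1 enriched relative to a fixed
baseline?", and the variant used is echoed in the result.  With identical
inputs the observed difference is exactly 0 by construction, not
statistically.

**Alternatives**: one-sided p-values mirror each other; the two-sided p is
`2·min(one-sided)` capped at 1 — conservative and standard for discrete
permutation nulls.  A z-derived normal-tail p (`p_z`) is reported alongside
the empirical p because both conventions appear in practice; the empirical
p is the primary quantity and the only one with finite-sample guarantees.

**Degenerate nulls**: when every permutation gives the same count
(`sd = 0`, e.g. an empty reference) the z-score is reported as `NA` — an
explicit undefined marker, never ±Inf — while the empirical p remains
valid.  This is a reportable state, not an error.

**Colocalization**: `colocalization_table` builds the 2×2 table of two
peak sets against companion sets (`mode = "any"` is overlap with the union
of companions; `"all"` requires every companion), and `yates_chi2` applies
the continuity-corrected χ² closed form with 1 df, refusing tables with a
zero margin.  χ² with Yates correction is the only contingency test
offered; per-peak (not per-base) counting is used because the rows are
peaks.  No multiple-testing correction is applied inside any test; the
manifest runner can append Benjamini–Hochberg adjusted columns across a
batch, off by default, and raw p-values are never overwritten.

## Reproducibility scheme

One root seed governs everything.  Permutation draw `i` of stream `s`
re-seeds a Mersenne-Twister from a deterministic hash of
`(seed, s, i)` (kept below 2³¹), so draws are independent of evaluation
order and of any parallelism, the differential test's two query sets use
disjoint streams (1 and 2), and `null_distribution(...)[i]` is identical
to `overlap_count(randomize_regions(..., draw_index = i), reference)` —
an identity the test suite asserts.  All functions restore the caller's
RNG state.  In the manifest runner, job `k` derives its policy seed from
the manifest seed and `k`, so re-running a manifest reproduces every
numeric field bit-for-bit.

## The synthetic generator

`make_scenario()` emulates the statistical skeleton of ATAC/ChIP peak-set
comparisons at desk scale: a 2-chromosome genome of 10 + 5 Mb, 500
reference peaks and 300 query peaks with lengths uniform in 200–600 bp.
These defaults give a background query–reference collision rate of a few
percent — large enough that the null is non-degenerate, small enough that
planted signal dominates — and run in milliseconds.  Each query region is,
independently with probability `f`, anchored to a uniformly chosen
reference peak: its start is jittered up to ±200 bp (default) and then
clipped so at least 1 bp of overlap with the anchor is guaranteed, making
`f` an exact lower bound on the expected overlap fraction and giving clean
analytic expectations for power accounting.  The planted/background truth
travels with each region as a `planted` column.

What the generator does *not* emulate: GC or accessibility-matched
backgrounds, clustered or telomere/centromere-depleted peak placement,
peak-width/signal correlation, and inter-peak spacing structure of real
chromatin data.  Calibration and power results on these scenarios
therefore validate the *machinery* — that the tests are correctly sized
and can detect planted association under their own null model — not that
the per-chromosome uniform null is an adequate biological background for
any particular real data set; choosing an appropriate mask (e.g. excluding
unmappable regions) remains the analyst's responsibility.

## Problem sizes in the test suite

The suite's Monte-Carlo experiments use the default desk-scale scenario:
1000 null replicates at 200 permutations for single-set type-I error
(observed rejection within [0.035, 0.065] at α = 0.05, the 99% binomial
band; the exact expected rate with the add-one estimator is
`10/201 ≈ 0.0497`), 500 replicates for the differential null, 200 and 100
replicates for the f = 0.5 and f = 0.9-vs-0 power experiments, 2000 draws
for the analytic-null comparison, and ≥ 200 random instances for exact
brute-force agreement of the interval algebra.  These sizes put each
experiment's false-alarm probability around or below 1% while keeping the
whole suite around two minutes on one CPU.

## Known limitations

* Coordinates are stored as doubles internally; exactness holds far beyond
  chromosome scale (< 2⁵³), but inputs are validated as integers.
* The rejection sampler degrades when the mask leaves only a sliver of
  feasible placements; `max_retries` then errors out rather than biasing
  the null.
* `allow_self_overlap = FALSE` (non-overlapping placement) is deliberately
  not implemented (see above).
* Strand-aware overlap, nearest-feature distances, Jaccard statistics,
  base-pair-level enrichment, circular rotation and block-bootstrap nulls
  are out of scope.
* The two empirical p conventions (empirical vs z-derived) can disagree in
  the extreme tails; the package reports both rather than interpolating.
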