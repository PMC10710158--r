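---
title: "Building CNV regions and scanning them for population differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building CNV regions and scanning them for population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrpop)
```

## The problem

Read-depth CNV callers such as CNVnator emit one call set per sequenced
individual. To say anything at the population level — which genomic
segments are copy-number variable in a breed, which are shared across
breeds, and which differentiate populations — the per-sample calls must be
condensed into *copy number variation regions* (CNVRs): non-redundant
intervals supported by recurrent, reciprocally overlapping calls. This
package implements that condensation, the Vst differentiation scan over
the resulting regions, and positional annotation, for multi-breed
whole-genome sequencing cohorts (the motivating use case is horse breed
panels aligned to EquCab3.0, but nothing is horse-specific).

## Coordinate conventions

Every interval inside the package is stored 1-based-start, half-open
`[start, end)`, so `length = end - start` everywhere, with no `±1`
adjustments scattered through the code. The convention is anchored on the
worked regions the pipeline must reproduce: a deletion printed as
89,585,201–89,632,900 bp with length 47,699 bp satisfies
`end - start` exactly. Consequences:

* CNVnator `chrom:start-end` regions are taken as start/end directly.
* BED input shifts only the start (`internal start = BED start + 1`); BED
  output shifts it back. `write_cnvr_bed()` and `read_bed_calls()` are
  exact inverses on coordinates.
* 1-based *inclusive* interval tables (QTL tables, published CNVR lists)
  convert with `end + 1`.

## From calls to CNVRs

The construction follows a fixed stage order, each stage a pure function:

1. **Length and placement filter** (`filter_calls()`): calls shorter than
   `min_length` (default 1,000 bp; a call of exactly 1 kb is kept — the
   filter removes *less than* 1 kb) or on chromosomes outside the genome's
   placed set are dropped, with counts by reason.
2. **Recurrence filter** (`recurrence_filter()`): a call survives only if
   at least `min_individuals` (default 2) *distinct* samples of its own
   population carry a call — of either CNV type — matching it at 50%
   reciprocal overlap. Kept-status is decided on the full call set before
   any removal, so the filter is order-independent. The matching criterion
   reuses the only overlap criterion the pipeline defines (reciprocal
   overlap), rather than inventing a second one.
3. **Breed merge** (`merge_reciprocal()` per population): calls are
   vertices, pairs with ≥ 50% reciprocal overlap *on both sides* are
   edges, and each connected component becomes one CNVR (single linkage).
   The threshold is closed: exactly 50% merges. Chains where A~B and B~C
   but A≁C still merge — this makes the output a partition of the calls,
   the property every downstream count relies on.
4. **Cohort merge** (`merge_breed_to_cohort()`): breed CNVR intervals are
   pooled and re-merged under the same criterion; member calls, breed
   provenance and the Dup/Del/Mixed class are carried through
   transitively.

A CNVR's span is the *union* of its member spans. Spans of distinct CNVRs
may therefore overlap by less than 50% reciprocally; trimming to
intersections was the alternative and was rejected because it can produce
spans that no longer cover their members.

Classification is by member CNV types: all gains → `DUP`, all losses →
`DEL`, both → `MIXED`. The type of each member is re-derived from its
copy number (`CN < 2` loss, `CN > 2` gain); when a caller's text label
disagrees with its read depth, the copy number wins, because the copy
number is what enters Vst. A call at exactly CN 2 carries no variant
signal and is routed to the reader's error report instead of the call
table. Readers never drop lines silently: for every input,
`rows kept + error records = lines read`.

Summaries report *both* counting units — per-CNVR class counts (which sum
to the CNVR count) and per-member call type counts (which can exceed it) —
because published per-breed tables in this field mix the two units and
only clearly labelled output avoids the ambiguity.

## The Vst scan

For each autosomal cohort CNVR, each sample receives one copy number: the
coverage-length-weighted mean of its overlapping calls, with uncovered
bases contributing the diploid baseline 2 (a sample with no call is
exactly 2.0). Continuous, read-depth-derived copy numbers are used rather
than rounded integer genotypes; rounding discards the dosage signal the
variance statistic feeds on.

For two populations A and B with `n_A`, `n_B` samples:

$$V_{st} = \frac{V_T - V_S}{V_T}, \qquad
V_S = \frac{n_A V_A + n_B V_B}{n_A + n_B}$$

where `V_T` is the variance of the pooled copy numbers and `V_A`, `V_B`
the within-population variances. All variances use the population
estimator (denominator *n*): the statistic is a variance *decomposition*,
and mixing an unbiased pooled estimator with weighted within-group
estimators breaks the identity it relies on. Numerical policy:

* `V_T = 0` (all samples identical) defines `Vst = 0` — zero variance is
  zero differentiation, not an undefined value.
* Slightly negative values (possible with unbalanced groups) are clamped
  to 0; the top tail, which is all the scan thresholds on, is unaffected.
* The statistic is symmetric in (A, B), invariant to adding a constant to
  all copy numbers and to positive rescaling; the test suite checks these
  properties against an independent loop-based implementation.

Putatively differentiated regions are the empirical top fraction
(default 1%) of each pair's own Vst distribution, using the nearest-rank
definition `k = ceil(f·n)` with ties at the threshold all selected. The
threshold is computed separately per population pair — empirical
distributions differ between pairs, so a shared threshold would be
meaningless.

## Positional annotation

`annotate_context()` assigns each CNVR one category by fixed precedence —
exonic > splicing > 5'UTR > 3'UTR > intronic > upstream > downstream >
intergenic — over all features of all transcripts, the convention of
ANNOVAR-style positional annotators. Defaults follow the same tradition:
1 kb strand-aware up/downstream windows, 2 bp splice windows at intron
boundaries. "Exonic" means coding sequence for coding transcripts and
whole exons for non-coding ones; UTRs are taken from the annotation file
when present and otherwise inferred as exonic sequence outside the coding
span. Independently of the category, every gene whose *gene body*
overlaps the CNVR by ≥ 1 bp is reported — this is the gene set used for
common/breed-specific partitions and for the across-pair intersections of
selected genes.

QTL-table and published-CNVR comparisons count a hit at ≥ 1 bp
intersection by default; this is deliberately permissive (the comparison
is positional, not proportional) and both a minimum-bp and a
minimum-fraction knob are exposed for stricter use.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the statistical structure the scan assumes:
per-locus, per-population distributions over integer copy-number states
0–6, independent draws per sample, calls emitted for non-reference states
with

* Gaussian boundary jitter (default sd 200 bp, applied independently to
  both breakpoints, resampled if the interval degenerates, clipped to the
  chromosome) — 100 bp-binned read-depth callers place breakpoints with
  errors of this order;
* Gaussian copy-number noise (default sd 0.2), clamped to stay on the
  call's own side of the diploid baseline so a noisy deletion is not
  emitted as a neutral or duplicated call;
* false-negative suppression (default 5% of true non-reference states
  emit no call);
* decoy calls (default ~5 per sample) uniform on the genome, log-uniform
  1–50 kb, states 1 or 3 — these exercise the recurrence filter, which
  removes them because they almost never recur reciprocally.

The default cohort is two populations of 50 samples and 100 disjoint
loci (5–50 kb, log-uniform), of which 1% are planted as strongly
differentiated: carrier frequency 0.95 of a homozygous deletion in one
population against 0.95 reference in the other, giving an analytic
expected Vst of 0.81. Background loci share one distribution across
populations (carrier frequency 0.1–0.5 of one alternative state), i.e.
expected Vst 0. `expected_vst()` computes the analytic value from the
distribution moments, and `match_cnvrs_to_loci()` links recovered CNVRs
back to planted loci by reciprocal overlap, so empirical-vs-expected
error is measurable end to end.

Deliberately *not* emulated: read-level data (no FASTQ/BAM), CNVnator's
binning artifacts, linkage between loci, and Hardy–Weinberg allelic
structure beneath the copy-number states (Vst consumes CN values
directly, so allele-level structure would add complexity without changing
what is tested). Passing recovery tests on this simulator therefore
demonstrates the *pipeline logic* — filtering, merging, matrix
construction, thresholding — not robustness to caller-specific artifacts
on real genomes.

All randomness flows from the single seed in `sim_config()`; the
generator saves and restores the caller's RNG state, and two runs from
one seed are byte-identical on disk.

## Problem sizes in the test suite

The suite validates the merge against a brute-force pairwise-edge
connected-components oracle on 200 random instances of up to 500 calls,
the Vst implementation against a loop-based oracle on 1,000 random
instances (agreement within 1e-12), and parameter recovery on the default
synthetic cohort (2 × 50 samples, 100 loci) — sizes chosen so the entire
suite exercises every stage in well under a minute while keeping the
oracle comparisons exhaustive at the scales where brute force is exact.

## Known limitations

* Sex chromosomes carry no ploidy correction; following the autosomes-only
  scope of the Vst scan, non-autosomal CNVRs are simply excluded from the
  copy-number matrix.
* Breakpoint resolution is inherited from the upstream caller; the merge
  does not refine boundaries below the caller's bin size.
* Table-level reproduction of published per-breed Dup/Del/Mixed counts is
  out of reach because the counting unit of those tables is ambiguous
  (their class counts exceed their CNVR counts); both units are emitted
  instead.
* No VCF ingestion and no liftover: calls must already be on the target
  assembly, in CNVnator text or BED-like form.
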