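---
title: "Replicate aggregation for exhaustive peak discovery: models and methods"
author: "iceberg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate aggregation for exhaustive peak discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceberg)
library(GenomicRanges)
```

## The problem

Genome-wide binding assays (CUT&RUN, ChIP-seq) read out protein-DNA
association through sequencing of released fragments, and are noisy: two
well-behaved replicates of the same experiment typically share only a
fraction of their called peaks, and the shared fraction *shrinks* as more
replicates are added. Conventional practice reacts with stringency — call at
a strict FDR, keep peaks reproduced in 2 of 3 replicates — which suppresses
false positives at the price of discarding most genuine but rare binding
events. For dynamic factors such as transcriptional co-factors, the strictly
concordant set across many replicates can collapse to a few dozen regions
while thousands of real events are each seen in only a handful of
replicates.

The aggregation strategy implemented here turns the replicate collection
into one deep, uniform observation instead: every replicate is downsampled
to the depth of the smallest, the equal-depth samples are pooled into an
aggregate track, and peak calling is performed on the aggregate against a
pooled IgG control. Random noise averages into a flat background while
consistent signal — however rare per replicate — accumulates. The procedure
is repeated with independent downsampling draws ("splits", default 3), and
a region is accepted when

1. it is called in a majority of the aggregates (default 2 of 3) at
   q < 0.05, and
2. it overlaps at least one peak called in at least one *individual*
   replicate at relaxed stringency (p < 0.01),

the second condition guarding against artifacts of pooling itself. The
final peak set carries, for every peak, the number of individual replicates
that detect it at strict stringency — its empirical *detection probability*
— from which peaks are binned into probability groups, including the USR
group ("undetectable in single replicates": never called alone at q < 0.05
yet supported at p < 0.01).

## The peak caller

The built-in caller is a Poisson local-background scanner in the MACS2
family, deliberately *not* bit-compatible with any external tool; external
narrowPeak/BED output can be substituted anywhere a peak set is consumed.
Sliding windows (width 50 bp, step 25 bp) are scored by the number of
fragments overlapping them by at least one base. The background rate for a
window is

$$\lambda = \max\left(\lambda_{genome},\ \lambda_{s}:\ s \in \{w, 1\,\mathrm{kb}, 10\,\mathrm{kb}\}\right),$$

where each $\lambda_s$ is estimated from the control fragment count $c_s$ in
a window of size $s$ centred on the scored window:

$$\lambda_s = (c_s + c_0)\,\frac{T}{C}\,\frac{w + \bar L}{s + \bar L}.$$

$T/C$ is the treatment/control depth ratio, $c_0 = 0.5$ a pseudocount so an
empty control window never yields a zero rate, and $(w+\bar L)/(s+\bar L)$
— with $\bar L$ the mean fragment length — rescales overlap-based counts
between scales (a fragment of length $\bar L$ overlaps a window of size $s$
with probability proportional to $s + \bar L$, so naive $w/s$ scaling would
underestimate window-scale rates by several fold and destroy calibration).

Two scale choices matter and were settled during design:

* **With a control, the window scale itself is included.** Artifact
  hotspots — point sources present in treatment and IgG alike — are diluted
  out of the 1 kb / 10 kb estimates; only the window-scale control count
  rises with them. Including it makes shared artifacts cancel exactly, which
  the synthetic-data tests verify (hotspots are called when the caller runs
  without a control, and never appear in the final aggregated set).
* **Without a control, only the largest local scale is used.** When the
  background is estimated from the treatment itself, small-scale estimates
  would measure the signal as its own background and suppress everything.

Window p-values are the Poisson survival probability $P(X \ge \text{count})$
(floored at `1e-320` against underflow at aggregate depth); q-values are
Benjamini-Hochberg across all tested windows (delegated to
`stats::p.adjust`, with the step-up definition re-verified against a
brute-force oracle in the tests). Significant windows are merged within
100 bp, peaks shorter than 50 bp dropped, and the summit is the midpoint of
the highest-count window. One call is made at the loosest stringency a
workflow needs and filtered downward with `thresholdPeaks()`, so nested
thresholds yield nested peak sets by construction.

On null data (treatment and control drawn from the same uniform
distribution) the fraction of windows significant at q < 0.05 stays below
0.05 within a three-sigma binomial tolerance across 20 seeded simulations —
the caller's calibration contract.

## Coordinates and interval algebra

On disk all interval formats are BED-convention 0-based half-open; in
memory everything is a `GRanges` (1-based closed), with conversion only at
the file boundary. This deviates from an all-0-based internal design on
purpose: the package's containers and algebra *are* the Bioconductor stack
(`GenomicRanges`, `IRanges`), and fighting its conventions internally would
buy nothing. Merging, multi-set segmentation (`overlapMatrix()`), and
"called in at least x datasets" extraction (`regionsAtLeast()`) are built on
`reduce()`, `disjoin()` and coverage; all of them are tested for exact
agreement with an independent per-base boolean-array oracle on hundreds of
random instances. Merging with gap 0 joins book-ended intervals, matching
the behaviour of the standard genome-arithmetic tools; overlap is always
"at least one shared base", with no reciprocal-fraction option.

Two definitional notes. `exactly[x]` in a decay curve is the *count
subtraction* `at_least[x] - at_least[x+1]`, as in the original analysis —
region counting, not region identity tracking — and can in principle go
negative when merging fuses regions; such values are clipped to zero with a
warning. Probability groups generalise the published 20-percentage-point
bins to any replicate number via right-closed percentage intervals,
reproducing the published groupings exactly at n = 25 and n = 10.

## Seeding and determinism

Reproducibility is a first-class contract: the method is about replication.
A single run seed drives everything through `childSeed()`, a documented
platform-stable derivation (polynomial rolling hash of a label, mixed with
the parent seed modulo a prime below $2^{31}$) that gives every
(replicate, split, purpose) combination its own stream. Splits are
independent downsampling draws, not disjoint partitions — the smallest
replicate, which sets the common depth, cannot be partitioned three ways —
so a replicate at exactly the plan depth contributes identical content to
every split. Two runs with equal inputs and seed produce byte-identical
output files.

## Saturation modelling

Build curves record the aggregate peak count after each replicate addition,
for several random addition orders (default 5) and every split. Polynomials
of order 1-5 are fitted by least squares to all (order, split) points
jointly. Because $R^2$ of nested fits never decreases with order, "take the
highest $R^2$" degenerates to "always order 5"; the default selection takes
the *lowest* order within $\Delta R^2 = 10^{-3}$ of the order-5 fit
(configurable: adjusted $R^2$, or a fixed order). Note a consequence
verified in the tests: data generated exactly from a cubic whose quadratic
term dominates its shape can legitimately select order 2 under this
criterion — parsimony is the point — so exact-coefficient recovery is
asserted on the fixed-order fit.

The plateau is the smallest positive root of the fitted model's first
derivative, found by dense sign-scan plus bisection to $10^{-9}$, within an
extrapolation horizon of three times the observed replicate count; a
plateau beyond the horizon is reported as not reached rather than
extrapolated. The model value at the plateau estimates the total
discoverable peak count, and `fractionDiscovered()` expresses the observed
count against it. Applied to the published regression coefficients, the
machinery reproduces the published reading: the fifth-order model's
derivative vanishes between 9 and 10 replicates, the third-order model's at
about 30, with 25 replicates having discovered over 93% of the predicted
total.

## The synthetic-data generator

The generator is the package's test substrate and emulates exactly the
structure the pipeline exploits, with defaults chosen once as the study
conditions:

* one 2 Mb chromosome, 200 disjoint 300 bp binding sites;
* a per-site occupancy probability from a two-component mixture — 25% of
  sites at 0.8-1.0 (stable, chromatin-mark-like), 75% at 0.02-0.3 (rare,
  dynamic-factor-like) — so both regimes of the published decay behaviour
  are present;
* per replicate, each site is active with its occupancy probability
  (Bernoulli, independent across replicates); active sites emit
  Poisson-distributed fragments (mean 40, scaled by a per-replicate
  efficiency jitter of 0.8-1.2) centred on the site with positional spread
  sd = site width / 4, and fragment lengths of 170 ± 30 bp (minimum 50);
* 50,000 uniform background fragments per replicate;
* 3 artifact hotspots depositing Poisson(60) fragments per replicate into
  treatment *and* IgG controls — the IgG replicates contain background and
  hotspots only;
* 25 treatment replicates, 10 IgG replicates, seed 1234.

The Bernoulli site-activity model collapses the two biological readings of
detection probability (fraction of bound cells; residence time) into the
one thing a bulk assay observes. What the generator does *not* model —
sequence content, mappability, PCR duplication, GC bias, broad-domain
marks — bounds what the tests show: passing them demonstrates that the
decision rule, calibration and analytics behave as designed on data with a
known answer, not that any particular biological dataset will saturate at a
given replicate count.

At this scale a full 25-replicate aggregation run (three aggregates, all
individual support calls) completes in about two minutes on one CPU; the
test suite uses this default-scale experiment once and caches it, and a
compact 6-replicate / 600 kb configuration elsewhere. On the default-scale
experiment the pipeline recovers every planted site of occupancy
probability at least 0.8, ranks site detection frequency against planted
probability at Spearman rho above 0.9, excludes all hotspots, and its
recall of planted sites exceeds the best 3-of-3 strict-threshold replicate
combination by a wide margin at precision above 0.9.

## Chromatin-loop integration

Loop files (BEDPE, two anchors and per-replicate counts) are filtered by
the published criteria: present in both biological replicates, size
strictly greater than 5 kb (anchor1 start to anchor2 end), mean count at
least 2 (inclusive, per the wording). "Present in both replicates" is
operationalised as a positive count in both count columns — the upstream
loop-caller's output format does not pin this down, and an anchor-overlap
matching mode across two files is deliberately left out of scope of the
current release. A loop joins a probability group when at least one anchor
overlaps one of the group's peaks (a loop may count in two groups through
its two anchors); per group the package reports loops per peak, the
percentage of peaks in at least one loop, and loop strength/size vectors
for external statistical testing. Distribution comparisons
(Kruskal-Wallis and friends) are intentionally not reimplemented here.

## Degenerate inputs and edge policies

* One replicate, or fewer than three splits, run with loud warnings —
  aggregates then resample a single replicate and the majority vote
  weakens.
* A zero-depth control is an error that points to the no-control mode;
  an empty treatment is an error.
* An empty called set has undefined precision (reported `NA`, excluded
  from F1 means and counted) and recall 0; an empty gold set is an error.
* The individual-call IgG control defaults to the smaller of 5 million
  fragments (the published choice, matching single-replicate library
  scale) and the pooled IgG depth, so small simulated pools pass through
  unchanged.
* Tie-breaks: the summit takes the first highest-count window; random
  combination selection sorts drawn indices for stable output order.

## Problem sizes used in validation

The acceptance-style checks run the default-scale simulated experiment (25
replicates, 200 sites, 2 Mb) once, 200 random interval-algebra instances on
chromosomes up to 100 kb, 20 null-calibration simulations of 10,000
fragments on 1 Mb, and two seeded demonstration pipelines (6 replicates,
600 kb); these sizes were chosen so the full suite exercises every
published-scale mechanism while remaining comfortable on a laptop.
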