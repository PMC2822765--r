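---
title: "Methods: copy-number indel calling and deletion-marker relatedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number indel calling and deletion-marker relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cghindels` implements an end-to-end analysis for two-color array
comparative genomic hybridization (aCGH) screens of selfing nematode
isolates against a reference genome: per-array intensity normalization,
copy-number segmentation and indel calling, a cross-strain catalog of
deletion and amplification alleles, parsimony trees over deletion
markers, and a multilocus linkage-disequilibrium test.  This vignette is
the package's account of the underlying models, the choices made where
the design was genuinely open, and what the synthetic-data validation
does and does not establish.

## The measurement model

Each probe on an exon-centric tiling array reports the fluorescence of a
test strain and of the reference, and the analysis operates on the
per-probe ratio $M = \log_2(\text{test}/\text{ref})$.  For copy-neutral
sequence $M \approx 0$; homozygous deletion of the probed sequence pushes
$M$ strongly negative (in practice below $-2$, i.e. less than a quarter
of the reference abundance once hybridization noise and partial
cross-hybridization are folded in), and amplification pushes it above
$+1$.  Probe-level noise is well approximated as Gaussian around the
segment mean, which is the assumption the segmentation's t-tests build
on.

Two-color arrays show a smooth intensity-dependent dye bias, so before
segmentation each array is normalized by robust LOWESS: $M$ is regressed
on the mean log intensity $A = (\log_2 \text{test} + \log_2
\text{ref})/2$ (the standard MA convention; the covariate is not stated
in the original protocols, and intensity is the standard choice for
two-color data) with smoothing span $f = 0.4$ and 3 bisquare
reweighting iterations, and $M$ is replaced by the residuals.
Normalization is strictly per array; aberrant probes are sparse and
down-weighted by the robust loss, so a planted 5-probe deletion at $-3$
among 10,000 probes moves the local fit by well under 0.05.  One pass
removes a smooth cubic bias of amplitude 0.5 down to a residual linear
trend below 0.02 per $A$-unit; a bias that strong leaves a lack-of-fit
ripple of roughly 2% of its amplitude (the span covers 40% of the data,
so sharp curvature is flattened), which is why the operator is idempotent
to better than 0.01 only once the bias is mostly gone.  Profiles loaded
without raw intensities (e.g. from a series-matrix export) skip this
stage.

## Segmentation by bottom-up t-test merging

Every probe starts as its own segment.  For each pair of adjacent
segments a Welch two-sample t-test asks whether their ratios share a
mean; the pair with the *largest* P (the most plausible merger) is
merged, the merged segment's statistics are updated, fresh tests against
its two neighbours are pushed, and the process repeats until the largest
remaining P falls below a critical value (default 0.05).  The pending
tests live in a max-heap over a doubly linked list of segments, with
lazy invalidation: stale entries are discarded when popped, which is
behaviourally identical to eager updating (the test suite checks the C++
implementation against an eager quadratic re-scan, exact agreement).
Ties on P merge the leftmost pair first, so runs are deterministic.
Chromosomes are segmented independently and segments never span them.

Numerical choices:

* **Small-segment variance.** A singleton has no variance and a 2-probe
  segment has one degree of freedom.  Comparisons involving such
  segments substitute a global noise variance — the squared scaled
  median absolute successive difference of the chromosome's ratios,
  $\hat\sigma = \mathrm{median}|x_{i+1}-x_i| / (\sqrt{2}\,\Phi^{-1}(3/4))$
  — and become z-tests.  The successive-difference estimator is robust
  to the (sparse) true copy-number jumps.
* **Zero-variance ties.** Two segments with identical constant values
  compare at P = 1 and merge first; this is the limiting behaviour and
  makes noise-free data collapse to exact runs.
* **Accepted-P sequence.** The sequence of accepted merge P values is
  *not* monotone: merging increases the power of later tests, so an
  accepted P can exceed an earlier one.  The meaningful invariant is
  heap correctness (identical behaviour to the eager re-scan), which is
  what the tests assert.

After merging stops, each segment receives a one-sample test of its mean
against 0.  Segments with $P \le 0.01$ are labeled deletions when the
mean log2 ratio is $\le -2$ and amplifications when it is $\ge +1$;
everything else is normal.  Adjacent same-label segments are then merged
and their statistics recomputed, and aberrant segments spanning fewer
than 3 probes are relabeled normal — except 2-probe deletion candidates
whose two ratios both sit at or below $-2$, which are kept (with one
degree of freedom a t-test can essentially never reach $P \le 0.01$, so
this class of unambiguous 2-probe events is admitted on the strength of
the ratios themselves; they are about 1% of calls in practice).

The classification test, like the merge test, uses the global noise SD
for segments below 3 probes.  This departs from treating only
singletons specially, for a reason the implementation made obvious:
merging at $\alpha = 0.05$ leaves occasional chance boundaries inside
long true aberrations, and if the 2-probe slivers between them are
tested with a 1-df sample variance they come out "normal", splitting a
single long amplification into several calls.  With the global-variance
z-test the slivers are labeled consistently with their neighbours, the
same-label merge restores the whole event, and isolated small segments
are still removed by the minimum-probe filter.  The residual failure
mode — a single interior probe whose ratio falls below the mean cutoff,
which no labeling rule can bridge — survives only in very long
amplifications near the cutoff and is visible in the review export.

Each aberrant segment becomes one call: the breakpoint probes are its
leftmost and rightmost probes; the indel length runs from the middle of
the left breakpoint probe to the middle of the right one; and flanking
probes mark where normal ratios consistently reappear outside the call.
"Consistently" is operationalized as: scanning outward, the flank is the
first probe past the threshold (above $-0.8$ for deletions, below
$+0.5$ for amplifications) such that at least 2 of the 3 probes beyond
it also pass (fewer when the chromosome ends; a candidate with no
outward followers is accepted).  The 2-of-3 rule is a choice — no
quantitative rule is published — and on synthetic data it reproduces the
reported qualitative behaviour that flanks are usually adjacent to their
breakpoints.  Manual breakpoint curation is deliberately out of scope;
instead every call is exported with ±10 probes of context for human
review.  P values are reported raw, without multiple-testing correction.

## The cross-strain catalog

Two calls of the same kind on the same chromosome carry the same allele
if they overlap and both breakpoint probes agree within 3 probes
(distance in probe-index units, since the rule is about array
resolution, not base pairs), or if both breakpoints of one call fall
inside the span of the other's flanking probes (the relaxed rule for
ragged breakpoints; an absent flank at a chromosome end extends the span
to the end).  Loci are the connected components of this relation —
union-find closure, since a pairwise rule alone does not define locus
identity; chains that transitively join calls farther apart than the
tolerance are permitted and flagged.  A locus's canonical breakpoints
are the modal breakpoints of its members (ties to the smaller index).

Deletion loci become binary presence/absence characters over the
isolates; amplifications are excluded from the marker matrix by default
(they are less robustly detected, and the true genomic position of
amplified copies is unknown), and the reference strain is never a row —
ratios are isolate/reference, so it carries no markers by construction.
Genes are annotated against the span from the left breakpoint probe's
start to the right breakpoint probe's end: contained genes are wholly
affected, intersecting ones partially.  Arm/center assignment uses the
midpoint of the left breakpoint probe against supplied arm intervals,
with the X chromosome always its own region.  The statistics battery
mirrors the field's standard tests: chi-square goodness-of-fit of
per-chromosome counts against probe-share expectations, one-way ANOVA of
raw (untransformed) lengths by strain and by chromosome with groups of
fewer than 2 observations dropped with a warning, and Welch's two-sample
t-test of lengths on arms versus centers-plus-X.  Lengths are
midpoint-to-midpoint, and an indel found in several strains counts once
per strain.

## Parsimony trees and bootstrap support

Deletion markers are analysed under two parsimony criteria:

* **Wagner** parsimony counts the minimum number of state changes with
  gains and losses equally weighted and no assumed ancestral state.  It
  is computed by Sankoff dynamic programming with unit costs, exact on
  binary characters for any (also multifurcating) tree and independent
  of root placement.
* **Camin-Sokal** parsimony treats the deletion as the derived state and
  forbids reversal: the set of carriers on the tree must be a union of
  subtrees under a hypothetical all-absent ancestor, and each maximal
  carrier-pure subtree costs one gain.  Scoring therefore needs a root:
  the exported scorer attaches the ancestor at the tree's root node, and
  the search treats the ancestor as an extra taxon (so root placement is
  itself optimized) and strips it from reported trees.  Camin-Sokal
  never scores below Wagner on the same tree.

Search strategies: exhaustive enumeration by stepwise insertion (every
unrooted topology exactly once; practical to 8 taxa), branch-and-bound
(exact — the score of a partial tree only grows as taxa are added, so
pruning at the incumbent keeps all ties), and a heuristic of stepwise
addition under 10 seeded jumbled input orders with
nearest-neighbour-interchange refinement to a local optimum.  All three
return every tied-optimal tree found, deduplicated by bipartition set.

Bootstrap support resamples loci (columns) with replacement, re-runs the
search per replicate, and counts bipartitions across replicates; when a
replicate has $k$ tied optimal trees each contributes $1/k$ — the
standard fractional convention, chosen because ties are common with
binary markers.  The consensus keeps strict-majority (>50%)
bipartitions, which are automatically mutually compatible, and the
replicate archive supports frequency queries for arbitrary strain groups
(so support can be quoted for groups absent from the consensus, and a
consensus from one method can be annotated with the other method's
frequencies).  With the heuristic inside the bootstrap, support values
inherit a small downward bias if the search misses optima; at the
package's problem sizes the heuristic matches branch-and-bound in every
test.

## Multilocus linkage disequilibrium

The standardized index of association compares the variance of pairwise
strain distances with its expectation under free recombination.  For $n$
strains and $l$ loci, $d$ is the per-pair count of mismatched loci,
$V_D$ its population variance over the $n(n-1)/2$ pairs, and $V_e =
\sum_j h_j$ with $h_j = \frac{n}{n-1}\bigl(1 - \sum_{\text{alleles}}
p^2\bigr)$ the unbiased single-locus diversity.  Then

$$I_A^S = \frac{V_D/V_e - 1}{l - 1},$$

0 in expectation at linkage equilibrium, positive when loci travel
together, as they do in a predominantly selfing species.  Constant
columns are rejected (they contribute zero diversity and make the
normalization ambiguous); callers drop fixed loci first.  Significance
comes from a Monte Carlo null built by independently permuting each
locus's alleles among strains — the only reading of "resampling loci to
scramble their order" that actually destroys inter-locus association
while preserving allele frequencies; permuting whole-locus *order* would
leave every pairwise distance unchanged and produce a degenerate null.
The P value uses the add-one correction so it is never exactly zero.

## The synthetic-data generator

The generator is the package's study stand-in and its defaults are the
study conditions: six chromosomes totalling ~100 Mb tiled at a mean
probe spacing of 260 bp (~380,000 probes of 50 bp; spacing is
exponentially jittered and truncated so probes never overlap, and it is
a configuration knob because published spacing figures for such arrays
differ between mean and median), autosome arms holding 38% of probes
(`arm_fraction = 0.23` per arm with the X armless), indels planted on a
strain genealogy with 85% of events anchored on arms, an 8:1
deletion:amplification ratio, log-normal lengths with median ~2.7 kb and
mean ~8.5 kb (`meanlog = log(2700)`, `sdlog = 1.51`, which also puts
roughly 7% of events below 250 bp), deletion signal $-3$ and
amplification signal $+1.5$, Gaussian probe noise of SD 0.25, and an
optional cubic intensity bias so LOWESS has a smooth non-linear target.
Boundary probes partially overlapping an event receive the full signal,
matching how breakpoint probes are treated downstream.  Events are
placed with a minimum separation of 10 probes so planted loci are
individually resolvable — at genome scale collisions would be rare
anyway.  Every event originates once on a branch and is inherited by all
descendant strains; optional recombination swaps exchange all loci in an
interval between two strains.  One root seed drives everything:
per-strain child seeds are drawn as a block from the root seed, so
cohorts are bit-reproducible.

What the generator deliberately does not emulate: sequence-level
hybridization (no FASTA, no thermodynamics), SNP variation, spatial
within-slide artifacts, and regions of extreme sequence divergence that
can masquerade as deletions in real aCGH data.  Passing recovery tests
on synthetic cohorts therefore demonstrates the algorithmic pipeline —
segmentation, classification, matching, trees, LD — under the stated
noise model, not robustness to those biological confounders.

## Validation scale and reproducibility

The test suite and the acceptance script validate at the study's own
scale where the quantity demands it: whole-genome cohorts of 6 strains
at ~380,000 probes for noise-free exactness (every planted indel of ≥3
probes recovered with exact breakpoints, zero spurious calls) and noisy
recovery (SD 0.25: sensitivity above 0.95, false-discovery proportion
below 0.05, >90% of breakpoints within ±1 probe); 200 random 30-probe
instances against an exhaustive least-squares change-point oracle;
all 105 six-taxon topologies against brute-force enumeration of internal
states; a 12-strain clonal cohort with 30 loci per branch and 200
bootstrap replicates for consensus recovery; 100 equilibrium matrices
(n = 12, l = 200) for LD calibration.  The analysis scripts under
`analysis/` run a 12-isolate cohort end-to-end with 1000 bootstrap
replicates and 1000 permutations, the sizes used in published practice.
All randomness flows from explicit seeds; reruns are byte-identical.

## Known limitations

* Breakpoints are probe-resolution by design; base-pair refinement needs
  targeted PCR/sequencing and is out of scope.
* Very long amplifications near the $+1$ cutoff can still fragment at an
  interior probe whose ratio dips below the cutoff; the review export
  exposes these for human judgement, replacing manual curation.
* The catalog's allele matching is deliberately transitive; with dense
  overlapping variation a chain can join calls whose breakpoints differ
  by more than the tolerance (flagged in the output).
* Amplification loci are matched like deletions, but the genomic
  position of the amplified copies is unknown in a two-color design —
  coordinates refer to the reference copy.
* Bootstrap support under the heuristic search is a lower bound on
  exact-search support in the worst case.
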