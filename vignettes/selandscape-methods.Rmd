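---
title: "Methods: super-enhancer landscapes and differential H3K27ac analysis"
author: "selandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer landscapes and differential H3K27ac analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selandscape)
```

This vignette is the package's own account of the statistical procedures
it implements, the parameters that matter, the synthetic data used to
validate them, and the design decisions taken where the methodology was
genuinely open.

## The analysis problem

Treatment studies of enhancer landscapes ask three linked questions of
H3K27ac ChIP-seq data: which regions carry reproducible acetylation
(consensus peaks), which clustered regions carry exceptionally high
aggregate signal (super-enhancers), and how occupancy changes between
conditions (differential marks and super-enhancer change classes). The
package implements each stage behind a small, testable function surface,
with 0-based half-open coordinates throughout.

## Consensus peaks

`consensus_peaks()` merges all replicate peaks of a condition at gap 0
and keeps merged regions supported by at least `min_support` replicates,
where a replicate supports a region when at least one of its peaks
overlaps it by ≥ 1 bp and contributes at most one unit of support. The
returned coordinates are the full merged region, not an intersection:
this matches the behaviour of occupancy-based consensus construction when
summit re-centring is disabled, and keeps interval widths interpretable.
The ≥ 1 bp support rule is the simplest testable choice (no minimum
overlap fraction is claimed anywhere in the workflow the package
follows); it is deliberate and the threshold semantics are frozen in the
tests. Typical settings are 3 of 5 replicates, or 2 of 4 in
four-replicate designs.

## Super-enhancer stitching, quantification and calling

`stitch_peaks()` first removes peaks *fully contained* within
`[tss − w, tss + w)` windows (default `w` = 2,500 bp); peaks merely
overlapping a window survive. This follows the established stitching
convention in which promoter-proximal acetylation is excluded before
cluster formation; removing partial overlaps instead would truncate
genuinely distal clusters touching a promoter. Remaining peaks are
transitively merged when their gap is at most the stitching distance
(default 12,500 bp).

`quantify_clusters()` counts fragments with ≥ 1 bp overlap per cluster
(a fragment spanning two clusters counts once in each — the stated
counting rule, kept symmetric and order-independent), scales by
`1e6 / library size` (CPM, where library size is the sample's *total*
fragment count, not the in-peak sum), and averages over each condition's
replicates with equal weights.

Two thresholding routes are provided:

* `rose_threshold()` — the classical tangent point of the ranked,
  [0, 1]-scaled signal curve (the rank where scaled signal minus scaled
  rank is maximal, ties resolved towards the larger signal). The test
  suite demonstrates its known failure mode: appending a single extreme
  outlier never lowers, and typically raises, the threshold.
* `call_superenhancers()` — a fixed threshold (default 60 normalised
  units) applied identically to every condition, which is what makes SE
  sets comparable across conditions. The comparison is inclusive (≥ 60):
  the boundary convention is unstated in the workflow the package
  follows, so the inclusive form was chosen and recorded.

`classify_se_change()` computes
`log2((signal_alt + ps)/(signal_ref + ps))` with pseudo-signal `ps` = 1
normalised unit (guards zero-signal ratios; at typical SE signals of
100+ its effect is < 0.015 log2 units) and classes the change as
increased (> 0.15), decreased (< −0.15) or sustained. A cluster enters
the comparison when it is a super-enhancer in *at least one* of the two
conditions; restricting to reference-condition SEs would silently drop
treatment-gained super-enhancers, which are biologically the interesting
ones in an induction experiment. Clusters below threshold in both
conditions are reported `NA`.

## Differential occupancy

`nb_test()` is an intentionally transparent negative-binomial Wald test:
the downstream logic of the analysis lives in its fixed thresholds and
classes, not in estimator internals, so a shrinkage GLM framework is
neither needed nor cloned.

* Normalisation: CPM by total library size.
* Dispersion: a single common α in the `variance = μ + αμ²`
  parameterisation, estimated by method of moments as the median over
  regions of `max(0, (s² − f̄·m)/m²)`, where `s²` is the pooled
  within-condition variance of the normalised counts, `m` the mean and
  `f̄` the mean CPM scale factor (`1e6 / library size`). Subtracting
  `f̄·m` rather than `m` removes the Poisson variance component on the
  CPM scale; at library size 1e6 the two coincide, but at realistic
  20-million-fragment libraries omitting `f̄` would bias α upward of its
  own accord and the test would lose calibration.
* Effect and test: `log2FC = log2((m_b + c)/(m_a + c))` with pseudocount
  `c` = 0.5 CPM (stability at zero counts; negligible above ~50 CPM), a
  delta-method standard error from the NB variance with the common α,
  and a two-sided normal p-value. When both means are identical the
  statistic is exactly 0 and p = 1.
* `bh_adjust()` applies Benjamini–Hochberg step-up adjustment (ties
  handled by the standard step-up minimum over eligible ranks).

`classify_marks()` applies the three-tier rule — increased
(log₂FC > 0.5, FDR < 0.05), decreased (log₂FC < −0.5, FDR < 0.05), not
significant (FDR > 0.5), otherwise unclassified. The gap between
FDR 0.05 and 0.5 is deliberate in the underlying design: "not
significant" is a *confident* absence of change, not merely a failed
rejection. `direction_grouping()` reduces the classes to up/ns/down per
comparison, with both `not_significant` and `unclassified` mapping to
`ns` (the grouping concerns direction of change; an ambiguous region has
no direction). The 27 patterns over three comparisons are numbered by
the canonical base-3 encoding `9·s₁ + 3·s₂ + s₃ + 1` (up = 0, ns = 1,
down = 2, first comparison most significant): this ordering is a package
convention chosen for testability; no claim is made that it matches any
particular published figure's group numbering.

## Annotation and enrichment

`nearest_gene()` measures the distance from a TSS to the nearest region
boundary (0 when the TSS lies inside the region; `start − tss` to the
left, `tss − end + 1` to the right), assigns the minimising gene within
100 kb, and breaks exact ties by the lexicographically smallest gene id
(deterministic and reproducible; no biological ordering is defensible at
an exact tie). The boundary-to-TSS convention, rather than
midpoint-to-TSS, was chosen so that distance 0 coincides exactly with
containment; it is symmetric under coordinate mirroring, which the tests
exercise. Strand affects only the TSS position, never a distance sign.
`annotate_feature()` calls a region `promoter` when it overlaps any
`[tss − w, tss + w)` window (default `w` = 2,500 bp, mirroring the
stitching exclusion window so "promoter" and "excluded from stitching"
describe the same neighbourhood).

`enrich()` is hypergeometric over-representation: for a set of size `m`
in a universe of size `N`, with query size `n` and overlap `k`, the
p-value is `P(X ≥ k)`. Sets are restricted to the universe and filtered
to sizes in [20, 500] *before* testing; BH adjustment runs across the
tested sets only, and the ten most significant sets (FDR < 0.05) are
flagged. Query genes outside the universe are dropped with a warning
rather than silently shrinking the universe.

## Downstream statistics

`zscore_within_group()` scales each gene to mean 0, sd 1 within each
cell line, using the population (1/n) standard deviation — the choice is
immaterial to k-means geometry (a gene-wise constant factor) and is
recorded; zero-variance genes map to 0 rather than NaN.
`kmeans_cluster()` runs Lloyd's algorithm with squared-Euclidean
distance and 25 random restarts, keeping the best inertia; the seed is
applied locally so the caller's RNG stream is untouched. Default k
values for the two study designs are 6 (single-drug) and 5
(combination), matching the cluster counts those analyses report, and
are ordinary arguments.

`survival_distribution_test()` maps two externally supplied survival
gene lists (high-expression-poor-prognosis, low-expression-poor-
prognosis; genes on both lists are excluded from both, with a warning —
the source platform's behaviour at such conflicts is unknown, and
double-counting would bias both groups) onto differential results and
compares log₂FC distributions with a Kruskal–Wallis omnibus plus Dunn
pairwise z statistics using the tie-corrected pooled variance
`N(N+1)/12 − Σ(t³−t)/(12(N−1))`; pairwise p-values are BH-adjusted
(consistent with the FDR convention used everywhere else in the
package; the adjustment method for the Dunn step is otherwise
unspecified in the workflow followed). When every value is tied the
statistic is defined as 0.

`ddct_fold_change()` implements ddCt exactly: replicate Ct values are
averaged, normalised to the housekeeping gene (TBP by default) within
sample, then to a calibrator sample; fold change is `2^(−ddCt)` and is 1
for the calibrator by construction. The transform is invariant to adding
a constant to all Ct values of a sample, which the tests assert.
`tumor_volume()` is `4/3·π·((d₁+d₂)/4)³` (mm³ from two perpendicular
diameters in mm).

## The synthetic-data generator

The generator (`simulation_design()`, `generate_genome()`,
`generate_truth()`, `simulate_counts()`, `simulate_replicate_peaks()`,
`simulate_fragments()`) emulates the statistical structure of a
replicated treatment-vs-control ChIP-seq experiment:

* negative-binomial replicate counts per region,
  `mean = base_signal · 2^effect · libsize/1e6`, variance `μ + αμ²`
  (α = 0 gives Poisson). `base_signal` is therefore a CPM-scale
  quantity. Library sizes default to ~20 million fragments ± 20%.
* clustered high-signal regions forming planted super-enhancers
  (default 8 members of 2 kb separated by 3 kb — within stitching reach
  — at 15–30 CPM each, so aggregate cluster signals sit well above the
  fixed threshold of 60), among isolated background peaks;
* per-condition multiplicative effects planted *count-based*: exact
  numbers of up/down regions are drawn, never Bernoulli flags, so truth
  tables are deterministic for a seed;
* replicate-to-replicate peak presence/absence (per-region detection
  probability, default 0.9) with bounded uniform boundary jitter;
* optional fragment realisation: exactly the counted number of
  fragments placed uniformly within each region, so interval counting
  reproduces the count matrix. Fragments exist to exercise overlap
  counting, not to model read structure, GC or mappability bias.

The NB dispersion default of α = 0.1 is a stand-in for replicate noise
(real H3K27ac data come without a stated noise model) and is an ordinary
argument everywhere. The recovery conditions built into the validation
use α = 0.1 for the five-replicate design and α = 0.05 with four
replicates for the combination design and super-enhancer change
recovery.

What passing tests on these data do *not* show: robustness to
copy-number variation, input-control artefacts, GC/mappability bias,
fragment-length effects, batch structure, or per-region dispersion
trends — none of which the generator models. Results on real data depend
additionally on upstream peak calling, which is out of scope.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle:
transitive-closure merging via graph components, O(n·m) overlap and
all-pairs distance scans, exhaustive threshold scans, closed-form
hypergeometric tails, hand-computed ranks. Recovery checks run the full
engine on planted truth: 10,000-region null calibration (fraction of
p < 0.05 within [0.03, 0.07]), planted |log₂FC| = 1 sensitivity at 1,000
of 10,000 regions, super-enhancer precision/recall and ±0.6/0 change
classes over 20 seeds, six-archetype k-means recovery across three
z-scored cell lines, and Dunn null size over 2,000 replicates. The
end-to-end pipeline fixture uses a 50-Mb chromosome, 600 genes, 240
background peaks and 5 planted super-enhancer clusters across four
conditions × four replicates; its background baselines (10–25 CPM) keep
stitched background clusters below the SE threshold while giving planted
effects enough counts to be recoverable.

One boundary is worth stating plainly: with five replicates per group
and dispersion α = 0.1, the per-sample coefficient of variation is at
least √α ≈ 0.32, so the standard error of a log₂ fold change is ≈ 0.29
even with the dispersion known exactly. A planted |log₂FC| = 1 then
yields a Wald statistic near 3.5, and with 10% prevalence the BH
threshold settles near p ≈ 0.004 — an information-theoretic sensitivity
ceiling of roughly 0.75 at the FDR 0.05 gate, for this or any other
estimator of the same model. At α = 0.05 the same pipeline recovers
≈ 99% of planted effects. The package reports both operating points
(`scripts/acceptance.R`) rather than presenting either alone.

## Known limitations

* The differential engine uses a common dispersion and a normal Wald
  approximation; very low counts (< ~5 CPM means) or heavy-tailed
  per-region dispersion call for a GLM framework with shrinkage.
* No input-control subtraction or copy-number correction in cluster
  quantification.
* `gene_set_overlap()` supports two or three sets (the proportional-Venn
  use case), not arbitrary intersections.
* Survival gene lists are inputs; the package does not fit survival
  models.
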