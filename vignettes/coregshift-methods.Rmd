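---
title: "Methods: modelling coregulator redistribution during stress adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling coregulator redistribution during stress adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregshift)
```

## Overview

`coregshift` analyses how a chromatin coregulator (the motivating case is
the histone acetyltransferase Gcn5) redistributes across genes when cells
adapt to stress. It combines four statistical components: regulated-gene
and dependency-class calling from replicated expression log-ratios,
length-normalized metagene profiling of tiling-array ChIP signal, K-means
clustering of positional profiles with correlation distance, and exact
hypergeometric set-composition tests. This vignette documents the models,
the tunable parameters, the synthetic data the package is validated on, and
the numerical choices made where the design was genuinely open.

## Expression model and dependency classes

The expression input is a set of named contrasts, each a gene × replicate
matrix of log2 ratios: the stress-response contrast in wild type
(`wt_kcl`), and mutant/wild-type contrasts without (`mut_vs_wt_ctrl`) and
with stress (`mut_vs_wt_kcl`). Two normalizations are available:
`median_center` (per-replicate median subtraction) and `lowess_ma`
(per-replicate lowess of log2 ratio against log2 mean intensity, trend
subtracted; span 0.3 by default, in the usual range for MA-plot
normalization of two-color arrays).

A gene is called **induced** in a contrast when its mean log2 ratio exceeds
the across-genes mean by `sd_multiplier` (default 1) across-genes standard
deviations *and* a two-sided one-sample t-test of its replicates against 0
gives `p < alpha` (default 0.05); **repressed** symmetrically below;
**unchanged** when the linear fold change is below `unchanged_fold`
(default 1.2). Three reading choices deserve note:

* The SD threshold is two-sided around the *empirical* mean of the log2
  ratios (not an assumed 0), and is computed on log2 ratios, which are
  symmetric in up/down regulation. Both choices are configurable.
* P-values are deliberately **uncorrected** — the calling rule is a
  per-gene screen whose composition is analysed downstream, and the
  companion enrichment tests are likewise reported uncorrected (with a
  Benjamini–Hochberg column available but never driving flags).
* Genes falling between the unchanged band and the regulated threshold are
  left unlabelled; the two definitions do not partition the gene universe
  and the gap is preserved rather than papered over.

Genes with zero replicate variance are handled explicitly: a non-zero mean
with zero variance is treated as a certain effect (p at the smallest
representable double) and an all-zero gene as a certain null (p = 1), so
that noise-free synthetic data flow through the caller without special
cases. A contrast whose across-genes SD is zero is an error: the threshold
is undefined.

**Dependency classes** follow from set intersections:
`dependent_induced = induced(wt) ∩ repressed(mutant/wt under stress)` —
genes that go up under stress but less so without the coregulator — and
`dependent_repressed = repressed(wt) ∩ induced(mutant/wt under stress)`.
The breadth of the dependency distribution is compared between conditions
with `dependency_spread()` (SD or IQR of per-gene means plus the binned
frequency table used for plotting; bin width 0.1 log2 units by default).

## ChIP enrichment and metagene profiling

Probe-level IP and input tracks are joined on probe position; probes with
non-positive raw intensity are dropped (counted in the report) and each
remaining probe is scored with the mean (optionally 10%-trimmed mean) of
log2(IP/input) over all probes within ± `bandwidth`/2 (default 250 bp, the
conventional tiling-array smoothing scale). This windowed score is a
deliberately simple enrichment statistic: the pipeline consumes only
relative enrichment, so a probe-affinity model is out of scope here.

The two conditions' enrichment tracks are made comparable by an affine
standardization `x → (x − m_t)/s_t · s_r + m_r` so the transformed track
has exactly the reference's genome-wide mean and SD; the operation is
idempotent and refuses degenerate (constant) tracks.

Metagene coordinates follow the standard average-gene construction: the
upstream flank `[tss − flank_bp, tss)` is split into `flank_bins` fixed-bp
bins, the body `[tss, tes)` into `body_bins` equal fractional-length bins,
and the downstream flank likewise (defaults 500 bp and 10/40/10). Bin 1 is
always 5′-most: minus-strand genes are mapped through the strand-flipped
coordinate, which makes profiles exactly invariant under mirroring the
genome. Bins without probe coverage are *missing*, never zero; group
averages use only covered genes per bin and report per-bin n and SEM.
Genes with fewer than `min_probes_per_gene` (default 5) probes in their
window are excluded and reported, so single-probe bins cannot dominate
group means.

Three groupings reproduce the standard views: regulation class,
expression-level tertiles (equal-count, ties broken by gene ID so the split
is deterministic), and ORF-length bins. Length boundaries honour the
strict inequalities the analysis is anchored on — short is < 500 bp and
long is > 2000 bp, so a 2000-bp gene falls in the 1000–2000 bin — with the
two inner bins being this package's subdivision of the middle range.

**Bound genes** are called when the maximum windowed enrichment within
flank+body+flank strictly exceeds `threshold_log2` (default 1.4, i.e.
2.6-fold) in *both* conditions; a per-gene mean is available as an
alternative summary. Strictness matters at the boundary: a gene at exactly
1.4 is not bound.

## Clustering and redistribution

Positional profiles are clustered by Lloyd-style K-means under correlation
distance `d(x, c) = 1 − Pearson(x, c)` with k = 5 clusters and 100
iterations by default — "standard correlation" similarity in the sense of
the classic microarray toolchains. Three numerical choices make this
reproducible and provably well-behaved:

* **Multi-start seeding.** K-means++-style initialization on correlation
  distance, best of `restarts` (default 20) runs by final objective, all
  driven by one integer seed. Input rows are sorted by gene ID before
  seeding, so results are invariant to input order.
* **Monotone objective.** Internally each profile is z-scored (Pearson
  correlation is invariant to per-profile affine maps, so assignments are
  unchanged), which makes the arithmetic mean of member rows the exact
  minimiser of summed correlation distance. The objective is therefore
  non-increasing and the implementation asserts this at every iteration.
  Reported centroids are arithmetic means of the raw member profiles.
* **Degenerate cases.** Zero-variance profiles (correlation undefined) are
  dropped and reported; a cluster emptied during iteration is refilled with
  the gene farthest from its current centroid, keeping k fixed; profiles
  with missing bins are dropped (or mean-imputed) per configuration.

For clustering, per-gene profiles are completed with
`profile_matrix(fill = "interpolate")`: missing bins are filled by linear
interpolation over the bin index. This is the standard resampling step
when genes much shorter than the bin grid are mapped onto a model gene —
at 50-bp probe spacing a 300-bp gene covers only a handful of its 40 body
bins, and without interpolation all short genes would be excluded from
exactly the analysis that is about them. `gene_profile()` itself always
reports missing bins as missing.

Clusters from the two conditions are matched by maximizing total
centroid-to-centroid Pearson correlation over all assignments (exact
exhaustive search; k ≤ 8, and k = 5 in practice). Degenerate centroids are
matched last with an undefined score. The redistribution summary then
reports the k × k label-flow matrix (columns relabelled through the
matching, so the diagonal holds stable genes and its marginals reconcile
with cluster sizes), per-matched-cluster change in mean association, a
signed body-shift statistic per condition (mean over genes of body-bin mean
minus flank-bin mean), and per-cluster length-composition enrichment.

Composition enrichment and all other set tests use the exact upper-tail
hypergeometric probability, computed in log space via `phyper` and verified
in the test suite against both full enumeration (N ≤ 12) and an independent
log-gamma summation (N ≤ 10⁴, relative error ≤ 1e-10). Enrichment is
one-tailed (upper) throughout by design, matching the directional claims
the pipeline makes; the term-enrichment universe is a required argument
because the background choice dominates such p-values and should never be
silent.

For cross-species comparison, `ortholog_overlap()` restricts each species'
gene set to genes with a partner in a one-to-one ortholog-pair map, counts
pairs whose members are both selected *and* share the regulation direction,
and reports the chance expectation `n1·n2/N`, a direction-concordant
expectation (scaled by the concordance probability of the direction
marginals), and the upper-tail hypergeometric p of the undirected overlap
— the undirected test is the conservative bound and is labelled as such.

## The synthetic data generator

The generator is the package's study-condition definition, not a test
convenience. It plants truth labels that every downstream stage is scored
against:

* **Genome.** Genes laid end-to-end with a fixed intergenic gap on one
  chromosome, alternating strands; lengths drawn uniformly within short
  (< 500 bp), medium (500–2000 bp) and long (> 2000 bp, capped at 6000 bp)
  categories, with deterministic largest-remainder allocation of the
  category proportions (default 0.25/0.5/0.25).
* **Occupancy.** Four archetypes: a Gaussian promoter peak (SD 150 bp)
  centred on the TSS, a plateau over the gene body, a plateau over
  flank+body+flank, and unbound; each scaled to a planted amplitude
  (default 2 log2 units). The input channel is flat plus Gaussian log2
  noise; the IP channel adds the archetype shape; overlapping genes' shapes
  are summed, as on a real array. The default redistribution plan swaps
  archetypes between conditions — short genes body-enriched → promoter-
  peaked, long genes promoter-peaked → body-enriched, medium genes stable —
  so the untreated condition has enrichment inversely related to gene
  length while the stress condition concentrates body enrichment on long
  genes, and both conditions contain the same well-shaped (non-flat)
  cluster archetypes. The peak SD and plateau shapes are this package's
  parameterization: the simplest shapes that reproduce the qualitative
  cluster archetypes seen in such data.
* **Expression.** Replicate log2 ratios are homoscedastic Normal(μ, 0.25)
  with μ = ±2 for planted induced/repressed genes in the wild-type
  contrast, ∓2 for dependent genes in the mutant/wild-type stress contrast,
  and 0 otherwise (a `null_sd` option plants a wide null of gene-level
  effects when non-zero; the default null is pure). A lognormal
  mean-intensity channel supports intensity normalization and tertile
  grouping. Defaults (amplitude 2, effect size 2, noise SD 0.25, 4
  replicates) were fixed once as representative of well-powered two-color
  microarray experiments and are stated configuration, not claims about any
  particular dataset.

What the generator does *not* emulate: dye bias, print-tip and spatial
artifacts, probe-affinity sequence effects, heteroscedastic
intensity-dependent noise, and correlated replicates. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
statistical model, not robustness to every artifact of real arrays — the
normalization and trimmed-mean options exist precisely because real data
need them.

## Validation and problem sizes

The test suite validates each stage against independent oracles:
enumeration and log-gamma summation for the hypergeometric tail; a frozen
Monte-Carlo oracle (10⁵ genes) for the null calling rate of the
regulated-gene rule, checked at 10⁴ genes within ±3 binomial SDs; exact
recovery of planted dependency classes at zero noise and ≥ 90% recovery
with ≤ 2% false calls at the default noise; exact planted-pattern recovery
(promoter argmax at the TSS-straddling bins, body argmax inside the body)
on noise-free profiles; adjusted Rand index ≥ 0.8 for five planted
archetypes at noise SD 0.25 (40 genes each, 20 restarts); the sign flip of
the long-vs-short body contrast plus ≥ 90% label-flow concentration under
planted redistribution (240 genes); moment-exact standardization; and
byte-identical demo reruns (300 genes, 9 hashed stages). These problem
sizes keep the whole suite under a minute or two while leaving every
statistical margin wide; `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

## Known limitations

* The windowed log-ratio score is not a peak caller and carries no FDR; it
  is a relative-enrichment summary feeding the profiling stages.
* Cluster matching is exact but exhaustive, so k is limited to 8; the
  analysis convention is k = 5.
* The per-gene maximum used for bound-gene calling is sensitive to single
  high-scoring windows on sparse arrays; the mean summary is provided for
  such cases.
* Term enrichment assumes any ontology ancestor closure is already baked
  into the supplied term map; no DAG propagation is performed.
* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and WIG (1-based) are converted on read, and bedGraph intervals are
  reduced to midpoint probes, which is faithful for probe-centric tiling
  data but lossy for long intervals.
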