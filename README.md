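# coregshift

Genome-wide redistribution analysis of a chromatin coregulator during
stress adaptation.

## The problem

Chromatin coregulators such as the histone acetyltransferase Gcn5 (the
catalytic subunit of the SAGA coactivator) are required for the correct
expression of some genes but not others, and their genomic localization can
change when cells adapt to stress. Dissecting this requires combining two
genome-wide measurements made in two conditions (e.g. normal growth vs. KCl
stress):

* replicated two-color expression log-ratios contrasting wild type with a
  deletion mutant, used to call stress-regulated genes and the subset whose
  regulation *requires* the coregulator, and
* tiling-array ChIP (IP vs. input) signal, used to profile where along genes
  the coregulator sits and how that positional pattern shifts between
  conditions.

`coregshift` implements this analysis as a tested, reusable R pipeline for
computational biologists working with probe-level occupancy data and
gene-level expression ratios. A truth-labelled synthetic-data generator
emulates the statistical structure of both data types, so every stage is
testable end-to-end without external downloads.

## The methods at the core

* **Regulated-gene calling.** For a contrast with replicate log2 ratios
  `x_g1..x_gn`, a gene is *induced* if its mean exceeds `m + c·s` (where `m`,
  `s` are the mean and SD of all genes' means and `c = 1` by default) and a
  two-sided one-sample t-test against 0 gives `p < 0.05` (uncorrected);
  *repressed* symmetrically below `m − c·s`; *unchanged* if its linear fold
  change is below 1.2. Coregulator-dependent stress genes are the
  intersections `induced(wt) ∩ repressed(mutant/wt)` and
  `repressed(wt) ∩ induced(mutant/wt)`.
* **Metagene (average gene) profiling.** Windowed log2(IP/input) scores
  (window width 250 bp) are standardized across conditions to a common mean
  and SD, then mapped per gene onto fixed-width flank bins plus
  length-normalized body bins (10/40/10 by default) and averaged over gene
  groups (by regulation, expression tertile, or ORF-length bins with short
  < 500 bp and long > 2000 bp).
* **Redistribution inference.** Per-gene positional profiles are clustered
  with K-means under correlation distance `d(x, c) = 1 − Pearson(x, c)`
  (k = 5, 100 iterations, 20 seeded restarts); clusters are matched across
  conditions by centroid correlation, gene flows between matched clusters
  are tabulated, and each cluster's composition is tested for gene-length
  enrichment with the exact upper-tail hypergeometric test
  `P(X ≥ x), X ~ Hypergeom(N, K, n)`.
* **Set comparisons.** The same hypergeometric machinery drives term
  (GMT) enrichment against an explicit universe (uncorrected p with an
  `alpha = 0.02` flag, plus a BH column) and cross-species ortholog-overlap
  analysis over a one-to-one ortholog-pair map, with chance expectation
  `n1·n2/N` and direction-concordant counting.

## Worked example

```r
library(coregshift)

manifest <- run_demo("demo_out", seed = 17, n_genes = 300)
length(manifest$stages)
#> [1] 9

rj <- jsonlite::read_json("demo_out/results/redistribution.json")
round(unlist(rj), 3)
#> body_shift_a body_shift_b     n_common
#>       -0.411       -0.145      300.000

sp <- jsonlite::read_json("demo_out/results/dependency_spread.json")
round(unlist(sp[c("spread_minus", "spread_plus", "ratio")]), 3)
#> spread_minus  spread_plus        ratio
#>        0.124        0.583        4.689
```

The demo simulates a 300-gene genome in which occupancy sits on short-gene
bodies before stress and moves to long-gene transcribed regions under
stress. `body_shift_a`/`body_shift_b` are the mean per-gene (body − flank)
enrichment before and after stress: the rise from −0.41 to −0.14 log2
units is the planted shift of signal into transcribed regions (the values
sit below zero because the demo genome is compact, so each gene's flanks
overlap its neighbours' signal). The dependency-spread ratio of ~4.7 shows
the mutant/wild-type ratios spreading out under stress, as expected when
coregulator-dependent effects are stress-specific. Other
outputs under `demo_out/results/` include the per-gene expression calls,
dependency classes, per-condition profile matrices and metagene tables,
cluster labels and centroids, the cross-condition label-flow matrix, the
cluster length-enrichment table, the term-enrichment table, and the
ortholog-overlap report. Every output is md5-hashed into
`manifest.json`; rerunning with the same seed reproduces the hashes
byte-for-byte.

A thin command-line wrapper is available at `inst/cli/coregshift.R`
(`demo`, `run --config config.yaml`, `validate`).

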