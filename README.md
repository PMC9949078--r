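# markerdecon

Cell-type composition assessment for bulk RNA-Seq of heterogeneous tissues,
using published single-cell RNA-Seq marker gene lists as the reference.

Bulk RNA-Seq of a complex tissue (the motivating application is kidney
cortex, with 40+ described cell types) measures a mixture of cell types, so
expression differences between sample groups may be biology or may be
sampling: biopsies that simply captured different cells. `markerdecon`
implements a computationally light composition check built on one idea —
**a gene expressed in exactly one cell type is a presence indicator for that
cell type**. If the unique-marker genes behave consistently across groups,
observed expression differences are unlikely to be composition artefacts.
The method infers presence; it does not estimate proportions (no signature
matrix is fit).

## The method

Given per-cell-type marker tables \(g, \text{expr}, c\) from a single-cell
study, a bulk transcript count matrix, and a two-group sample design:

1. **Unique-marker reference.** Concatenate the marker tables and delete
   every gene symbol listed under ≥ 2 cell types, leaving a map
   *gene → cell type* that is a function. Symbols are upper-cased so
   orthologous genes match across species (rat *Lep* ↔ primate *LEP*).
2. **TMM+1 normalization.** Trimmed mean of M-values: against a reference
   sample (upper-quartile fraction closest to the mean), per-gene
   M = log2 count-proportion ratios are doubly trimmed (30% of M, 5% of A)
   and precision-weighted; factors are rescaled to geometric mean 1.
   Normalized abundance = count / (library size × factor), rescaled to the
   mean library size, + 1, so unexpressed transcripts sit at a floor of 1.
   A pooled-mean filter then drops low-expression transcripts.
3. **Annotation.** Inner join to the reference by gene symbol; every
   isoform of a matched gene carries the gene's single cell type.
4. **Composition statistics.** Per-transcript unpaired t-tests
   (pooled-variance by default, Welch optional) with the
   Benjamini–Krieger–Yekutieli two-stage FDR at q = 0.05: stage 1 is a
   Benjamini–Hochberg step-up at q′ = q/(1+q); its rejection count r₁
   estimates m₀ = m − r₁ true nulls and stage 2 re-runs the step-up at
   q′·m/m₀. Cell-type **presence** per group = any marker transcript with
   group mean above the floor; **group-exclusive genes** = expressed in
   every sample of one group and no sample of the other. Sequencing-QC
   metrics are compared with Welch's t-test per metric.
5. **Variation.** Per-group coefficient of variation per transcript, and
   covariance PCA of samples with axis-aligned 2-standard-deviation group
   ellipsoids.

A synthetic-data generator (`simulate_dataset()`) emulates the target study
design (8 vs 9 samples, 43 cell types, negative binomial counts) with a
ground-truth manifest, so the whole pipeline is testable without any
download.

## Worked example

```r
library(markerdecon)

sim <- simulate_dataset(sim_config(seed = 1), "sim")   # synthetic inputs
res <- run_pipeline(run_config(
  markers = "sim/markers",
  counts  = sim$counts_path,
  groups  = sim$groups_path,
  qc      = sim$qc_path,
  out_dir = "sim/results"))

res$report
#> Composition report
#>   transcripts tested:   162
#>   significant (q <= 0.05): 0
#>   cell types detected:  43
#>   group-exclusive genes: 0

glance(res$annotated)
#> # A tibble: 1 × 5
#>   n_transcripts n_genes n_cell_types n_unmatched_transcripts ...
#> 1           162     129           43                    2010

res$pca
#> PCA of 17 samples; top components explain 38.23%, 21.21%, 10.22% (total 69.65%)
```

Reading the output: of 2,172 simulated transcripts, 162 (129 unique marker
genes, some as two isoforms) matched the 43-cell-type reference; all 43
mixed-in cell types are called present in both groups; no transcript
differs between groups after two-stage FDR and no gene is group-exclusive —
exactly what a null simulation (both groups drawn from the same mixture)
should produce. `tidy(res$norm)` gives the per-sample TMM factors,
`res$report$presence` the per-cell-type presence calls with supporting
marker counts, and `autoplot(res$pca)` the score plot with 2-SD group
ellipses. Every table is also written under `sim/results/`, together with a
`manifest.json` recording input checksums, parameters and stage counts.

The same stages are available from the shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "markerdecon", package = "markerdecon"))')
Rscript $CLI simulate  --out-dir sim --seed 1
Rscript $CLI build-ref --markers sim/markers --out ref.csv
Rscript $CLI preprocess --counts sim/counts.csv --out norm.csv
Rscript $CLI annotate  --matrix norm.csv --ref ref.csv --out ann.csv
Rscript $CLI compare   --annotated ann.csv --groups sim/groups.csv --out-dir results
Rscript $CLI run       --config run.yaml      # all stages, one YAML
```

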