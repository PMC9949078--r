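---
title: "Marker-based cell-type composition assessment for bulk RNA-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based cell-type composition assessment for bulk RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(markerdecon)
library(dplyr)
```

## The problem

Bulk RNA-Seq of a heterogeneous tissue — kidney cortex is the motivating
case, with more than forty described cell types — measures a mixture. When
two groups of samples differ in expression, the difference may be biological
or may simply reflect different cell-type composition of the biopsies. This
package implements a deliberately light-weight composition check: genes that
a published single-cell RNA-Seq study found expressed in *exactly one* cell
type are used as presence indicators. If a unique marker of a cell type is
expressed in a bulk sample, it is reasonable to infer that the cell type is
present; if the marker set behaves the same way in both groups, observed
expression differences are unlikely to be sampling artefacts. The method
deliberately does **not** estimate cell-type proportions — no signature
matrix is fit — it infers presence and compares composition between groups.

The pipeline has five stages, each exposed as ordinary functions over data
frames:

1. **Reference building** (`load_marker_tables()`, `build_reference()`):
   per-cell-type marker tables are concatenated and every gene symbol that
   appears under two or more cell types is removed entirely, leaving genes
   uniquely assignable to one cell type. Within a single cell type,
   duplicated rows collapse to the maximum expression — repetition within a
   type is not ambiguity. Gene symbols are upper-cased and trimmed before
   any comparison, because official symbols are shared across species while
   case conventions differ (rat *Lep*, primate *LEP*); this is what makes a
   rodent single-cell reference usable with primate bulk data.
2. **Normalization** (`tmm_normalize()`, `filter_low_expression()`): trimmed
   mean of M-values with a +1 offset, then a pooled-mean expression filter.
3. **Annotation** (`annotate_matrix()`): inner join of the bulk matrix to
   the reference by gene symbol. Every transcript isoform of a matched gene
   receives the gene's single cell-type label; unmatched transcripts and
   unmatched reference genes are counted, since "how many of the reference
   cell types are detectable at all" is itself a result.
4. **Composition statistics** (`compare_groups()`, `presence_table()`,
   `exclusive_genes()`, `compare_qc_metrics()`).
5. **Variation** (`cv_by_group()`, `pca_expression()`).

`run_pipeline()` composes the stages into one reproducible run with a JSON
manifest; `simulate_dataset()` generates synthetic inputs with known ground
truth.

## Normalization: TMM with an additive offset

`tmm_normalize()` implements the trimmed mean of M-values from first
principles. The reference sample is the one whose upper-quartile count
fraction is closest to the cross-sample mean of that fraction. For every
other sample, per-gene log2 count-proportion ratios (M) and mean log2
abundances (A) against the reference are doubly trimmed — the default trims
30% of M and 5% of A from each tail, the standard published values — and the
scaling factor is 2 to the precision-weighted mean of the surviving M
values, with inverse asymptotic binomial variances as weights. Factors are
rescaled to geometric mean 1, an invariant the tests assert at 1e-8.
Normalized abundances are counts divided by (library size × factor),
rescaled to the mean library size (counts-per-million by flag), plus an
offset of 1 so unexpressed transcripts sit at a floor of exactly 1
("TMM+1"). The unit tests pin the factors against a frozen table computed
once with edgeR's `calcNormFactors(method = "TMM")` on twenty seeded
negative binomial matrices (agreement within 1e-6; observed ~5e-12).

Two numerical notes. First, because M and A are proportion-based, the trim
window is unchanged when one sample's counts are multiplied by a constant;
the unweighted factor is then exactly scale-free, but the default precision
weights depend on raw counts, so the weighted factor moves slightly (~1% for
a 7× scaling — the reference implementation behaves identically). Second,
when fewer than 10 genes survive the double trim the factor falls back to
the untrimmed mean of M with a warning rather than failing.

**Offset and filter.** The filter retains transcripts whose pooled mean
across *all* samples is at least the threshold (default 1; a row with mean
exactly 1.0 is retained, matching the strict "average of less than 1 is
removed" reading). Where exactly the upstream commercial software adds its
+1 is not documented; this package adds the offset to every scaled value, so
with the default offset of 1 every normalized value is ≥ 1 and the default
filter only removes rows in matrices normalized with `offset = 0` (or when a
threshold above the offset is chosen). Both the offset and the threshold are
plain arguments, and the simulator emits a tail of low-expression background
transcripts precisely so that the filter's behaviour is testable at
`offset = 0` or `threshold > 1`.

## Group comparison and the two-stage FDR

Per-transcript comparisons are unpaired t-tests — pooled-variance by
default, matching the common statistics-software default for "multiple
unpaired t-tests", with Welch's correction available via
`stats_config(welch = TRUE)`. Sequencing-QC metric comparisons
(`compare_qc_metrics()`) always use Welch, reported as raw per-metric
p-values without multiplicity correction, following the convention of
per-panel QC figures.

Multiplicity across transcripts is handled by the Benjamini–Krieger–
Yekutieli adaptive two-stage linear step-up at level `q` (default 0.05).
With `q' = q/(1+q)`, stage 1 is a Benjamini–Hochberg step-up at `q'`; its
rejection count `r1` estimates the number of true nulls as `m0 = m - r1`,
and stage 2 is a step-up at `q' · m / m0` (nothing is rejected when
`r1 = 0`; everything when `r1 = m`). Reported q-values are the step-up
cumulative minimum of `p_(i) · m0 / i · (1+q)`, the smallest level at which
the transcript would be rejected given the stage-1 null estimate, so
`q_value <= q` reproduces the rejection set exactly. Because the procedure
is adaptive, a q-value can be smaller than its p-value; the rejection set,
not the q-value, is the primary contract, and the tests compare it against
a brute-force enumerator of both stages on a thousand random p-vectors.
The output keeps raw `p` next to `q_value` so "significant before
correction" and "significant after FDR" can be distinguished — marker
transcripts of low-abundance cell types often show the former without the
latter.

Under a pure-null simulation (200 transcripts, groups of 8 and 9, 200
replicates) the mean false-discovery proportion at `q = 0.05` stays below
0.075, and with ten planted 3-standard-deviation mean shifts among 200
nulls the procedure recovers ≥ 90% of planted transcripts with observed FDR
≤ 0.1 over 100 replicates — both asserted in the test suite and recomputed
by `scripts/acceptance.R`.

## Presence and group-exclusive genes

A cell type is called **present** in a group when at least one of its
marker transcripts has group-mean abundance strictly above the presence
threshold. The threshold defaults to the normalization offset (1): any
evidence above the unexpressed floor counts, and a marker sitting exactly
at the floor does not. Raising the threshold can only remove presence
calls (tested as a monotonicity property).

A gene is **exclusive** to a group under the default `all-vs-none` rule
when every sample of that group expresses at least one of its transcripts
above the threshold and no sample of the other group expresses any. This is
the strongest reading of "only found to be expressed in one group"; since
the criterion is not standardized, the relaxed `any-vs-none` rule is
provided as an option. Both operate at the gene level, so a gene whose
individual isoforms alternate across samples still counts as expressed in
each sample where *some* isoform is on.

## Variation analysis

`cv_by_group()` reports the per-transcript coefficient of variation
(sample SD with the n−1 denominator over the group mean) in each group,
plus which group has the higher mean — the table behind the CV scatter
plot, which `write_cv_scatter()` writes next to the image so the figure is
reproducible data. `pca_expression()` runs covariance PCA (samples as
observations, transcripts mean-centered but not scaled — the usual default
for expression data; correlation PCA by flag, which drops zero-variance
transcripts first). Explained percentages come from the eigenvalues of the
sample covariance and sum to 100 over all components. Group ellipsoids are
axis-aligned in the retained component space: center at the group-mean
score, radius two standard deviations of the group's scores along each
component. Full covariance ellipsoids are deliberately out of scope.

## The synthetic-data generator

Because the motivating study's animal data live in an external archive, the
package ships a generator (`simulate_dataset()`) whose defaults emulate the
study design: two groups of 8 and 9 samples, 43 reference cell types with 3
unique markers each (129 unique marker genes — close to, though not exactly,
the study's 144, which 43 equal-sized lists cannot produce), 10 deliberately
shared (ambiguous) marker genes to exercise duplicate removal, 2,000
low-expression background transcripts (the study-scale pool of ~27,000
defaulted down to keep tests fast), and negative binomial counts with
dispersion 0.1 — the standard bulk RNA-Seq overdispersion scale. Mixture
weights are one Dirichlet draw shared by both groups (no true composition
difference, as the study found) unless an explicit cell-type × group weight
matrix is supplied; a zero row marks an absent cell type whose markers are
structural zeros. The expected count of a marker gene is library size ×
cell-type weight × a lognormal gene intensity; a quarter of marker genes are
emitted as two transcript isoforms splitting the gene expectation 60/40.
Planted group differences are log2 fold changes applied in the second
group; planted exclusive genes are structural zeros in the other group,
floored at a detectable expectation, and drawn only from mixed-in cell
types so planting can never make an absent type look present. Every file the
generator writes is reproduced byte-for-byte from the same seed, and
`truth.json` records exactly what a correct pipeline must recover.

What the generator does *not* emulate: gene–gene correlation, GC/length
bias, batch effects, library-preparation differences, or any real marker
biology — gene symbols are synthetic. Passing the recovery tests therefore
demonstrates the pipeline's internal correctness (normalization, joins,
calls, error control), not that a particular real marker list is adequate
for a particular tissue.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use simulation sizes chosen to
make the Monte Carlo assertions stable while keeping a full run in the tens
of seconds on one CPU: 20 seeded matrices for the TMM fixture, 1,000
p-vectors for the FDR enumerator, 200 null and 100 planted-effect
replicates for error control and power, and 20 seeded end-to-end mixtures
for presence/exclusive recovery. The acceptance script takes `--seed` and
derives every stream from it; the pipeline itself is deterministic, and
re-running it on identical inputs reproduces identical output files, which
the manifest's input checksums make auditable.

## Known limitations

- Presence inference is qualitative; the method cannot say how *much* of a
  cell type is present, and a cell type without unique markers surviving
  duplicate removal is invisible to it.
- Cross-species matching relies entirely on shared official gene symbols;
  no ortholog mapping or alias resolution is attempted.
- With the default offset (1) and threshold (1) the expression filter is a
  floor check, as discussed above.
- The two-stage FDR's q-values are procedure-specific quantities, not
  posterior error probabilities, and comparisons across different `q`
  levels should use the rejection sets.
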