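---
title: "Methods: classifying and testing intragenic vs intergenic LINE-1 elements"
author: "l1census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and testing intragenic vs intergenic LINE-1 elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1census)
```

# The scientific question

Full-length LINE-1 (L1) retrotransposons are abundant in mammalian
genomes, but only a subset retains the intact 5′ UTR promoter, two open
reading frames and 3′ UTR required for activity. Elements inserted inside
gene bodies (intragenic) are candidates for co-opted regulatory roles: an
L1 transcribed in antisense can pair with complementary sequence in the
host pre-mRNA and repress it, a mechanism that does not depend on the
element's own strand. This motivates three linked analyses, which this
package implements as a reusable, tested pipeline:

1. where full-length L1s sit relative to genes, and at what density per
   chromosome class;
2. whether intragenic elements are more *structurally conserved* than
   intergenic ones, feature by feature, after adjusting for element age;
3. whether genes hosting intragenic L1s are preferentially
   *down-regulated* across early embryonic stages.

Because the original data sources are large external resources (reference
genome builds, an L1 annotation database, a public microarray series), the
package ships a synthetic-data generator that reproduces their statistical
structure at desk scale, so every stage of the pipeline is testable
offline, with known planted truth.

# Gene spans and element classification

A gene's span runs **from the first to the last exon of its largest
transcript isoform**. "Largest" is interpreted as the largest *genomic
span* (last exon end minus first exon start), not the largest summed exon
length, because the definition is phrased in terms of first and last
exons; ties are broken deterministically by the lexicographically smallest
transcript id. Exon structure inside the span is deliberately ignored:
an element inside an intron is intragenic.

Classification of an element against the set of gene spans is three-way:

* `intragenic_total` — some single span contains the element entirely;
* `intragenic_partial` — at least 1 bp overlaps some span, but no span
  contains it. No larger minimum overlap is imposed; 1 bp is the weakest
  defensible reading and is exercised explicitly by half-open boundary
  tests;
* `intergenic` — otherwise (including chromosomes with no annotated gene).

Overlap is strand-agnostic (the antisense mechanism above makes both
orientations relevant). An element overlapping two genes' spans is counted
**once** in element-level tallies but attributed to **every** overlapped
gene when building gene sets, because the two uses are different: element
counts feed densities, gene sets feed the expression association. This
choice is recorded in the run manifest of every pipeline run.

Internally all coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted exactly once at the file boundary. Interval
queries go through `GenomicRanges`, and the classifier is validated
against a brute-force enumeration oracle on random small genomes.

## Densities

For each chromosome class (autosome, X, Y — derived purely from
chromosome names, with other contigs excluded and counted), the intragenic
region length is the length of the **union** of gene spans, so overlapping
genes are not double-counted, and the intergenic length is its complement;
the two sum to the chromosome length exactly. Densities are reported in
counts per Mbp twice: against the matching region length (the
compartment-specific density) and against the whole chromosome-class
length (the distribution-style denominator). Both are emitted and
labelled; percent-intergenic content per class is read directly off the
report.

# The age-stratified conservation screen

Element age confounds the intragenic/intergenic comparison: young and old
subfamilies differ both in conservation and in where they sit. Subfamily
(mouse: F, A, T_F, G_F by 5′ monomer signature; human: L1PA, L1M) is
therefore used as the stratification variable, and each categorical
feature is tested by the Cochran–Mantel–Haenszel statistic over
per-subfamily 2×2 tables, **without continuity correction** (exposed as a
flag). Uncorrected, the single-stratum statistic satisfies the identity
CMH = ((n−1)/n)·Pearson χ², which the tests verify to 1e-10, and the full
statistic is cross-checked against an independent stratified reference
implementation. The common odds ratio is the Mantel–Haenszel estimator
with a Robins–Breslow–Greenland variance for its 95% CI; crude 2×2 odds
ratios elsewhere use Woolf intervals. Strata with a zero row or column
margin carry no information about the odds ratio and are dropped, with the
number of informative strata reported — pooling sparse strata instead
would change the estimand.

Directionality is one test, two readings: with "conserved" as the
condition-positive state, OR > 1 means conservation is enriched among
intragenic elements and OR < 1 means the mutated state is; the screen
labels the direction rather than running a second test.

Quantitative features (intactness scores, GC content, monomer counts, ORF
gap/stop/frameshift counts) use Welch's unequal-variance t-test via
`stats::t.test`; equal-variance balanced cases reduce to the pooled
Student t, verified to 1e-10.

The screen applies **no multiple-testing adjustment**; each feature is
flagged at a fixed p < 1.0E-03. This matches the analysis the package
reproduces and is configurable. A feature whose test fails (e.g. entirely
missing states) yields a `status = "failed"` row instead of aborting the
screen, so one bad column cannot silence the rest.

Why Mantel–Haenszel and not the pooled table: a constructed
Simpson-confounding instance — strata (99, 1, 900, 100) and
(100, 900, 1, 99), each with stratum OR = 11 — pools to OR ≈ 0.049. The MH
estimate follows the strata (OR = 11), the pooled table reverses; the
acceptance suite evaluates exactly this instance.

# Expression association

Differential expression per gene is a paired t-test on per-replicate
differences against the reference (one-cell) stage: with R replicates,
t = d̄/(s_d/√R) on R−1 df, two-sided. Replicates are paired by replicate
index; a sample sheet can remap arbitrary column names. Genes with
p < 0.05 are called up or down by the sign of d̄. Degenerate genes
(s_d = 0) are forced significant in their sign direction with p recorded
as 0 and flagged — with zero noise the evidence is exact — or called `ns`
when d̄ = 0.

The association table per stage and direction has rows L1-present /
L1-absent and columns called-in-direction / **rest**, where "rest" is
every tested gene not called in that direction, including genes called in
the opposite direction (the literal reading; configurable in principle
but deliberately not a second code path). The gene universe is the
expression matrix after any duplicate collapse, and the L1 gene set is
intersected with it before counting, so the margins always reconstruct
the universe. Pearson χ² without Yates correction (consistent with the
CMH choice), OR = ad/bc, Woolf 95% CI; zero cells keep the raw OR (0 or
∞) honest while the CI uses the Haldane–Anscombe +0.5 adjustment, flagged.
A contrast is significant only if p < 1.0E-03 **and** OR > 1.

Cross-stage intersections take the gene sets of the stages whose
association passed both thresholds — membership is derived from the
significance flags at run time, never from a hard-coded stage list — and
report the intersection together with full Venn region counts
(inclusion–exclusion, verified against a direct oracle). The ortholog
join emits every pair whose members lie in the two species' common sets;
one-to-many pairs are all emitted.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. One user-facing seed drives a named sub-stream per generator
step (genome, L1 table, expression, orthologs), so adding a generator
never perturbs another; identical configurations give byte-identical
files (all writers use fixed formatting, floats at six significant
digits, and no timestamps).

Defaults, chosen once as a realistic mouse-like desk-scale study:

* **Genome**: 19 autosomes plus X and Y at 10 Mbp each; 100 genes per
  chromosome with spans uniform in 5–50 kb (union-genic fraction ≈ 19%,
  and with 7 kb elements an intragenic element fraction near the ~16–21%
  observed for full-length L1s). Genes may overlap, exercising the span
  union; 1–3 transcripts of 1–5 exons each.
* **Elements**: 200 per chromosome, 7 kb (mouse full-length scale);
  subfamilies F/A/T_F/G_F drawn with weights 2602/6336/4940/1622, the
  genome-wide abundances of those subfamilies.
* **Features**: 42 categorical + 11 quantitative, the panel sizes of the
  mouse structural-feature annotation. Conserved-state rates default to
  0.8 (intragenic) vs 0.5 (intergenic), a planted per-stratum odds ratio
  of exactly (0.8/0.2)/(0.5/0.5) = 4; equal rates plant the null.
* **Expression**: six stages (1-cell … blastocyst), 3 replicates (the
  series emulated does not fix the replicate count; 3 is configurable,
  not asserted), baseline N(8, 2²) log2 with N(0, 0.25²) replicate noise
  (typical microarray scale), planted down-effect −2 log2 (four-fold,
  the scale of maternal-transcript clearance), and per-stage down
  probabilities 0.30 (L1-hosting) vs 0.20 (other genes), a planted
  association OR of (0.30/0.70)/(0.20/0.80) = 1.714.

Simulation is at gene level; probe-level structure is out of scope, with
only a per-gene duplicate-row mean collapse provided at I/O.

## What validation does and does not show

* **Type-I calibration**: with all effects null, the fraction of MH
  feature tests and of association tests with p < 0.05 stays within ±3
  Monte-Carlo standard errors of 0.05 over 200 simulated screens. The
  association calibration is measured on the down-direction cells, where
  the null generator yields adequate expected counts (≈30 per cell);
  up-direction cells under this null have expected counts near 3, where
  the χ² approximation itself — not the implementation — is the limit.
* **Parameter recovery**: the planted feature OR = 4 (at 10,000 elements)
  and planted association OR = 1.714 (at 10,000 genes, 7% of them
  L1-hosting, matching the ~1,454 host genes among ~21,000 array genes of
  the human data) fall inside the reported 95% CIs in ≥ 90% of 100
  replicate simulations. The association OR measured through DE calls
  carries a small real attenuation (false-positive down calls at
  α_de/2 = 2.5% dilute both groups, shrinking the observed OR to ≈ 1.65);
  this is a property of the estimand-through-misclassification, stated
  here rather than hidden, and at the realistic host-gene fraction the
  coverage criterion is met with margin.
* Problem sizes used throughout validation (200 screens of 1,000 elements
  × 20 features; 100 replicates at 10,000 elements/genes) are the
  package's chosen desk-scale study conditions.

Passing these checks shows the machinery is calibrated and recovers
planted effects under the generator's assumptions: independent Bernoulli
feature states given location class, homoscedastic Gaussian noise,
effects constant across replicates, and independence between genes. Real
L1 data violate several of these (correlated features along the element,
heteroscedastic arrays, correlated genes), so the validation supports the
*implementation*, not the biological conclusions on any particular
dataset. The published genome-build-dependent counts (11,897 human /
16,508 mouse elements and the per-feature p-values) depend on specific
database versions and are intentionally out of scope; only their printed
percentage arithmetic (21.41%, 15.71%) is reproduced, via fixtures whose
classification realizes exactly those counts.

# Numerical and degenerate-input conventions

* Half-open interval logic throughout; an element abutting a span end has
  zero overlap and is intergenic.
* Percentages in summaries are rounded half-up to two decimals (exact
  halves away from zero), the convention of printed tables.
* `mh_test` with Σbᵢcᵢ/nᵢ = 0 reports OR = ∞ with an undefined CI and a
  degenerate flag; all-degenerate strata are an error ("no informative
  strata").
* `welch_test` requires two values per group and non-zero variance in at
  least one group; both-zero variance is an error rather than a silent
  t = 0 or ±∞.
* Association tables with a zero margin return p = 1 with a degenerate
  flag instead of NaN chi-squares.
* Zero elements yield empty-but-well-formed tables and a missing
  (not zero, not NaN) intragenic percentage.
* TSV writers emit floats at six significant digits; round trips are
  exact for coordinates and states, and within 1e-5 relative for floats.

# Known limitations

* Subfamily assignment, sequence-level feature annotation, and FASTA
  handling are out of scope; subfamily and feature states are consumed as
  input columns.
* The CMH statistic's χ² reference is asymptotic; very sparse strata are
  dropped rather than exactly conditioned on (no exact test).
* The "rest" column definition and replicate pairing rule are single
  documented choices, not per-run options explored combinatorially.
* The generator plants effects independently per gene and per feature; it
  does not emulate correlation structure, batch effects, or probe-level
  noise.
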