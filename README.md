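# l1census

Comparative census and association analysis of **intragenic versus
intergenic full-length LINE-1 (L1) retrotransposons**.

Full-length L1 elements (~6 kb in human, ~7 kb in mouse) lie either inside
gene bodies — *intragenic*, where their transcripts can act in antisense on
the host pre-mRNA — or outside them (*intergenic*). The two populations
differ in structural conservation and in their relationship to host-gene
regulation during early embryogenesis. `l1census` packages the complete
analysis chain for a user with a gene annotation, an L1 element table with
structural-feature annotations, and a staged expression matrix:

1. **Genomic classification and density.** Each element is classified
   against gene spans (first to last exon of the largest transcript
   isoform) as `intragenic_total`, `intragenic_partial` (≥ 1 bp overlap) or
   `intergenic`, and element densities are reported per chromosome class
   (autosome, X, Y) in counts per Mbp (cMbp), with intragenic/intergenic
   denominators taken from the union of gene spans and its complement.
2. **Age-stratified conservation screen.** For every categorical structural
   feature, a 2×2 table (location × conserved/mutated) is built per L1
   subfamily stratum — subfamily serving as an element-age proxy — and
   combined by the Cochran–Mantel–Haenszel statistic without continuity
   correction,

   ```
   X² = (Σᵢ aᵢ − Σᵢ Eᵢ)² / Σᵢ Vᵢ ,   Eᵢ = (aᵢ+bᵢ)(aᵢ+cᵢ)/nᵢ ,
   Vᵢ = (aᵢ+bᵢ)(cᵢ+dᵢ)(aᵢ+cᵢ)(bᵢ+dᵢ)/(nᵢ²(nᵢ−1)) ,
   ```

   with the Mantel–Haenszel common odds ratio
   `OR = Σᵢ(aᵢdᵢ/nᵢ) / Σᵢ(bᵢcᵢ/nᵢ)` and a Robins–Breslow–Greenland 95% CI.
   Quantitative features use Welch unequal-variance t-tests. Significance
   threshold: p < 1.0E-03, no multiplicity adjustment.
3. **Expression association.** Per-gene paired t-tests (replicates paired
   by index) call each stage up/down/ns against the one-cell reference at
   p < 0.05; a 2×2 chi-square (L1 present/absent × called-in-direction /
   rest, no continuity correction) with OR = ad/bc and Woolf 95% CI tests
   whether L1-hosting genes are enriched among down- (or up-) regulated
   genes, significant at p < 1.0E-03 **and** OR > 1. Gene sets of the
   significant stages are intersected (with Venn region counts) and joined
   across species through an ortholog pair table.
4. **Synthetic data.** A seeded generator emulates all inputs — genome
   annotation (GFF3), chromosome sizes, an L1 table with planted
   per-stratum feature odds ratios, and a staged expression matrix with a
   planted L1/down-regulation association — plus truth tables, enabling
   type-I calibration and parameter-recovery studies with no downloads.

## Worked example

```r
library(l1census)

cfg <- simulation_config(seed = 11)          # mouse-like desk-scale defaults
bundle <- simulate_bundle(cfg, "demo_inputs")

res <- run_all(run_config(
  genes       = "demo_inputs/genes.gff3",
  chrom_sizes = "demo_inputs/chrom_sizes.tsv",
  l1          = "demo_inputs/l1.tsv",
  expression  = "demo_inputs/expression.tsv",
  l1_genes    = "demo_inputs/l1_genes.txt",
  outdir      = "demo_out"))

str(res$summary)
#> List of 4
#>  $ n_total        : int 4200
#>  $ n_intragenic   : int 1001
#>  $ pct_intragenic : num 23.8
#>  $ n_genes_with_l1: int 844
```

23.8% of the 4,200 simulated elements overlap a gene span, hosted by 844
genes. Autosomal densities separate the two compartments (intragenic
elements are planted uniformly, so their density per intragenic Mbp
exceeds the intergenic density):

```r
subset(res$densities, chromosome_class == "autosome")
#>     species chromosome_class region_class l1_count region_length_mbp density_cmbp
#>   synthetic         autosome          all     3800            190.00        20.00
#>   synthetic         autosome   intragenic      896             35.84        25.00
#>   synthetic         autosome   intergenic     2904            154.16        18.84
```

The conservation screen recovers the planted feature structure (defaults
plant conserved-state rates 0.8 intragenic vs 0.5 intergenic, a
per-stratum odds ratio of 4):

```r
head(subset(res$conservation, significant), 3)[, c("feature", "p", "or", "direction")]
#>                       feature        p   or                     direction
#>           UTR5_promoter_motif 1.32e-60 3.84 conserved-enriched-intragenic
#>   UTR5_antisense_SA154_splice 1.37e-65 4.10 conserved-enriched-intragenic
#>               ORF1_residue_01 9.65e-61 3.94 conserved-enriched-intragenic
```

and the stage screen recovers the planted L1/down-regulation association
(planted OR = (0.30/0.70)/(0.20/0.80) = 1.714) at every stage:

```r
res$screen$assoc[res$screen$assoc$direction == "down",
                 c("stage", "p", "or", "ci_low", "ci_high", "significant")]
#>      stage        p   or ci_low ci_high significant
#>     2-cell 6.08e-08 1.73   1.42    2.11        TRUE
#>     4-cell 9.64e-08 1.70   1.40    2.08        TRUE
#>     8-cell 1.05e-07 1.71   1.40    2.09        TRUE
#>     morula 6.51e-08 1.71   1.41    2.09        TRUE
#> blastocyst 1.05e-07 1.71   1.40    2.09        TRUE
```

A thin command-line front end over the same functions is installed at
`system.file("scripts", "l1census", package = "l1census")` with subcommands
`simulate`, `classify`, `density`, `conserve`, `expr-assoc`, `intersect`,
`orthologs` and `run-all`.

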