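# methint

Integrated methylome–transcriptome analysis for two-group studies of mixed
immune-cell populations (such as PBMCs in rheumatoid arthritis versus
healthy donors), built as an R package plus a numbered analysis workflow.

DNA methylation studies of autoimmune disease face a recurring set of
analytical steps: classify every CpG by its sequence context, remove
cell-composition and batch confounding inherent to mixed-cell tissue, test
for differential methylation and expression under FDR control, and ask
whether the two layers change together — and whether genetic risk loci
preferentially sit where both layers change. `methint` implements that
pipeline end-to-end and ships a synthetic-data generator with recorded
ground truth so every stage is testable without any external download.

## What the package computes

- **CpG feature classes from sequence.** CpG islands are called with the
  classical composition definition — a region of more than 200 bp with GC
  content strictly above 50% and observed/expected CpG ratio
  `(#CpG × L) / (#C × #G)` strictly above 0.60 — via a 200-bp sliding window
  (1-bp step), merge of qualifying windows, trimming of terminal non-GC
  bases, and revalidation of the merged interval against the definition.
  Each CpG site is then an **island** site, a **shore** (≤ 2 kb from an
  island), a **shelf** (2–4 kb) or **open sea** (> 4 kb).
- **Genic context.** Each CpG is assigned one of promoter
  ([TSS − 2000, TSS + 500) in gene orientation), enhancer, gene body or
  intergenic, with precedence promoter > enhancer > gene body > intergenic,
  plus a signed strand-aware TSS distance.
- **Covariate adjustment.** Per CpG, beta values are residualised on batch
  indicators and cell fractions (never on the group label) and recentred:
  `beta* = beta − X(X'X)⁻¹X'beta + mean(beta)`, clipped to [0, 1].
- **Differential methylation / expression.** Region-level (per gene ×
  promoter/enhancer/gene-body) mean betas are compared between groups by
  Welch's t-test; expression counts are log2-CPM normalised and tested the
  same way; both use Benjamini–Hochberg FDR with significance at q < 0.05.
- **Integration.** CpGs are split at the mean methylation variance into
  HIGH/LOW and the expression variance of anchored genes is compared
  (one-sided Mann–Whitney U); DM regions and DE genes are intersected under
  direction rules — promoter/enhancer methylation anticorrelated with
  expression, gene-body methylation positively correlated.
- **Genetic–epigenetic interaction.** Disease-GWAS genes and their
  first-degree PPI neighbors are tested for enrichment of concordant DM+DE
  genes against non-disease-GWAS genes and their neighbors (two-sided
  Fisher exact test, odds ratio with Haldane correction at zero cells).

## Worked example

```r
library(methint)

bundle <- simulate_bundle(sim_config(seed = 1), dir = "results/bundle")
res <- run_pipeline(bundle, out_dir = "results/pipeline")

res$strata$feature_difference$summary
#>       class    n        mean    variance
#>      ISLAND 2658  0.04673046 0.004717919
#>       SHORE 1223  0.02287681 0.001916687
#>       SHELF 1179 -0.03224837 0.001565329
#>    OPEN_SEA 4678 -0.02632903 0.001337849

sum(res$dm$significant); sum(res$de$significant); nrow(res$concordant)
#> [1] 32
#> [1] 16
#> [1] 24

res$enrichment$table
#>                 dmde
#> set              yes no
#>   ra_expanded     13 13
#>   nonra_expanded   0 12
res$enrichment$p
#> [1] 0.00256
```

Reading: on the default synthetic cohort (2 × 600 kb genome, 9,738 CpGs, 60
genes, 10 samples per group), islands and shores come out hypermethylated in
the case group and shelves/open seas hypomethylated (mean RA − HD
difference per class above), matching the planted sign pattern. 32 of 150
gene–regions are differentially methylated and 16 of 60 genes differentially
expressed at q < 0.05; 24 (gene, region) records survive the
direction-aware intersection. The disease-GWAS set plus PPI neighbors is
strongly enriched for those concordant genes (13/26 versus 0/12, odds ratio
25, Fisher p = 0.0026) — the generator plants this enrichment.

The same steps, with commentary, live in `analysis/01_simulate.R` …
`analysis/07_genetic_epigenetic.R`; each writes its tables under
`results/tables/`.

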