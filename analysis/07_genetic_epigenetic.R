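#!/usr/bin/env Rscript
# Step 8: genetic-epigenetic interaction. Tests whether disease-GWAS genes
# and their first-degree PPI interactors are enriched for concordant DM+DE
# genes relative to non-disease-GWAS genes and their interactors (two-sided
# Fisher exact test on the 2x2 table over the union of the expanded sets).

suppressPackageStartupMessages(library(methint))

b <- read_bundle("results/bundle")
res <- run_pipeline("results/bundle")

background <- intersect(unique(res$dm$gene), res$de$gene)
dmde <- intersect(unique(res$concordant$gene), background)
ra_exp <- expand_with_neighbors(b$ra_genes, b$ppi, background)
nonra_exp <- expand_with_neighbors(b$nonra_genes, b$ppi, background)
enr <- enrichment_test(dmde, ra_exp, nonra_exp, background)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(list(table = enr$table, odds_ratio = enr$odds_ratio,
                          p = enr$p, overlap_rule = enr$overlap_rule),
                     "results/tables/enrichment.json", auto_unbox = TRUE,
                     digits = NA)

cat("RA-expanded vs non-RA-expanded x DM+DE status:\n")
print(enr$table)
cat(sprintf("odds ratio = %.2f, two-sided Fisher exact p = %.3g\n",
            enr$odds_ratio, enr$p))
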