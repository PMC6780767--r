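#!/usr/bin/env Rscript
# Steps 6-7: region-level differential methylation (FDR < 0.05), gene-level
# differential expression (FDR < 0.05), and their direction-aware
# intersection: promoter/enhancer regions must be anticorrelated with
# expression, gene-body regions positively correlated.

suppressPackageStartupMessages(library(methint))

b <- read_bundle("results/bundle")
islands <- do.call(rbind, lapply(names(b$sequences), function(chr) {
  isl <- call_cpg_islands(b$sequences[[chr]])
  if (nrow(isl)) cbind(chrom = chr, isl) else NULL
}))
annot <- assign_genic_class(cpg_feature_classes(b$sites, islands),
                            b$genes, b$enhancers)
adj <- adjust_covariates(b$meth$beta, b$meth$samples)

dm <- test_dm_regions(region_methylation(adj, annot), b$meth$samples,
                      alpha = 0.05)
de <- test_de(normalize_log_cpm(b$counts), b$meth$samples, alpha = 0.05)
cc <- intersect_dm_de(dm, de, alpha = 0.05, enforce_direction = TRUE)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(dm, "results/tables/dm_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(de, "results/tables/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cc, "results/tables/concordant_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_dm <- b$truth$true_dm_genes
cat(sprintf("DM regions at q < 0.05: %d of %d tested (%d distinct genes)\n",
            sum(dm$significant), nrow(dm),
            length(unique(dm$gene[dm$significant]))))
cat(sprintf("  of which truly DM: %d\n",
            length(intersect(unique(dm$gene[dm$significant]), truth_dm))))
cat(sprintf("DE genes at q < 0.05: %d of %d\n", sum(de$significant),
            nrow(de)))
cat(sprintf("Concordant (direction-consistent DM+DE) records: %d\n",
            nrow(cc)))
print(cc, row.names = FALSE)
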