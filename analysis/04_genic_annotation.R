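#!/usr/bin/env Rscript
# Step 4: genic-context annotation (promoter / enhancer / gene body /
# intergenic) and the TSS-distance profile of promoter CpGs.
#
# Promoters are hypermethylated in RA while enhancers, gene bodies and
# intergenic CpGs are hypomethylated, and promoter methylation variability
# concentrates near the TSS — the generator plants this gradient and the
# profile recovers it.

suppressPackageStartupMessages(library(methint))

b <- read_bundle("results/bundle")
islands <- do.call(rbind, lapply(names(b$sequences), function(chr) {
  isl <- call_cpg_islands(b$sequences[[chr]])
  if (nrow(isl)) cbind(chrom = chr, isl) else NULL
}))
annot <- cpg_feature_classes(b$sites, islands)
annot <- assign_genic_class(annot, b$genes, b$enhancers)

adj <- adjust_covariates(b$meth$beta, b$meth$samples)
delta <- methylation_difference(adj, b$meth$samples)
v <- methylation_variance(adj)

gd <- stratify_by_class(delta, annot$genic_class)
gv <- stratify_by_class(v, annot$genic_class)

prom <- annot$genic_class == "PROMOTER"
profile <- tss_distance_profile(annot$tss_distance[prom], delta[prom],
                                variances = v[prom])

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(cbind(gd$summary, mean_variance = gv$summary$mean),
            "results/tables/genic_class_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(profile, "results/tables/tss_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Genic-class methylation differences (RA - HD):\n")
print(gd$summary, row.names = FALSE)
cat(sprintf("Kruskal-Wallis p: difference %.3g, variance %.3g\n", gd$p, gv$p))
cat("TSS-distance profile (variance peaks near the TSS):\n")
print(profile, row.names = FALSE)
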