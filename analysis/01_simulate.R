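#!/usr/bin/env Rscript
# Step 1 of the workflow: generate the synthetic two-group PBMC cohort.
#
# The bundle emulates the structure of a methylome+transcriptome study of
# rheumatoid arthritis (RA) versus healthy donors (HD): a small genome with
# planted CpG islands on a CpG-depleted AT-rich background, gene models and
# enhancers, per-CpG beta values with class-specific group shifts on a
# quarter of genes (islands/shores/promoters hypermethylated in RA; shelves,
# open seas, enhancers, gene bodies, intergenic hypomethylated), batch and
# cell-composition confounding, and NB expression counts coupled to region
# methylation. Ground truth is recorded in truth.json.

suppressPackageStartupMessages(library(methint))

cfg <- sim_config(seed = 1)
dir <- "results/bundle"
bundle <- simulate_bundle(cfg, dir = dir)

cat("Simulated cohort written to", dir, "\n")
cat(sprintf("  %d chromosomes x %g bp, %d genes, %d enhancers\n",
            cfg$n_chrom, cfg$chrom_len, nrow(bundle$genes),
            nrow(bundle$enhancers)))
cat(sprintf("  %d CpG sites, %d samples (%d per group)\n",
            nrow(bundle$annotation), nrow(bundle$meth$samples),
            cfg$n_samples_per_group))
cat(sprintf("  %d planted islands, %d true DM genes, %d coupled DE genes\n",
            nrow(bundle$truth$true_islands),
            length(bundle$truth$true_dm_genes),
            nrow(bundle$truth$true_de)))
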