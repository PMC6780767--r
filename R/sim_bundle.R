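#' Simulate a complete, internally consistent fixture bundle
#'
#' Runs all generators in sequence: genome with planted islands, gene models
#' and enhancers, CpG detection and annotation (against the planted island
#' truth), methylation with planted group effects on the true DM genes,
#' expression counts coupled to region methylation, and GWAS/PPI gene sets.
#' Ground truth (planted islands, DM genes with realized region deltas,
#' coupled DE genes with implied log2 fold changes, gene sets) is recorded so
#' downstream tests never re-derive it. With a fixed seed the bundle,
#' including all serialized files, is bit-identical across runs.
#'
#' @param config a [sim_config()] object.
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `genes.tsv`, `enhancers.bed`, `methylation.tsv`, `counts.tsv`,
#'   `samples.tsv`, `gwas_ra.txt`, `gwas_nonra.txt`, `ppi.tsv` and
#'   `truth.json`.
#' @return (invisibly) a list with `config`, `genome`, `genes`, `enhancers`,
#'   `annotation`, `meth`, `counts`, `sets` and `truth`.
#' @export
simulate_bundle <- function(config = sim_config(), dir = NULL) {
  genome <- generate_genome(config)
  models <- generate_gene_models(config, genome)

  sites <- do.call(rbind, lapply(names(genome$sequences), function(chr) {
    data.frame(chrom = chr, pos = find_cpg_sites(genome$sequences[[chr]]))
  }))
  annot <- cpg_feature_classes(sites, genome$islands)
  annot <- assign_genic_class(annot, models$genes, models$enhancers)

  truth <- list(gene_ids = models$genes$gene, true_islands = genome$islands)
  truth$true_dm_genes <- with_seed(config$seed + 5L, {
    n_dm <- round(config$frac_dm_genes * length(truth$gene_ids))
    sort(sample(truth$gene_ids, n_dm))
  })

  meth <- generate_methylation(config, annot, truth)

  # realized region-level planted deltas (mean per-CpG shift per region)
  use <- annot$genic_class %in% c("PROMOTER", "ENHANCER", "GENE_BODY") &
    !is.na(annot$anchor_gene) & annot$anchor_gene %in% truth$true_dm_genes
  if (any(use)) {
    id <- paste(annot$anchor_gene[use], annot$genic_class[use], sep = "\r")
    d <- tapply(meth$shift[use], id, mean)
    parts <- strsplit(names(d), "\r", fixed = TRUE)
    truth$dm_effects <- data.frame(
      gene = vapply(parts, `[`, "", 1L),
      region_class = vapply(parts, `[`, "", 2L),
      delta = as.numeric(d))
  } else {
    truth$dm_effects <- data.frame(gene = character(0),
                                   region_class = character(0),
                                   delta = numeric(0))
  }

  expr <- generate_expression(config, meth, truth)
  truth$true_de <- expr$true_de
  sets <- generate_gene_sets_and_ppi(config, truth)
  truth$ra_genes <- sets$ra_genes
  truth$nonra_genes <- sets$nonra_genes

  out <- list(config = config, genome = genome, genes = models$genes,
              enhancers = models$enhancers, annotation = annot, meth = meth,
              counts = expr$counts, sets = sets, truth = truth)
  if (!is.null(dir)) write_bundle(out, dir)
  invisible(out)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$genome$sequences, file.path(dir, "genome.fa"))
  write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  utils::write.table(bundle$enhancers, file.path(dir, "enhancers.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meth_tab <- cbind(bundle$annotation[, c("chrom", "pos")],
                    as.data.frame(round(bundle$meth$beta, 6)))
  write_tsv(meth_tab, file.path(dir, "methylation.tsv"))
  counts_tab <- cbind(data.frame(gene = rownames(bundle$counts)),
                      as.data.frame(bundle$counts))
  write_tsv(counts_tab, file.path(dir, "counts.tsv"))
  write_tsv(bundle$meth$samples, file.path(dir, "samples.tsv"))
  writeLines(bundle$sets$ra_genes, file.path(dir, "gwas_ra.txt"))
  writeLines(bundle$sets$nonra_genes, file.path(dir, "gwas_nonra.txt"))
  write_tsv(bundle$sets$ppi, file.path(dir, "ppi.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
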