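#' Run the integrated methylome-transcriptome analysis end-to-end
#'
#' Orchestrates all stages on a bundle (in-memory list from
#' [simulate_bundle()] or a directory of bundle files): island calling from
#' sequence (or a supplied island set), CpG feature and genic annotation,
#' covariate adjustment, sample structure (PCA + hierarchical clustering),
#' per-chromosome summary, class-stratified difference/variance statistics,
#' methylation-expression variance linkage, region-level differential
#' methylation and gene-level differential expression at the FDR threshold,
#' direction-aware intersection, and the genetic-epigenetic enrichment test.
#' A stage failure aborts with the stage name and cause.
#'
#' @param bundle bundle list or directory path.
#' @param out_dir optional directory for stage outputs (TSV/JSON) and
#'   `run_manifest.json`.
#' @param fdr_meth,fdr_expr FDR thresholds for the two tests.
#' @param params island-calling parameters ([island_params()]).
#' @param shore_bp,shelf_bp feature-class distance boundaries.
#' @param promoter_up,promoter_down promoter window around the TSS.
#' @param enforce_direction require direction-consistent DM/DE intersection.
#' @param adjust apply covariate adjustment before all methylation stages.
#' @param islands optional pre-computed island data.frame (`chrom`, `start`,
#'   `end`) to bypass sequence-based calling.
#' @return list of stage results (see names of the returned list).
#' @export
run_pipeline <- function(bundle, out_dir = NULL, fdr_meth = 0.05,
                         fdr_expr = 0.05, params = island_params(),
                         shore_bp = 2000L, shelf_bp = 4000L,
                         promoter_up = 2000L, promoter_down = 500L,
                         enforce_direction = TRUE, adjust = TRUE,
                         islands = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sequences <- if (!is.null(bundle$genome)) bundle$genome$sequences else
    bundle$sequences
  sites <- stage("cpg_sites", {
    if (!is.null(bundle$annotation)) bundle$annotation[, c("chrom", "pos")]
    else if (!is.null(bundle$sites)) bundle$sites
    else do.call(rbind, lapply(names(sequences), function(chr) {
      data.frame(chrom = chr, pos = find_cpg_sites(sequences[[chr]]))
    }))
  })
  islands <- stage("cpg_islands", {
    if (!is.null(islands)) islands
    else do.call(rbind, lapply(names(sequences), function(chr) {
      isl <- call_cpg_islands(sequences[[chr]], params)
      if (nrow(isl)) cbind(chrom = chr, isl[, c("start", "end")])
      else NULL
    }))
  })
  genes <- if (!is.null(bundle$genes)) bundle$genes else
    stop("pipeline stage 'annotation' failed: no gene models in bundle")
  annot <- stage("annotation", {
    a <- cpg_feature_classes(sites, islands, shore_bp = shore_bp,
                             shelf_bp = shelf_bp)
    assign_genic_class(a, genes, bundle$enhancers,
                       promoter_up = promoter_up,
                       promoter_down = promoter_down)
  })
  beta <- bundle$meth$beta
  samples <- bundle$meth$samples
  adjusted <- stage("covariate_adjustment", {
    if (adjust) adjust_covariates(beta, samples) else beta
  })
  structure_res <- stage("sample_structure",
                         pca_and_cluster(adjusted, samples, k = 2L))
  delta <- stage("methylation_difference",
                 methylation_difference(adjusted, samples))
  variance <- stage("methylation_variance", methylation_variance(adjusted))
  chrom_sum <- stage("chromosome_summary",
                     chromosome_summary(annot$chrom, delta))
  strata <- stage("class_strata", list(
    feature_difference = stratify_by_class(delta, annot$feature_class),
    feature_variance = stratify_by_class(variance, annot$feature_class),
    genic_difference = stratify_by_class(delta, annot$genic_class),
    genic_variance = stratify_by_class(variance, annot$genic_class)
  ))
  log_cpm <- stage("normalization", normalize_log_cpm(bundle$counts))
  expr_var <- stage("expression_variance", expression_variance(log_cpm))
  var_assoc <- stage("variance_linkage", {
    vc <- split_variance_classes(variance)
    variance_association(vc, annot, expr_var)
  })
  regions <- stage("region_methylation", region_methylation(adjusted, annot))
  dm <- stage("dm_regions", test_dm_regions(regions, samples,
                                            alpha = fdr_meth))
  de <- stage("de_genes", test_de(log_cpm, samples, alpha = fdr_expr))
  concordant <- stage("dm_de_intersection",
                      intersect_dm_de(dm, de, alpha = min(fdr_meth, fdr_expr),
                                      enforce_direction = enforce_direction))
  enrichment <- stage("genetic_epigenetic", {
    background <- intersect(unique(dm$gene), de$gene)
    ra_genes <- if (!is.null(bundle$sets)) bundle$sets$ra_genes else
      bundle$ra_genes
    nonra_genes <- if (!is.null(bundle$sets)) bundle$sets$nonra_genes else
      bundle$nonra_genes
    ppi <- if (!is.null(bundle$sets)) bundle$sets$ppi else bundle$ppi
    dmde <- intersect(unique(concordant$gene), background)
    ra_exp <- expand_with_neighbors(ra_genes, ppi, background)
    nonra_exp <- expand_with_neighbors(nonra_genes, ppi, background)
    enrichment_test(dmde, ra_exp, nonra_exp, background)
  })
  res <- list(islands = islands, annotation = annot, adjusted = adjusted,
              structure = structure_res, delta = delta, variance = variance,
              chromosome_summary = chrom_sum, strata = strata,
              log_cpm = log_cpm, expression_variance = expr_var,
              variance_association = var_assoc, regions = regions,
              dm = dm, de = de, concordant = concordant,
              enrichment = enrichment)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir, fdr_meth = fdr_meth,
                           fdr_expr = fdr_expr,
                           enforce_direction = enforce_direction,
                           adjust = adjust, params = params)
  }
  res
}

#' Per-chromosome summary of methylation differences
#'
#' Tabular stand-in for a genome-wide circular plot: one row per chromosome
#' with the number of CpGs, mean absolute difference, and the fractions of
#' hyper-, hypo- and unchanged CpGs (which sum to 1).
#'
#' @param chrom chromosome per CpG.
#' @param delta per-CpG methylation difference (RA - HD).
#' @return data.frame: `chrom`, `n_cpg`, `mean_abs_delta`, `frac_hyper`,
#'   `frac_hypo`, `frac_zero`.
#' @export
chromosome_summary <- function(chrom, delta) {
  stopifnot(length(chrom) == length(delta))
  out <- lapply(split(delta, chrom), function(d) {
    data.frame(n_cpg = length(d), mean_abs_delta = mean(abs(d)),
               frac_hyper = mean(d > 0), frac_hypo = mean(d < 0),
               frac_zero = mean(d == 0))
  })
  cbind(data.frame(chrom = names(out)), do.call(rbind, out),
        row.names = NULL)
}

write_pipeline_outputs <- function(res, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opts <- list(...)
  write_tsv(res$islands, file.path(out_dir, "islands.bed.tsv"))
  write_tsv(res$annotation, file.path(out_dir, "cpg_annotation.tsv"))
  scores <- as.data.frame(res$structure$scores[, 1:min(5, ncol(res$structure$scores))])
  scores <- cbind(data.frame(sample = rownames(res$structure$scores),
                             cluster = res$structure$clusters), scores)
  write_tsv(scores, file.path(out_dir, "pca_scores.tsv"))
  write_tsv(res$chromosome_summary,
            file.path(out_dir, "chromosome_summary.tsv"))
  strata_tab <- do.call(rbind, lapply(names(res$strata), function(nm) {
    cbind(data.frame(stratum = nm), res$strata[[nm]]$summary,
          data.frame(kw_p = res$strata[[nm]]$p))
  }))
  write_tsv(strata_tab, file.path(out_dir, "class_strata.tsv"))
  write_tsv(res$variance_association,
            file.path(out_dir, "variance_association.tsv"))
  write_tsv(res$dm, file.path(out_dir, "dm_regions.tsv"))
  write_tsv(res$de, file.path(out_dir, "de_results.tsv"))
  write_tsv(res$concordant, file.path(out_dir, "concordant_genes.tsv"))
  jsonlite::write_json(
    list(table = res$enrichment$table,
         odds_ratio = res$enrichment$odds_ratio, p = res$enrichment$p,
         overlap_rule = res$enrichment$overlap_rule),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "run_manifest.json"))
  manifest <- list(
    settings = opts[c("fdr_meth", "fdr_expr", "enforce_direction", "adjust")],
    island_params = unclass(opts$params),
    counts = list(n_islands = nrow(res$islands),
                  n_cpg = nrow(res$annotation),
                  n_regions_tested = nrow(res$dm),
                  n_genes_tested = nrow(res$de),
                  n_dm = sum(res$dm$significant),
                  n_de = sum(res$de$significant),
                  n_concordant = nrow(res$concordant)),
    files = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
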