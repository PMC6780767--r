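#' Generate GWAS-like gene sets and a PPI edge list
#'
#' The RA-associated set is sampled with weight `gwas_enrichment` on DM+DE
#' genes (1 = uniform, the null); the non-RA set is sampled uniformly from
#' the remaining genes. PPI edges are wired so that, at enrichment factors
#' above 1, RA genes preferentially interact with additional DM+DE genes;
#' at factor 1 the wiring is uniform. The edge list is undirected, has no
#' self-loops and is deduplicated.
#'
#' @param config a [sim_config()] object.
#' @param ground_truth list with `gene_ids` and `true_de` (data.frame with a
#'   `gene` column; the DM+DE genes).
#' @return list with `ra_genes`, `nonra_genes` (character vectors) and `ppi`
#'   (data.frame `a`, `b`).
#' @export
generate_gene_sets_and_ppi <- function(config, ground_truth) {
  genes <- ground_truth$gene_ids
  dmde <- ground_truth$true_de$gene
  f <- config$gwas_enrichment
  if (config$n_ra_genes + config$n_nonra_genes > length(genes)) {
    stop("gene-set sizes exceed the number of genes")
  }
  with_seed(config$seed + 4L, {
    w <- ifelse(genes %in% dmde, f, 1)
    ra <- sample(genes, config$n_ra_genes, prob = w)
    nonra <- sample(setdiff(genes, ra), config$n_nonra_genes)
    p_wire <- (f - 1) / f
    edges <- matrix(character(0), 0, 2)
    extra_dmde <- setdiff(dmde, ra)
    for (i in seq_len(config$n_ppi_edges)) {
      if (stats::runif(1) < p_wire && length(extra_dmde) > 0L) {
        a <- sample(ra, 1L)
        b <- sample(extra_dmde, 1L)
      } else {
        pair <- sample(genes, 2L)
        a <- pair[1L]; b <- pair[2L]
      }
      edges <- rbind(edges, sort(c(a, b)))
    }
    keep <- edges[, 1L] != edges[, 2L] & !duplicated(paste(edges[, 1L],
                                                           edges[, 2L]))
    ppi <- data.frame(a = edges[keep, 1L], b = edges[keep, 2L])
    list(ra_genes = ra, nonra_genes = nonra, ppi = ppi)
  })
}
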