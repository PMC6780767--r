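#' Generate expression counts coupled to region methylation
#'
#' Negative-binomial-like counts per gene and sample. For coupled genes (the
#' true DM genes), the log mean is shifted by
#' `- coupling_strength * (promoter beta + enhancer beta)
#'  + coupling_strength * (gene-body beta)`
#' using the gene's per-sample region mean betas, so promoter/enhancer
#' methylation decreases and gene-body methylation increases expression.
#' Uncoupled genes are independent of methylation. Per-gene expression noise
#' is optionally scaled with the gene's realized methylation variance
#' (`var_coupling`), linking methylation variability to expression
#' variability. Sample library factors are log-normal around the configured
#' library size.
#'
#' @param config a [sim_config()] object.
#' @param meth output of [generate_methylation()].
#' @param ground_truth list with `gene_ids` (all genes) and `true_dm_genes`.
#' @return list with `counts` (gene x sample integer matrix) and `true_de`
#'   (data.frame `gene`, `log2fc`: the coupling-implied expression change of
#'   each coupled gene, computed from the planted region deltas).
#' @export
generate_expression <- function(config, meth, ground_truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- ground_truth$gene_ids
  G <- length(genes)
  m <- nrow(meth$samples)
  k <- config$coupling_strength
  with_seed(config$seed + 3L, {
    rel <- exp(stats::rnorm(G, log(50), 1))
    eta <- matrix(log(rel), G, m)

    coupled <- genes %in% ground_truth$true_dm_genes
    reg <- region_methylation(meth$beta, meth$annotation)
    if (any(coupled) && nrow(reg$key) > 0L) {
      sgn <- ifelse(reg$key$region_class == "GENE_BODY", 1, -1)
      gidx <- match(reg$key$gene, genes)
      for (r in which(!is.na(gidx) & coupled[gidx])) {
        eta[gidx[r], ] <- eta[gidx[r], ] + sgn[r] * k * reg$means[r, ]
      }
    }

    # methylation-variance -> expression-noise link
    sd_g <- rep(0.15, G)
    if (config$var_coupling > 0) {
      v <- methylation_variance(meth$beta)
      vg <- tapply(v, meth$annotation$anchor_gene, mean)
      score <- vg[genes] / mean(v)
      score[is.na(score)] <- 1
      sd_g <- pmax(0.15 * (1 + config$var_coupling * (score - 1)), 0.02)
    }
    eta <- eta + matrix(stats::rnorm(G * m, 0, rep(sd_g, times = m)), G, m)

    mu <- exp(eta)
    lib_factor <- exp(stats::rnorm(m, 0, config$lib_size_sd))
    mu <- sweep(mu, 2, lib_factor, "*")
    mu <- mu * config$lib_size / mean(colSums(mu))
    counts <- matrix(stats::rnbinom(G * m, mu = mu,
                                    size = 1 / config$nb_dispersion), G, m)
    dimnames(counts) <- list(genes, meth$samples$sample)

    true_de <- coupling_log2fc(config, ground_truth)
    list(counts = counts, true_de = true_de)
  })
}

# Expected log2 fold change implied by the planted region deltas and the
# coupling rule, for each coupled gene.
coupling_log2fc <- function(config, truth) {
  eff <- truth$dm_effects
  if (is.null(eff) || nrow(eff) == 0L) {
    return(data.frame(gene = character(0), log2fc = numeric(0)))
  }
  sgn <- ifelse(eff$region_class == "GENE_BODY", 1, -1)
  lfc <- tapply(sgn * config$coupling_strength * eff$delta, eff$gene, sum) /
    log(2)
  data.frame(gene = names(lfc), log2fc = as.numeric(lfc))
}
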