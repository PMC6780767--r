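# Region-level simulation studies used to verify FDR control and parameter
# recovery of the differential-methylation and differential-expression tests.

#' One-CpG-per-gene annotation for region-level simulation studies
#'
#' Builds a minimal CpG annotation in which each gene is represented by a
#' single CpG of the given region class, so region means equal CpG values and
#' the region-level test can be studied in isolation.
#'
#' @param n_genes number of genes.
#' @param region_class genic class of every CpG.
#' @param feature_class CpG feature class of every CpG.
#' @return annotation data.frame accepted by [generate_methylation()].
#' @export
region_study_annotation <- function(n_genes, region_class = "PROMOTER",
                                    feature_class = "OPEN_SEA") {
  data.frame(chrom = "chr1", pos = seq_len(n_genes) * 100L,
             feature_class = feature_class, genic_class = region_class,
             anchor_gene = sprintf("g%04d", seq_len(n_genes)),
             tss_distance = NA_real_)
}

#' Neutral simulation configuration for region-level studies
#'
#' A [sim_config()] with no batch, cell-composition or class-variance
#' structure, so the methylation noise SD is exactly `noise_sd` on the logit
#' scale (about `noise_sd / 4` on the beta scale near beta = 0.5).
#'
#' @param seed RNG seed.
#' @param n_per_group samples per group.
#' @param noise_sd logit-scale noise SD (default 0.2, about 0.05 on the beta
#'   scale).
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config` object.
#' @export
region_study_config <- function(seed, n_per_group = 10L, noise_sd = 0.2,
                                ...) {
  flat <- c(ISLAND = 1, SHORE = 1, SHELF = 1, OPEN_SEA = 1)
  flat_g <- c(PROMOTER = 1, ENHANCER = 1, GENE_BODY = 1, INTERGENIC = 1)
  defaults <- list(seed = seed, n_samples_per_group = n_per_group,
                   noise_sd = noise_sd, batch_effects = c(0, 0),
                   cell_effects = rep(0, 5), tss_variance_bump = 0,
                   variance_multipliers = list(feature = flat,
                                               genic = flat_g))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' False-discovery-proportion study for the region-level methylation test
#'
#' Simulates replicate cohorts of null and shifted genes (one CpG per gene),
#' runs [region_methylation()] + [test_dm_regions()] at the given FDR
#' threshold, and reports the per-replicate false-discovery proportion
#' FP / max(1, calls) together with the recovered region deltas of the
#' shifted genes.
#'
#' @param reps number of replicate cohorts.
#' @param n_null,n_dm numbers of null and shifted genes.
#' @param delta planted region-level beta shift (RA - HD) of the DM genes.
#' @param n_per_group samples per group.
#' @param noise_sd logit-scale noise SD.
#' @param alpha FDR threshold.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with `fdp` (per replicate), `mean_fdp`, `power` (mean
#'   proportion of shifted genes called) and `mean_delta_hat` (mean recovered
#'   delta of shifted genes per replicate).
#' @export
dm_fdr_study <- function(reps = 50L, n_null = 1800L, n_dm = 200L,
                         delta = 0.2, n_per_group = 10L, noise_sd = 0.2,
                         alpha = 0.05, seed = 1L) {
  n_genes <- n_null + n_dm
  annot <- region_study_annotation(n_genes)
  dm_genes <- annot$anchor_gene[seq_len(n_dm)]
  truth <- list(true_dm_genes = dm_genes,
                dm_effects = data.frame(gene = dm_genes,
                                        region_class = rep("PROMOTER", n_dm),
                                        delta = rep(delta, n_dm)))
  fdp <- power <- mean_delta_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- region_study_config(seed + r, n_per_group = n_per_group,
                               noise_sd = noise_sd)
    meth <- generate_methylation(cfg, annot, truth)
    dm <- test_dm_regions(region_methylation(meth$beta, meth$annotation),
                          meth$samples, alpha = alpha)
    called <- dm$gene[dm$significant]
    fdp[r] <- sum(!(called %in% dm_genes)) / max(1L, length(called))
    power[r] <- mean(dm_genes %in% called)
    mean_delta_hat[r] <- mean(dm$delta[dm$gene %in% dm_genes])
  }
  list(fdp = fdp, mean_fdp = mean(fdp), power = mean(power),
       mean_delta_hat = mean_delta_hat)
}

#' Log2 fold-change recovery study for the expression test
#'
#' Simulates replicate count cohorts with a planted fold change on a subset
#' of genes under negative-binomial noise, runs [normalize_log_cpm()] +
#' [test_de()], and reports the mean recovered log2 fold-change magnitude of
#' the shifted genes per replicate. The planted changes are balanced (half
#' the DE genes up, half down) so that counts-per-million normalisation is
#' not confounded by a group-level composition shift.
#'
#' @param reps replicates.
#' @param n_null,n_de numbers of null and shifted genes.
#' @param log2fc planted log2 fold change (RA vs HD).
#' @param n_per_group samples per group.
#' @param dispersion negative-binomial dispersion.
#' @param seed base seed.
#' @return list with `log2fc_hat` (per replicate, mean over shifted genes),
#'   `mean_log2fc`, and `power` at FDR < 0.05.
#' @export
de_recovery_study <- function(reps = 20L, n_null = 400L, n_de = 100L,
                              log2fc = 2, n_per_group = 10L,
                              dispersion = 0.1, seed = 1L) {
  G <- n_null + n_de
  lfc_hat <- power <- numeric(reps)
  for (r in seq_len(reps)) {
    res <- with_seed(seed + r, {
      base_mu <- exp(stats::rnorm(G, log(100), 1))
      mu <- matrix(base_mu, G, 2L * n_per_group)
      de_idx <- seq_len(n_de)
      up <- de_idx[seq_len(n_de %/% 2L)]
      down <- setdiff(de_idx, up)
      ra <- seq_len(n_per_group)
      mu[up, ra] <- mu[up, ra] * 2^log2fc
      mu[down, ra] <- mu[down, ra] * 2^-log2fc
      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / dispersion), G,
                       2L * n_per_group)
      dimnames(counts) <- list(sprintf("g%04d", seq_len(G)),
                               c(sprintf("RA%02d", seq_len(n_per_group)),
                                 sprintf("HD%02d", seq_len(n_per_group))))
      samples <- data.frame(sample = colnames(counts),
                            group = rep(c("RA", "HD"), each = n_per_group))
      de <- test_de(normalize_log_cpm(counts), samples)
      list(lfc = mean(c(de$log2fc[up], -de$log2fc[down])),
           pow = mean(de$significant[de_idx]))
    })
    lfc_hat[r] <- res$lfc
    power[r] <- res$pow
  }
  list(log2fc_hat = lfc_hat, mean_log2fc = mean(lfc_hat),
       power = mean(power))
}
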