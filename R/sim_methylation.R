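#' Generate a methylation beta-value matrix with planted group effects
#'
#' Per-CpG, per-sample beta values follow a logit-normal model around a
#' beta-scale mean: `mu = baseline + group shift + batch offset + linear
#' cell-fraction term`, and `beta = plogis(rnorm(qlogis(mu), sd))`. The group
#' shift applies only to CpGs anchored to true DM genes: either the summed
#' feature-class and genic-class entries of the config's effect table or,
#' when `ground_truth$dm_effects` is supplied, an explicit per (gene, region
#' class) delta. The noise SD is the config `noise_sd` scaled by class
#' variance multipliers and a TSS-proximity bump for promoter CpGs.
#'
#' @param config a [sim_config()] object.
#' @param cpg_annotation data.frame with one row per CpG: `chrom`, `pos`,
#'   `feature_class`, `genic_class`, `anchor_gene`, `tss_distance`.
#' @param ground_truth list with at least `true_dm_genes` (character), and
#'   optionally `dm_effects` (data.frame `gene`, `region_class`, `delta`).
#' @return list with `beta` (CpG x sample matrix), `samples` (metadata
#'   data.frame: `sample`, `group`, `batch`, `frac_*` columns summing to 1),
#'   `annotation` (the input annotation) and `shift` (the planted per-CpG
#'   group effect).
#' @export
generate_methylation <- function(config, cpg_annotation, ground_truth) {
  stopifnot(inherits(config, "sim_config"),
            all(c("feature_class", "genic_class", "anchor_gene") %in%
                  names(cpg_annotation)))
  n <- nrow(cpg_annotation)
  npg <- config$n_samples_per_group
  m <- 2L * npg
  with_seed(config$seed + 2L, {
    samples <- data.frame(
      sample = c(sprintf("RA%02d", seq_len(npg)),
                 sprintf("HD%02d", seq_len(npg))),
      group = rep(c("RA", "HD"), each = npg),
      batch = rep(((seq_len(npg) - 1L) %% config$n_batches) + 1L, 2L)
    )
    K <- length(config$cell_fraction_dirichlet)
    fr <- matrix(stats::rgamma(m * K,
                               shape = rep(config$cell_fraction_dirichlet,
                                           each = m)), nrow = m)
    fr <- fr / rowSums(fr)
    colnames(fr) <- paste0("frac_", seq_len(K))
    samples <- cbind(samples, as.data.frame(fr))

    shift <- planted_shift(config, cpg_annotation, ground_truth)
    baseline <- stats::runif(n, config$baseline_beta - 0.15,
                             config$baseline_beta + 0.15)
    sample_off <- config$batch_effects[samples$batch] +
      as.numeric(fr %*% config$cell_effects)
    is_ra <- as.numeric(samples$group == "RA")
    mu <- matrix(baseline, n, m) + outer(shift, is_ra) +
      matrix(sample_off, n, m, byrow = TRUE)
    if (any(mu < -0.1 | mu > 1.1)) {
      stop("planted effects push the mean methylation outside (0, 1) ",
           "beyond the clamping tolerance; reduce the effect sizes")
    }
    mu <- pmin(pmax(mu, 0.02), 0.98)

    sd_cpg <- cpg_noise_sd(config, cpg_annotation)
    beta <- matrix(stats::plogis(stats::rnorm(n * m, mean = stats::qlogis(mu),
                                              sd = rep(sd_cpg, times = m))),
                  n, m)
    dimnames(beta) <- list(NULL, samples$sample)
    list(beta = beta, samples = samples, annotation = cpg_annotation,
         shift = shift)
  })
}

# Planted per-CpG group effect (RA - HD) on the beta scale.
planted_shift <- function(config, annot, truth) {
  n <- nrow(annot)
  shift <- numeric(n)
  if (!is.null(truth$dm_effects)) {
    key <- paste(annot$anchor_gene, annot$genic_class)
    eff <- truth$dm_effects
    idx <- match(key, paste(eff$gene, eff$region_class))
    shift[!is.na(idx)] <- eff$delta[idx[!is.na(idx)]]
  } else if (length(truth$true_dm_genes)) {
    et <- config$effect_table
    dm <- !is.na(annot$anchor_gene) & annot$anchor_gene %in% truth$true_dm_genes
    shift[dm] <- et$feature[as.character(annot$feature_class[dm])] +
      et$genic[as.character(annot$genic_class[dm])]
  }
  shift
}

# Per-CpG noise SD on the logit scale.
cpg_noise_sd <- function(config, annot) {
  vm <- config$variance_multipliers
  mult <- vm$feature[as.character(annot$feature_class)] *
    vm$genic[as.character(annot$genic_class)]
  mult[is.na(mult)] <- 1
  prom <- !is.na(annot$genic_class) & annot$genic_class == "PROMOTER" &
    !is.na(annot$tss_distance)
  if (config$tss_variance_bump > 0 && any(prom)) {
    mult[prom] <- mult[prom] *
      (1 + config$tss_variance_bump * exp(-abs(annot$tss_distance[prom]) / 250))
  }
  config$noise_sd * mult
}
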