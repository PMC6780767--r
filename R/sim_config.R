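#' Default per-class methylation shift table
#'
#' Signed mean beta shifts (RA minus HD) applied to CpGs of true DM genes,
#' split into a CpG-feature component and a genic component (the two are
#' summed per CpG). Signs reproduce the expected pattern for RA PBMCs:
#' islands, shores and promoters hypermethylated; shelves, open seas,
#' enhancers, gene bodies and intergenic regions hypomethylated.
#'
#' @return list with numeric vectors `feature` and `genic`.
#' @export
default_effect_table <- function() {
  list(
    feature = c(ISLAND = 0.20, SHORE = 0.15, SHELF = -0.10, OPEN_SEA = -0.08),
    genic = c(PROMOTER = 0.15, ENHANCER = -0.12, GENE_BODY = -0.10,
              INTERGENIC = -0.05)
  )
}

# Class-specific noise multipliers emulating the observed variance ordering:
# islands/shores most variable among CpG features; enhancers > promoters >
# intergenic > gene bodies among genic contexts.
default_variance_multipliers <- function() {
  list(
    feature = c(ISLAND = 1.6, SHORE = 1.4, SHELF = 1.0, OPEN_SEA = 1.1),
    genic = c(PROMOTER = 1.3, ENHANCER = 2.6, GENE_BODY = 0.9,
              INTERGENIC = 1.1)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic fixture bundle: genome geometry, planted CpG
#' islands, gene/enhancer layout, per-class methylation shifts for true DM
#' genes, confounders (batch, cell composition), logit-normal methylation
#' noise, negative-binomial expression counts coupled to region methylation,
#' and GWAS/PPI gene sets enriched for DM+DE genes.
#'
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param n_chrom,chrom_len number and length (bp) of chromosomes.
#' @param n_genes,n_enhancers total genes and enhancer intervals.
#' @param n_samples_per_group samples per group (RA and HD).
#' @param n_batches number of batches; `batch_effects` gives one beta-scale
#'   offset per batch.
#' @param island_density planted islands per Mb; `island_length` in bp.
#' @param frac_tss_island fraction of genes whose TSS carries an island.
#' @param effect_table per-class signed beta shifts, see
#'   [default_effect_table()].
#' @param frac_dm_genes fraction of genes that are truly differentially
#'   methylated.
#' @param coupling_strength non-negative methylation-to-expression link
#'   coefficient (natural-log scale per unit beta); the sign of the effect is
#'   carried by the region-class rule, not by this parameter.
#' @param var_coupling strength of the link between a gene's methylation
#'   variance and its expression noise (0 disables).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param lib_size expected library size; `lib_size_sd` log-scale SD of
#'   sample-specific library factors.
#' @param noise_sd SD of the logit-scale methylation noise (about 0.05 on the
#'   beta scale near beta = 0.5 at the default 0.2).
#' @param baseline_beta center of the per-CpG baseline methylation (baselines
#'   are drawn uniformly within +/- 0.15 of it).
#' @param batch_effects beta-scale offset per batch.
#' @param cell_effects beta-scale coefficient per cell type.
#' @param cell_fraction_dirichlet Dirichlet concentration vector for cell
#'   fractions.
#' @param tss_variance_bump amplitude of the extra methylation variability of
#'   promoter CpGs near the TSS (exp(-|d|/250 bp) kernel; 0 disables).
#' @param variance_multipliers class-specific noise multipliers, see
#'   [default_variance_multipliers()].
#' @param n_ra_genes,n_nonra_genes GWAS gene-set sizes.
#' @param gwas_enrichment enrichment factor (>= 1) of DM+DE genes in the RA
#'   set and its PPI wiring; 1 means no enrichment (null).
#' @param n_ppi_edges number of PPI edges to draw.
#' @param slot_pitch genomic slot pitch in bp (one gene per slot).
#' @param gene_length_range min/max gene body length in bp.
#' @param enhancer_length enhancer interval length in bp.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 6e5,
                       n_genes = 60L,
                       n_enhancers = 30L,
                       n_samples_per_group = 10L,
                       n_batches = 2L,
                       island_density = 42,
                       island_length = 500L,
                       frac_tss_island = 0.6,
                       effect_table = default_effect_table(),
                       frac_dm_genes = 0.25,
                       coupling_strength = 7,
                       var_coupling = 0.5,
                       nb_dispersion = 0.1,
                       lib_size = 3e5,
                       lib_size_sd = 0.15,
                       noise_sd = 0.15,
                       baseline_beta = 0.5,
                       batch_effects = c(0, 0.03),
                       cell_effects = c(0.08, 0, -0.05, 0, 0),
                       cell_fraction_dirichlet = c(18, 8, 6, 4, 4),
                       tss_variance_bump = 0.8,
                       variance_multipliers = default_variance_multipliers(),
                       n_ra_genes = 12L,
                       n_nonra_genes = 12L,
                       gwas_enrichment = 4,
                       n_ppi_edges = 40L,
                       slot_pitch = 15000L,
                       gene_length_range = c(2000L, 4500L),
                       enhancer_length = 500L) {
  counts <- c(n_chrom = n_chrom, chrom_len = chrom_len, n_genes = n_genes,
              n_samples_per_group = n_samples_per_group,
              n_batches = n_batches)
  if (any(counts < 1)) {
    stop("counts must be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (n_enhancers < 0) stop("n_enhancers must be >= 0")
  shifts <- unlist(effect_table)
  if (any(shifts <= -1 | shifts >= 1)) stop("beta shifts must be in (-1, 1)")
  if (frac_dm_genes < 0 || frac_dm_genes > 1) {
    stop("frac_dm_genes must be in [0, 1]")
  }
  if (frac_tss_island < 0 || frac_tss_island > 1) {
    stop("frac_tss_island must be in [0, 1]")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (coupling_strength < 0) {
    stop("coupling_strength must be >= 0; the direction of the ",
         "methylation-expression link is carried by the region-class rule")
  }
  if (gwas_enrichment < 1) stop("gwas_enrichment must be >= 1")
  if (length(batch_effects) != n_batches) {
    stop("batch_effects must have one entry per batch")
  }
  if (length(cell_effects) != length(cell_fraction_dirichlet)) {
    stop("cell_effects must match cell_fraction_dirichlet in length")
  }
  if (any(cell_fraction_dirichlet <= 0)) {
    stop("Dirichlet concentrations must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- structure(as.list(environment()), class = "sim_config")
  chrom_layout(cfg)  # validates geometry (sizing/placement errors)
  cfg
}

# Deterministic genomic layout shared by the genome and gene-model
# generators: one slot per gene, islands anchored at a fixed in-slot offset
# so consecutive planted islands are >= 10 kb apart.
chrom_layout <- function(config) {
  S <- floor(config$chrom_len / config$slot_pitch)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  base <- config$n_genes %/% config$n_chrom
  extra <- config$n_genes %% config$n_chrom
  genes_per_chrom <- base + (seq_len(config$n_chrom) <= extra)
  if (any(genes_per_chrom > S)) {
    stop("cannot place ", config$n_genes, " genes: only ", S,
         " slots of ", config$slot_pitch, " bp per chromosome")
  }
  enh_base <- config$n_enhancers %/% config$n_chrom
  enh_extra <- config$n_enhancers %% config$n_chrom
  enh_per_chrom <- enh_base + (seq_len(config$n_chrom) <= enh_extra)
  if (any(enh_per_chrom > S)) {
    stop("cannot place ", config$n_enhancers, " enhancers without overlap")
  }
  n_isl <- round(config$island_density * config$chrom_len / 1e6)
  layout <- lapply(seq_len(config$n_chrom), function(ci) {
    ng <- genes_per_chrom[ci]
    tss_isl <- min(round(config$frac_tss_island * ng), n_isl)
    spare <- n_isl - tss_isl
    if (spare > S - ng) {
      stop("chrom_len too small to host ", n_isl,
           " islands with >= 10 kb separation")
    }
    slot_start <- (seq_len(S) - 1L) * config$slot_pitch
    anchor <- slot_start + 7000L
    gene_slots <- seq_len(ng)
    # islands: at the TSS of the first tss_isl genes, plus geneless slots
    island_slots <- c(gene_slots[seq_len(tss_isl)],
                      if (spare > 0) (ng + seq_len(spare)))
    list(chrom = chroms[ci], n_slots = S, slot_start = slot_start,
         anchor = anchor, gene_slots = gene_slots,
         island_slots = sort(island_slots),
         enhancer_slots = seq_len(enh_per_chrom[ci]))
  })
  names(layout) <- chroms
  layout
}
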