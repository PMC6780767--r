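small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_chrom = 2, chrom_len = 3e5,
                                 n_genes = 30, n_enhancers = 16,
                                 island_density = 40),
                            list(...))
  do.call(sim_config, args)
}

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(coupling_strength = -1), "carried by the")
  expect_error(sim_config(batch_effects = c(0, 0, 0)), "per batch")
  expect_error(sim_config(frac_dm_genes = 1.2), "frac_dm_genes")
  expect_error(sim_config(effect_table = list(feature = c(ISLAND = 1.5),
                                              genic = c(PROMOTER = 0))),
               "shifts")
  # genome too small for the requested gene count
  expect_error(sim_config(chrom_len = 6e4, n_genes = 100), "slots")
  # too many islands for the separation constraint
  expect_error(sim_config(chrom_len = 1e5, n_genes = 2, n_enhancers = 2,
                          island_density = 500),
               "islands")
})

test_that("the genome generator plants recoverable islands on an AT-rich,
           CpG-depleted background", {
  cfg <- small_config()
  g <- generate_genome(cfg)
  expect_equal(names(g$sequences), c("chr1", "chr2"))
  expect_true(all(nchar(g$sequences) == cfg$chrom_len))
  expect_true(all(g$islands$start >= 0 & g$islands$end <= cfg$chrom_len))
  # planted islands are >= 10 kb apart
  for (chr in unique(g$islands$chrom)) {
    s <- g$islands[g$islands$chrom == chr, ]
    expect_true(all(s$start[-1] - s$end[-nrow(s)] >= 10000))
  }
  # every planted island is recovered; no spurious calls; edges within one
  # window of the truth
  for (chr in names(g$sequences)) {
    called <- call_cpg_islands(g$sequences[[chr]])
    truth <- g$islands[g$islands$chrom == chr, ]
    expect_equal(nrow(called), nrow(truth))
    expect_true(all(abs(called$start - truth$start) < 200))
    expect_true(all(abs(called$end - truth$end) < 200))
  }
  # the planted truth satisfies the definition when re-measured
  for (j in sample(nrow(g$islands), 5)) {
    sub <- substr(g$sequences[[g$islands$chrom[j]]], g$islands$start[j] + 1,
                  g$islands$end[j])
    expect_gt(gc_content(sub), 0.5)
    expect_gt(obs_exp_cpg(sub), 0.6)
  }
  # zero island density: background only, empty truth, no calls
  g0 <- generate_genome(small_config(island_density = 0, frac_tss_island = 0))
  expect_equal(nrow(g0$islands), 0L)
  expect_equal(nrow(call_cpg_islands(g0$sequences[["chr1"]])), 0L)
})

test_that("gene models and enhancers are within bounds and non-overlapping", {
  cfg <- small_config()
  g <- generate_genome(cfg)
  mod <- generate_gene_models(cfg, g)
  expect_equal(nrow(mod$genes), cfg$n_genes)
  expect_true(all(mod$genes$start >= 0 & mod$genes$start < mod$genes$end &
                    mod$genes$end <= cfg$chrom_len))
  expect_true(all(mod$genes$tss >= mod$genes$start &
                    mod$genes$tss < mod$genes$end))
  for (chr in unique(mod$genes$chrom)) {
    gg <- mod$genes[mod$genes$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    ee <- mod$enhancers[mod$enhancers$chrom == chr, ]
    # enhancers overlap no gene body or promoter
    for (k in seq_len(nrow(ee))) {
      expect_false(any(ee$start[k] < gg$end & ee$end[k] > gg$start))
    }
  }
  none <- generate_gene_models(small_config(n_enhancers = 0), g)
  expect_equal(nrow(none$enhancers), 0L)
})

test_that("methylation values honor the model contract", {
  cfg <- small_config()
  b <- simulate_bundle(cfg)
  expect_true(all(b$meth$beta >= 0 & b$meth$beta <= 1))
  fr <- as.matrix(b$meth$samples[, grep("^frac_", names(b$meth$samples))])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-6))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(nrow(b$meth$samples), 2 * cfg$n_samples_per_group)
  # counts are non-negative integers
  expect_true(all(b$counts >= 0))
  expect_true(all(b$counts == round(b$counts)))
  # library sizes near the configured target
  expect_true(all(colSums(b$counts) > cfg$lib_size / 3 &
                    colSums(b$counts) < cfg$lib_size * 3))
})

test_that("a null configuration produces no systematic group differences", {
  null_et <- list(feature = c(ISLAND = 0, SHORE = 0, SHELF = 0,
                              OPEN_SEA = 0),
                  genic = c(PROMOTER = 0, ENHANCER = 0, GENE_BODY = 0,
                            INTERGENIC = 0))
  cfg <- small_config(effect_table = null_et, batch_effects = c(0, 0),
                      cell_effects = rep(0, 5))
  b <- simulate_bundle(cfg)
  d <- methylation_difference(b$meth$beta, b$meth$samples)
  v <- methylation_variance(b$meth$beta)
  se <- sqrt(2 * v / cfg$n_samples_per_group)
  expect_gt(mean(abs(d) < 3 * se), 0.99)
  expect_lt(abs(mean(d)), 0.005)
})

test_that("a planted promoter shift of +0.2 is realized in the region means
           at +/- 0.05", {
  annot <- region_study_annotation(400)
  dm_genes <- annot$anchor_gene[1:100]
  truth <- list(true_dm_genes = dm_genes,
                dm_effects = data.frame(gene = dm_genes,
                                        region_class = "PROMOTER",
                                        delta = 0.2))
  meth <- generate_methylation(region_study_config(77, n_per_group = 20),
                               annot, truth)
  reg <- region_methylation(meth$beta, meth$annotation)
  delta <- methylation_difference(reg$means, meth$samples)
  shifted <- reg$key$gene %in% dm_genes
  expect_equal(mean(delta[shifted]), 0.2, tolerance = 0.05)
  expect_lt(abs(mean(delta[!shifted])), 0.05)
})

test_that("expression is coupled to methylation with the configured signs
           and decoupled when the strength is zero", {
  cfg <- small_config()
  b <- simulate_bundle(cfg)
  # promoter-hypermethylated DM genes have negative implied log2fc
  eff <- b$truth$dm_effects
  prom_hyper <- eff$gene[eff$region_class == "PROMOTER" & eff$delta > 0]
  lfc <- b$truth$true_de
  expect_true(all(lfc$log2fc[lfc$gene %in% prom_hyper &
                               !lfc$gene %in%
                               eff$gene[eff$region_class == "GENE_BODY"]] < 0))
  # coupling 0: per-gene promoter methylation and expression are unrelated
  annot <- region_study_annotation(500)
  truth0 <- list(gene_ids = annot$anchor_gene,
                 true_dm_genes = annot$anchor_gene,
                 dm_effects = data.frame(gene = annot$anchor_gene,
                                         region_class = "PROMOTER",
                                         delta = 0))
  cfg0 <- region_study_config(31, coupling_strength = 0, var_coupling = 0)
  meth0 <- generate_methylation(cfg0, annot, truth0)
  expr0 <- generate_expression(cfg0, meth0, truth0)
  reg0 <- region_methylation(meth0$beta, meth0$annotation)
  pb <- rowMeans(reg0$means)
  lc <- rowMeans(log1p(expr0$counts[reg0$key$gene, , drop = FALSE]))
  expect_lt(abs(cor(pb, lc)), 0.1)
})

test_that("gene sets and PPI are well-formed and respond to the enrichment
           factor", {
  cfg <- small_config()
  b <- simulate_bundle(cfg)
  ppi <- b$sets$ppi
  expect_true(all(ppi$a != ppi$b))
  expect_false(any(duplicated(paste(pmin(ppi$a, ppi$b),
                                    pmax(ppi$a, ppi$b)))))
  expect_true(all(c(ppi$a, ppi$b) %in% b$genes$gene))
  expect_equal(length(b$sets$ra_genes), cfg$n_ra_genes)
  expect_equal(length(intersect(b$sets$ra_genes, b$sets$nonra_genes)), 0L)
  # factor-1 wiring is uniform: RA sets over seeds are not DM-enriched
  dmde_frac <- vapply(1:20, function(s) {
    bb <- generate_gene_sets_and_ppi(small_config(seed = s,
                                                  gwas_enrichment = 1),
                                     b$truth)
    mean(bb$ra_genes %in% b$truth$true_de$gene)
  }, 0)
  base_rate <- length(b$truth$true_de$gene) / nrow(b$genes)
  expect_lt(abs(mean(dmde_frac) - base_rate), 0.12)
})

test_that("a fixed seed reproduces the bundle bit-identically, including all
           serialized files", {
  cfg <- small_config(seed = 9)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b1 <- simulate_bundle(cfg, dir = d1)
  b2 <- simulate_bundle(cfg, dir = d2)
  expect_identical(b1$meth$beta, b2$meth$beta)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$genome$sequences, b2$genome$sequences)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the data
  b3 <- simulate_bundle(small_config(seed = 10))
  expect_false(identical(b1$meth$beta, b3$meth$beta))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a bundle round-trips through its serialized files", {
  cfg <- small_config(seed = 4)
  d <- file.path(tempdir(), "bundle_rt")
  b <- simulate_bundle(cfg, dir = d)
  rb <- read_bundle(d)
  expect_equal(rb$sequences, b$genome$sequences)
  expect_equal(rb$genes, b$genes)
  expect_equal(unname(rb$counts), unname(b$counts))
  expect_equal(as.numeric(rb$meth$beta), as.numeric(round(b$meth$beta, 6)),
               tolerance = 1e-9)
  expect_setequal(rb$truth$true_dm_genes, b$truth$true_dm_genes)
  unlink(d, recursive = TRUE)
})
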