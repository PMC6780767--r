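test_that("covariate adjustment removes planted batch and cell effects but
           preserves group contrasts", {
  set.seed(11)
  n_cpg <- 300; npg <- 8
  samples <- make_samples(npg, n_batches = 2)
  fr <- matrix(rgamma(2 * npg * 3, shape = c(6, 3, 2)), ncol = 3,
               byrow = TRUE)
  fr <- fr / rowSums(fr)
  colnames(fr) <- paste0("frac_", 1:3)
  samples <- cbind(samples, as.data.frame(fr))
  noise <- matrix(rnorm(n_cpg * 2 * npg, 0, 0.02), n_cpg)
  base <- matrix(runif(n_cpg, 0.3, 0.7), n_cpg, 2 * npg)

  # no covariate effects: adjustment is nearly a no-op (changes stay below
  # the noise SD for essentially all values)
  raw <- base + noise
  adj <- adjust_covariates(raw, samples)
  expect_lt(quantile(abs(adj - raw), 0.99), 0.04)
  expect_lt(mean(abs(adj - raw)), 0.01)

  # beta exactly linear in one cell fraction: residuals vanish
  lin <- base + matrix(0.3 * fr[, 1], n_cpg, 2 * npg, byrow = TRUE)
  adj_lin <- adjust_covariates(lin, samples)
  expect_lt(max(apply(adj_lin, 1, var)) / max(apply(lin, 1, var)), 1e-12)

  # planted batch offset +0.1 is removed
  off <- ifelse(samples$batch == 2, 0.1, 0)
  batched <- raw + matrix(off, n_cpg, 2 * npg, byrow = TRUE)
  adj_b <- adjust_covariates(batched, samples)
  bm <- tapply(colMeans(adj_b), samples$batch, mean)
  expect_lt(abs(diff(bm)), 0.01)

  # group effects survive adjustment
  grp <- raw + outer(rep(0.2, n_cpg), as.numeric(samples$group == "RA"))
  d <- methylation_difference(adjust_covariates(grp, samples), samples)
  expect_equal(mean(d), 0.2, tolerance = 0.02)

  expect_error(adjust_covariates(raw[, 1:4], samples[1:4, ]),
               "fewer samples")
})

test_that("methylation difference is the RA minus HD group mean and is
           antisymmetric under label swap", {
  samples <- make_samples(2)
  m <- rbind(c(0.6, 0.8, 0.5, 0.5))
  expect_equal(methylation_difference(m, samples), 0.2)
  expect_equal(methylation_difference(cbind(m[, 1:2, drop = FALSE],
                                            m[, 1:2, drop = FALSE]),
                                      samples), 0)
  swapped <- samples
  swapped$group <- rev(samples$group)
  expect_equal(methylation_difference(m, swapped),
               -methylation_difference(m, samples))
  bad <- samples
  bad$group <- "RA"
  expect_error(methylation_difference(m, bad), "both groups")
})

test_that("methylation variance is the unbiased definitional variance", {
  expect_equal(methylation_variance(rbind(rep(0.4, 5))), 0)
  expect_equal(methylation_variance(rbind(c(0, 1))), 0.5)
  m <- matrix(runif(50), 5)
  expect_equal(methylation_variance(m + 0.1), methylation_variance(m),
               tolerance = 1e-12)
  expect_equal(methylation_variance(m), apply(m, 1, var), tolerance = 1e-12)
  expect_error(methylation_variance(matrix(1, 2, 1)), "2 samples")
})

test_that("class stratification orders planted shifts and flags degenerate
           input", {
  set.seed(3)
  cls <- factor(sample(c("ISLAND", "SHORE", "SHELF", "OPEN_SEA"), 10000,
                       replace = TRUE))
  shift <- c(ISLAND = 0.04, SHORE = 0.02, SHELF = -0.02, OPEN_SEA = -0.01)
  vals <- rnorm(10000, shift[as.character(cls)], 0.02)
  st <- stratify_by_class(vals, cls)
  expect_lt(st$p, 1e-3)
  got <- st$summary$mean[match(names(shift), st$summary$class)]
  expect_equal(order(got), order(shift))
  # single class: undefined test
  one <- stratify_by_class(vals, factor(rep("ISLAND", 10000)))
  expect_true(one$degenerate)
  expect_true(is.na(one$p))
  # identically distributed classes: no systematic signal
  ps <- vapply(1:40, function(i) {
    stratify_by_class(rnorm(200), factor(sample(letters[1:4], 200, TRUE)))$p
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("variance split is strict-greater-than-mean and scale
           equivariant", {
  expect_equal(as.character(split_variance_classes(c(0.1, 0.3))),
               c("LOW", "HIGH"))
  expect_true(all(split_variance_classes(rep(0.2, 5)) == "LOW"))
  v <- runif(100)
  expect_identical(split_variance_classes(v), split_variance_classes(3 * v))
})

test_that("region methylation averages member CpGs per sample", {
  beta <- rbind(c(0.2, 0.6), c(0.4, 0.8), c(0.9, 0.1))
  annot <- data.frame(anchor_gene = c("g1", "g1", "g2"),
                      genic_class = c("PROMOTER", "PROMOTER", "INTERGENIC"))
  reg <- region_methylation(beta, annot)
  expect_equal(nrow(reg$means), 1L)  # intergenic CpGs excluded
  expect_equal(unname(reg$means[1, ]), c(0.3, 0.7))
  expect_equal(reg$key$n_cpg, 2L)
  # permuting CpG order changes nothing
  reg2 <- region_methylation(beta[c(2, 1, 3), ], annot[c(2, 1, 3), ])
  expect_equal(reg$means, reg2$means)
  # a one-CpG region equals that CpG
  annot1 <- data.frame(anchor_gene = "g3", genic_class = "GENE_BODY")
  expect_equal(unname(region_methylation(rbind(c(0.15, 0.85)),
                                         annot1)$means[1, ]),
               c(0.15, 0.85))
})

test_that("region-level test matches t.test and its BH matches the step-up
           oracle", {
  set.seed(21)
  samples <- make_samples(6)
  means <- matrix(runif(40 * 12), 40)
  reg <- list(means = means,
              key = data.frame(gene = sprintf("g%02d", 1:40),
                               region_class = "PROMOTER",
                               n_cpg = 1L))
  dm <- test_dm_regions(reg, samples)
  for (i in c(1, 7, 40)) {
    tt <- t.test(means[i, 1:6], means[i, 7:12])
    expect_equal(dm$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(dm$delta[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  expect_equal(dm$q, oracle_bh(dm$p), tolerance = 1e-12)
  expect_true(all(dm$q >= dm$p))
  # canonical BH example: p = .01,.02,.03,.04 with m = 4 -> all q = .04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("degenerate zero-variance regions get p = 1 (equal means) or
           p = 0 (unequal means, flagged)", {
  samples <- make_samples(2)
  means <- rbind(c(0.5, 0.5, 0.5, 0.5), c(0.8, 0.8, 0.2, 0.2))
  reg <- list(means = means,
              key = data.frame(gene = c("a", "b"), region_class = "PROMOTER",
                               n_cpg = 1L))
  dm <- test_dm_regions(reg, samples)
  expect_equal(dm$p, c(1, 0))
  expect_equal(dm$degenerate, c(TRUE, TRUE))
})

test_that("the region test controls false positives under the null and has
           power against a 0.2 shift", {
  null_res <- dm_fdr_study(reps = 15, n_null = 200, n_dm = 0, delta = 0,
                           seed = 100)
  # with no true signal every call is false; calls must be rare
  expect_lte(mean(null_res$fdp > 0), 0.2)
  sig <- dm_fdr_study(reps = 10, n_null = 180, n_dm = 20, delta = 0.2,
                      seed = 200)
  expect_gte(sig$power, 0.9)
  expect_equal(mean(sig$mean_delta_hat), 0.2, tolerance = 0.05)
})

test_that("PCA and clustering recover constructed group structure", {
  set.seed(5)
  samples <- make_samples(5)
  # rank-1 group structure, tiny jitter to avoid exact ties in clustering
  sig <- outer(runif(200, 0.5, 1), as.numeric(samples$group == "RA") - 0.5)
  res <- pca_and_cluster(0.5 + sig + matrix(rnorm(2000, 0, 1e-4), 200),
                         samples)
  expect_gt(res$explained[1], 0.99)
  expect_equal(res$ari, 1)
  expect_true(all(diff(res$explained) <= 1e-8))
  expect_equal(sum(res$explained), 1)
  # pure noise: no agreement with labels on average
  aris <- vapply(1:10, function(i) {
    pca_and_cluster(matrix(runif(200 * 10), 200), samples)$ari
  }, 0)
  expect_lt(abs(mean(aris)), 0.25)
  expect_error(pca_and_cluster(matrix(runif(30), 3), make_samples(5), k = 11),
               "exceed")
})
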