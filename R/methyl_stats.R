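#' Remove cell-composition and batch effects from a beta-value matrix
#'
#' Per CpG, fits ordinary least squares of beta on batch indicators and cell
#' fractions (the group label is deliberately excluded so the group contrast
#' is preserved), then replaces the values by residual + grand mean, clipped
#' to \[0, 1\]. One cell-fraction column is dropped since fractions sum to 1;
#' any remaining collinear covariates are dropped with a warning.
#'
#' @param beta CpG x sample matrix of beta values in \[0, 1\].
#' @param samples sample metadata data.frame with `sample`, `group`, `batch`
#'   and cell-fraction columns starting with `frac_`.
#' @return adjusted matrix of the same shape.
#' @export
adjust_covariates <- function(beta, samples) {
  stopifnot(ncol(beta) == nrow(samples))
  frac_cols <- grep("^frac_", names(samples), value = TRUE)
  X <- stats::model.matrix(~1, data = samples)
  if (length(unique(samples$batch)) > 1L) {
    X <- cbind(X, stats::model.matrix(~0 + factor(batch), data = samples)[, -1L,
                                                                          drop = FALSE])
  }
  if (length(frac_cols) > 1L) {
    # drop the last fraction: fractions sum to 1 (collinear with intercept)
    X <- cbind(X, as.matrix(samples[, frac_cols[-length(frac_cols)],
                                    drop = FALSE]))
  }
  if (nrow(X) < ncol(X) + 2L) {
    stop("fewer samples than covariates + 2; cannot adjust")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qrX$rank, " collinear covariate column(s)")
  }
  res <- t(qr.resid(qrX, t(beta)))
  adj <- res + rowMeans(beta)
  adj[adj < 0] <- 0
  adj[adj > 1] <- 1
  dimnames(adj) <- dimnames(beta)
  adj
}

#' Per-CpG methylation difference (case minus control)
#'
#' @param beta CpG x sample beta matrix.
#' @param samples metadata with a `group` column coded RA/HD.
#' @return numeric vector: mean over RA samples minus mean over HD samples.
#' @export
methylation_difference <- function(beta, samples) {
  gi <- group_indices(samples)
  rowMeans(beta[, gi$ra, drop = FALSE]) - rowMeans(beta[, gi$hd, drop = FALSE])
}

#' Per-CpG methylation variance across all samples
#'
#' Unbiased (n - 1) variance pooled across both groups, matching a single
#' "variance of methylation" axis.
#'
#' @param beta CpG x sample beta matrix (>= 2 samples).
#' @return numeric vector of per-CpG variances.
#' @export
methylation_variance <- function(beta) {
  if (ncol(beta) < 2L) stop("need at least 2 samples")
  row_vars(beta)
}

#' Summarise a per-CpG statistic by class with an omnibus test
#'
#' Per-class mean, variance and count, plus a Kruskal-Wallis omnibus p-value
#' across the non-empty classes. With fewer than two non-empty classes the
#' test is undefined and flagged.
#'
#' @param values per-CpG statistic (e.g. methylation difference or variance).
#' @param classes factor of the same length (feature or genic classes).
#' @return list with `summary` (data.frame class/n/mean/variance), `p`
#'   (Kruskal-Wallis) and `degenerate` flag.
#' @export
stratify_by_class <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  classes <- as.factor(classes)
  s <- data.frame(
    class = levels(classes),
    n = as.integer(table(classes)),
    mean = as.numeric(tapply(values, classes, mean)),
    variance = as.numeric(tapply(values, classes, stats::var))
  )
  nonempty <- levels(classes)[table(classes) > 0]
  if (length(nonempty) < 2L) {
    return(list(summary = s, p = NA_real_, degenerate = TRUE))
  }
  keep <- classes %in% nonempty
  kw <- stats::kruskal.test(values[keep], droplevels(classes[keep]))
  list(summary = s, p = kw$p.value, degenerate = FALSE)
}

#' Split CpGs into high- and low-variance classes
#'
#' HIGH iff the CpG's methylation variance strictly exceeds the mean variance
#' over all CpGs, LOW otherwise.
#'
#' @param variances per-CpG variances.
#' @return factor with levels HIGH, LOW.
#' @export
split_variance_classes <- function(variances) {
  stopifnot(length(variances) >= 1L)
  factor(ifelse(variances > mean(variances), "HIGH", "LOW"),
         levels = c("HIGH", "LOW"))
}

#' Region-level methylation: mean beta per (gene, region class, sample)
#'
#' Arithmetic mean of member-CpG betas per sample over promoter, enhancer and
#' gene-body CpGs anchored to each gene. Regions with no CpGs simply do not
#' appear.
#'
#' @param beta CpG x sample beta matrix (rows aligned with `annot`).
#' @param annot annotation data.frame with `anchor_gene` and `genic_class`.
#' @return list with `means` (region x sample matrix) and `key` (data.frame
#'   `gene`, `region_class`, `n_cpg` aligned with the rows of `means`).
#' @export
region_methylation <- function(beta, annot) {
  stopifnot(nrow(beta) == nrow(annot))
  use <- annot$genic_class %in% c("PROMOTER", "ENHANCER", "GENE_BODY") &
    !is.na(annot$anchor_gene)
  if (!any(use)) {
    return(list(means = matrix(numeric(0), 0, ncol(beta),
                               dimnames = list(NULL, colnames(beta))),
                key = data.frame(gene = character(0),
                                 region_class = character(0),
                                 n_cpg = integer(0))))
  }
  b <- beta[use, , drop = FALSE]
  id <- paste(annot$anchor_gene[use], annot$genic_class[use], sep = "\r")
  sums <- rowsum(b, id)
  counts <- as.integer(table(id)[rownames(sums)])
  means <- sums / counts
  parts <- strsplit(rownames(means), "\r", fixed = TRUE)
  key <- data.frame(gene = vapply(parts, `[`, "", 1L),
                    region_class = vapply(parts, `[`, "", 2L),
                    n_cpg = counts)
  rownames(means) <- NULL
  list(means = means, key = key)
}

#' Region-level differential methylation with BH FDR control
#'
#' Welch two-sample t-test per region on (covariate-adjusted) region mean
#' betas, with Benjamini-Hochberg adjustment over all tested regions.
#' Zero-variance regions are handled as degenerate: p = 1 for equal means,
#' p = 0 (flagged) otherwise.
#'
#' @param regions output of [region_methylation()] (list with `means`, `key`).
#' @param samples sample metadata with `group` coded RA/HD (>= 2 per group).
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame: `gene`, `region_class`, `n_cpg`, `delta` (RA - HD),
#'   `statistic`, `p`, `q`, `significant`, `degenerate`.
#' @export
test_dm_regions <- function(regions, samples, alpha = 0.05) {
  gi <- group_indices(samples)
  w <- row_welch(regions$means, gi$ra, gi$hd)
  out <- cbind(regions$key[, c("gene", "region_class", "n_cpg")], w)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out$df <- NULL
  rownames(out) <- NULL
  out
}

#' PCA and hierarchical clustering of samples on the methylome
#'
#' PCA on the column-centered sample x CpG matrix (samples as observations),
#' agglomerative clustering with Euclidean distance and Ward linkage cut at
#' `k`, and the adjusted Rand agreement between clusters and group labels.
#'
#' @param beta CpG x sample beta matrix (>= 3 samples).
#' @param samples sample metadata with `group`.
#' @param k number of clusters to cut.
#' @return list with `scores` (sample x PC), `explained` (variance fractions),
#'   `clusters` (integer labels) and `ari`.
#' @export
pca_and_cluster <- function(beta, samples, k = 2L) {
  n <- ncol(beta)
  if (n < 3L) stop("need at least 3 samples")
  if (k > n) stop("k cannot exceed the number of samples")
  X <- t(beta)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  list(scores = pc$x, explained = explained, clusters = cl,
       ari = mclust::adjustedRandIndex(cl, samples$group))
}
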