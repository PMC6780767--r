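#' Assign each CpG a genic class and signed TSS distance
#'
#' Every CpG receives exactly one of PROMOTER, ENHANCER, GENE_BODY or
#' INTERGENIC, with precedence PROMOTER > ENHANCER > GENE_BODY > INTERGENIC,
#' plus an anchor gene and a signed, strand-aware distance to the nearest TSS
#' (negative = upstream of the TSS in gene orientation).
#'
#' The promoter window is `[tss - promoter_up, tss + promoter_down)` in gene
#' orientation. Promoter and gene-body sites anchor to the matched gene
#' (nearest TSS among matches); enhancer and intergenic sites anchor to the
#' gene with the nearest TSS.
#'
#' @param sites_df data.frame with `chrom`, `pos` (0-based CpG positions).
#' @param genes data.frame with `gene`, `chrom`, `strand` (+/-), `start`,
#'   `end` (0-based half-open), `tss`.
#' @param enhancers data.frame with `chrom`, `start`, `end` (may have 0 rows).
#' @param promoter_up,promoter_down promoter window in bp around the TSS
#'   (upstream / downstream in gene orientation); must be non-negative.
#' @return `sites_df` with added columns `genic_class` (factor), `anchor_gene`,
#'   `tss_distance`.
#' @export
assign_genic_class <- function(sites_df, genes, enhancers = NULL,
                               promoter_up = 2000L, promoter_down = 500L) {
  if (promoter_up < 0 || promoter_down < 0) {
    stop("promoter window must be non-negative")
  }
  stopifnot(all(c("chrom", "pos") %in% names(sites_df)),
            all(c("gene", "chrom", "strand", "start", "end", "tss") %in%
                  names(genes)))
  lv <- c("PROMOTER", "ENHANCER", "GENE_BODY", "INTERGENIC")
  n <- nrow(sites_df)
  cls <- rep("INTERGENIC", n)
  anchor <- rep(NA_character_, n)
  tssd <- rep(NA_real_, n)

  for (chr in unique(sites_df$chrom)) {
    si <- which(sites_df$chrom == chr)
    p <- sites_df$pos[si]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) > 0L) {
      # order-independent: process genes in a canonical order
      g <- g[order(g$gene), , drop = FALSE]
      # signed distance matrix: sites x genes
      d <- outer(p, g$tss, "-")
      neg <- g$strand == "-"
      if (any(neg)) d[, neg] <- -d[, neg]
      in_prom <- sweep(d, 2, -promoter_up, ">=") &
        sweep(d, 2, promoter_down, "<")
      in_body <- outer(p, g$start, ">=") & outer(p, g$end, "<")
      absd <- abs(d)
      nearest <- max.col(-absd, ties.method = "first")
      pick <- function(hit) {
        # among hit genes, the one with smallest |tss distance|
        a <- absd
        a[!hit] <- Inf
        max.col(-a, ties.method = "first")
      }
      prom_any <- rowSums(in_prom) > 0
      body_any <- rowSums(in_body) > 0
      gene_for <- nearest
      gene_for[prom_any] <- pick(in_prom)[prom_any]
      gene_for[!prom_any & body_any] <- pick(in_body)[!prom_any & body_any]
      cls[si][prom_any] <- "PROMOTER"
      cls[si][!prom_any & body_any] <- "GENE_BODY"
      anchor[si] <- g$gene[gene_for]
      tssd[si] <- d[cbind(seq_along(p), gene_for)]
    }
    if (!is.null(enhancers) && nrow(enhancers) > 0L) {
      e <- enhancers[enhancers$chrom == chr, , drop = FALSE]
      if (nrow(e) > 0L) {
        in_enh <- rep(FALSE, length(p))
        for (k in seq_len(nrow(e))) {
          in_enh <- in_enh | (p >= e$start[k] & p < e$end[k])
        }
        take <- in_enh & cls[si] != "PROMOTER"
        cls[si][take] <- "ENHANCER"
      }
    }
  }
  sites_df$genic_class <- factor(cls, levels = lv)
  sites_df$anchor_gene <- anchor
  sites_df$tss_distance <- tssd
  sites_df
}

#' Profile methylation change and variability by distance to the TSS
#'
#' Bins promoter CpGs by signed TSS distance and summarises the mean absolute
#' methylation difference and the mean per-CpG methylation variance per bin.
#'
#' @param tss_distance signed TSS distances of promoter CpGs.
#' @param diffs per-CpG methylation difference (case minus control).
#' @param variances optional per-CpG methylation variance; when omitted the
#'   across-site variance of `diffs` within the bin is reported instead.
#' @param breaks bin edges in bp (left-closed, right-open).
#' @return data.frame with one row per bin: `lower`, `upper`, `center`, `n`,
#'   `mean_abs_diff`, `variance`. Empty when there are no promoter sites.
#' @export
tss_distance_profile <- function(tss_distance, diffs, variances = NULL,
                                 breaks = seq(-2000, 500, by = 250)) {
  stopifnot(length(tss_distance) == length(diffs))
  if (length(tss_distance) == 0L) {
    return(data.frame(lower = numeric(0), upper = numeric(0),
                      center = numeric(0), n = integer(0),
                      mean_abs_diff = numeric(0), variance = numeric(0)))
  }
  bin <- cut(tss_distance, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1L]
  lv <- levels(bin)
  n <- as.integer(table(bin))
  mad_ <- tapply(abs(diffs), bin, mean)
  v <- if (is.null(variances)) {
    tapply(diffs, bin, function(x) if (length(x) > 1L) stats::var(x) else NA_real_)
  } else {
    tapply(variances, bin, mean)
  }
  data.frame(lower = lower, upper = upper, center = (lower + upper) / 2,
             n = n,
             mean_abs_diff = as.numeric(mad_[lv]),
             variance = as.numeric(v[lv]))
}
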