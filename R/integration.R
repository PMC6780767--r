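#' Link methylation variability to expression variability
#'
#' For each genic region class, compares the expression variance of genes
#' anchored to HIGH methylation-variance CpGs against genes anchored to LOW
#' methylation-variance CpGs with a one-sided Mann-Whitney U test (HIGH >
#' LOW). A gene contributes once per anchored CpG, so genes with several CpGs
#' are weighted by their CpG count.
#'
#' @param variance_classes factor HIGH/LOW per CpG
#'   (see [split_variance_classes()]).
#' @param annot CpG annotation with `genic_class` and `anchor_gene`, aligned
#'   with `variance_classes`.
#' @param expr_var named per-gene expression variance
#'   (see [expression_variance()]).
#' @param classes region classes to test.
#' @return data.frame per class: `region_class`, `n_high`, `n_low`, `U`,
#'   `rank_biserial`, `p`, `tested` (FALSE when a side is empty).
#' @export
variance_association <- function(variance_classes, annot, expr_var,
                                 classes = c("ENHANCER", "PROMOTER",
                                             "GENE_BODY")) {
  stopifnot(length(variance_classes) == nrow(annot))
  out <- lapply(classes, function(cl) {
    idx <- which(annot$genic_class == cl & annot$anchor_gene %in%
                   names(expr_var))
    hi <- expr_var[annot$anchor_gene[idx][variance_classes[idx] == "HIGH"]]
    lo <- expr_var[annot$anchor_gene[idx][variance_classes[idx] == "LOW"]]
    if (length(hi) == 0L || length(lo) == 0L) {
      return(data.frame(region_class = cl, n_high = length(hi),
                        n_low = length(lo), U = NA_real_,
                        rank_biserial = NA_real_, p = NA_real_,
                        tested = FALSE))
    }
    wt <- stats::wilcox.test(hi, lo, alternative = "greater", exact = FALSE)
    U <- unname(wt$statistic)
    data.frame(region_class = cl, n_high = length(hi), n_low = length(lo),
               U = U, rank_biserial = 2 * U / (length(hi) * length(lo)) - 1,
               p = wt$p.value, tested = TRUE)
  })
  do.call(rbind, out)
}

#' Intersect differentially methylated regions with differentially expressed
#' genes under direction rules
#'
#' A (gene, region class) pair is reported when both the methylation q-value
#' and the expression q-value fall below `alpha`. With `enforce_direction`
#' (the default), promoter and enhancer regions must be anticorrelated
#' (methylation and expression change in opposite directions) while gene-body
#' regions must be positively correlated, reflecting the expected regulatory
#' relationships. Pairs whose direction is undefined (delta or log2fc exactly
#' zero) are excluded.
#'
#' @param dm output of [test_dm_regions()].
#' @param de output of [test_de()].
#' @param alpha FDR threshold applied to both q-values.
#' @param enforce_direction logical; disable for sensitivity analysis.
#' @return data.frame: `gene`, `region_class`, `delta`, `log2fc`, `q_meth`,
#'   `q_expr`, `meth_direction` (hyper/hypo), `expr_direction` (up/down),
#'   `rule`.
#' @export
intersect_dm_de <- function(dm, de, alpha = 0.05, enforce_direction = TRUE) {
  m <- merge(dm[dm$q < alpha, c("gene", "region_class", "delta", "q")],
             de[de$q < alpha, c("gene", "log2fc", "q")],
             by = "gene", suffixes = c("_meth", "_expr"))
  if (nrow(m) == 0L) return(empty_concordant())
  defined <- m$delta != 0 & m$log2fc != 0
  m <- m[defined, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_concordant())
  anti <- m$region_class %in% c("PROMOTER", "ENHANCER")
  m$rule <- ifelse(anti, "anticorrelated", "positively_correlated")
  if (enforce_direction) {
    keep <- ifelse(anti,
                   sign(m$delta) != sign(m$log2fc),
                   sign(m$delta) == sign(m$log2fc))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(empty_concordant())
  m$meth_direction <- ifelse(m$delta > 0, "hyper", "hypo")
  m$expr_direction <- ifelse(m$log2fc > 0, "up", "down")
  m <- m[order(m$gene, m$region_class),
         c("gene", "region_class", "delta", "log2fc", "q_meth", "q_expr",
           "meth_direction", "expr_direction", "rule")]
  rownames(m) <- NULL
  m
}

empty_concordant <- function() {
  data.frame(gene = character(0), region_class = character(0),
             delta = numeric(0), log2fc = numeric(0), q_meth = numeric(0),
             q_expr = numeric(0), meth_direction = character(0),
             expr_direction = character(0), rule = character(0))
}
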