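#' Log2 counts-per-million normalisation
#'
#' `log2((count + prior) / (library size + lib_offset) * 1e6)`. The pseudo
#' counts avoid log(0) while leaving large counts essentially untouched.
#'
#' @param counts gene x sample matrix of non-negative integer counts.
#' @param prior count pseudocount added to each count (default 0.5).
#' @param lib_offset offset added to each library size (default 1).
#' @return gene x sample matrix of log2 CPM values.
#' @export
normalize_log_cpm <- function(counts, prior = 0.5, lib_offset = 1) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column(s): ",
                          paste(which(lib == 0), collapse = ", "))
  log2(sweep(counts + prior, 2, lib + lib_offset, "/") * 1e6)
}

#' Gene-level differential expression with BH FDR control
#'
#' Welch two-sample t-test per gene on log2 CPM values; `log2fc` is the mean
#' log2 CPM in RA minus the mean in HD. BH adjustment over all genes; the same
#' degenerate-case rules as [test_dm_regions()] apply.
#'
#' @param log_cpm gene x sample matrix from [normalize_log_cpm()].
#' @param samples sample metadata with `group` coded RA/HD (>= 2 per group).
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame: `gene`, `log2fc`, `statistic`, `p`, `q`, `significant`,
#'   `degenerate`.
#' @export
test_de <- function(log_cpm, samples, alpha = 0.05) {
  gi <- group_indices(samples)
  w <- row_welch(log_cpm, gi$ra, gi$hd)
  out <- data.frame(gene = rownames(log_cpm), log2fc = w$delta,
                    statistic = w$statistic, p = w$p,
                    degenerate = w$degenerate)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out[, c("gene", "log2fc", "statistic", "p", "q", "significant", "degenerate")]
}

#' Per-gene expression variance
#'
#' Unbiased variance of log2 CPM across all samples.
#'
#' @param log_cpm gene x sample matrix.
#' @return named numeric vector of per-gene variances.
#' @export
expression_variance <- function(log_cpm) {
  v <- row_vars(log_cpm)
  names(v) <- rownames(log_cpm)
  v
}
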