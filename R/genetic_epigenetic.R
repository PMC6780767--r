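#' Expand a gene set with its first-degree PPI neighbors
#'
#' Returns the union of the genes and their direct interactors in the
#' protein-protein interaction network (first degree only; neighbors of
#' neighbors are not included), optionally intersected with a background set.
#'
#' @param genes character vector of gene symbols.
#' @param ppi data.frame with two symbol columns (`a`, `b`), undirected edges.
#' @param background optional symbol set to intersect the result with.
#' @return character vector of symbols.
#' @export
expand_with_neighbors <- function(genes, ppi, background = NULL) {
  genes <- unique(genes)
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    nb <- c(ppi[[2L]][ppi[[1L]] %in% genes], ppi[[1L]][ppi[[2L]] %in% genes])
    genes <- union(genes, nb)
  }
  if (!is.null(background)) genes <- intersect(genes, background)
  genes
}

#' Genetic-epigenetic enrichment test
#'
#' Tests whether genes in the PPI-expanded disease-GWAS set are more likely to
#' be both differentially methylated and differentially expressed (DM+DE) than
#' genes in the expanded non-disease-GWAS set, using a two-sided Fisher exact
#' test on the 2x2 table (rows: RA-expanded vs non-RA-expanded; columns: DM+DE
#' vs not) over the union of the two expanded sets. Genes present in both
#' expanded sets are assigned to the RA row by default (`overlap = "ra"`,
#' conservative toward the disease contrast) or dropped (`overlap = "drop"`).
#' The odds ratio uses a Haldane 0.5 correction when any cell is zero.
#'
#' @param dmde symbol set of DM+DE genes (subset of `background`).
#' @param ra_expanded,nonra_expanded expanded gene sets (subsets of
#'   `background`).
#' @param background all genes tested for both methylation and expression.
#' @param overlap how to resolve genes in both expanded sets.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`, `overlap_n`,
#'   `overlap_rule`.
#' @export
enrichment_test <- function(dmde, ra_expanded, nonra_expanded, background,
                            overlap = c("ra", "drop")) {
  overlap <- match.arg(overlap)
  check_subset <- function(x, nm) {
    if (!all(x %in% background)) {
      stop(nm, " contains genes outside the background")
    }
  }
  check_subset(dmde, "dmde")
  check_subset(ra_expanded, "ra_expanded")
  check_subset(nonra_expanded, "nonra_expanded")
  both <- intersect(ra_expanded, nonra_expanded)
  nonra <- setdiff(nonra_expanded, both)
  ra <- if (overlap == "ra") unique(ra_expanded) else setdiff(ra_expanded, both)
  if (length(ra) == 0L) stop("the RA-expanded set is empty")
  if (length(nonra) == 0L) stop("the non-RA-expanded set is empty")
  tab <- matrix(c(sum(ra %in% dmde), sum(!(ra %in% dmde)),
                  sum(nonra %in% dmde), sum(!(nonra %in% dmde))),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("ra_expanded", "nonra_expanded"),
                                dmde = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(table = tab, odds_ratio = unname(or), p = p,
       overlap_n = length(both), overlap_rule = overlap)
}
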