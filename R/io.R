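# Plain-text readers/writers for the bundle formats. All intervals are
# 0-based half-open; all tables are tab-separated with a header row.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a simulated bundle directory back into memory
#'
#' @param dir directory written by [simulate_bundle()].
#' @return list with `sequences`, `genes`, `enhancers`, `meth` (list `beta`,
#'   `samples`), `counts`, `ra_genes`, `nonra_genes`, `ppi`, `truth`.
#' @export
read_bundle <- function(dir) {
  meth_tab <- read_tsv(file.path(dir, "methylation.tsv"))
  beta <- as.matrix(meth_tab[, -(1:2), drop = FALSE])
  counts_tab <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(counts_tab[, -1L, drop = FALSE])
  rownames(counts) <- counts_tab$gene
  enh_path <- file.path(dir, "enhancers.bed")
  enh <- if (file.size(enh_path) > 0) {
    utils::read.table(enh_path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "name"))
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  }
  list(
    sequences = read_fasta(file.path(dir, "genome.fa")),
    genes = read_tsv(file.path(dir, "genes.tsv")),
    enhancers = enh,
    sites = meth_tab[, 1:2],
    meth = list(beta = beta,
                samples = read_tsv(file.path(dir, "samples.tsv"))),
    counts = counts,
    ra_genes = readLines(file.path(dir, "gwas_ra.txt")),
    nonra_genes = readLines(file.path(dir, "gwas_nonra.txt")),
    ppi = read_tsv(file.path(dir, "ppi.tsv")),
    truth = jsonlite::fromJSON(file.path(dir, "truth.json"))
  )
}
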