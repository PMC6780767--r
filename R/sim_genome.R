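#' Generate a synthetic genome with planted CpG islands
#'
#' The background is AT-rich (GC about 0.35) and strongly CpG-depleted (80%
#' of background CpG dyads removed, mimicking vertebrate CpG depletion), so
#' that no background window can satisfy the island obs/exp criterion.
#' Islands are CpG-dense periodic blocks planted at fixed slot anchors at
#' least 10 kb apart; their composition (GC 0.60-0.68, obs/exp about 1)
#' strictly satisfies the island definition. Ground-truth intervals are
#' recorded 0-based half-open.
#'
#' @param config a [sim_config()] object.
#' @return list with `sequences` (named character vector), `islands`
#'   (data.frame `chrom`, `start`, `end`) and `layout` (internal geometry).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- chrom_layout(config)
  with_seed(config$seed, {
    island_gc <- c(0.60, 0.64, 0.68)
    sequences <- character(0)
    islands <- list()
    isl_i <- 0L
    for (lay in layout) {
      ch <- sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE,
                   prob = c(0.325, 0.175, 0.175, 0.325))
      # CpG depletion: remove 80% of background CpG dyads
      n <- length(ch)
      dy <- which(ch[-n] == "C" & ch[-1L] == "G")
      drop <- dy[stats::runif(length(dy)) < 0.8]
      if (length(drop)) {
        ch[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
      }
      for (slot in lay$island_slots) {
        isl_i <- isl_i + 1L
        start <- lay$anchor[slot] - config$island_length %/% 2L
        end <- start + config$island_length
        reg <- cpg_region_from_targets(config$island_length,
                                       gc = island_gc[(isl_i %% 3L) + 1L],
                                       obs_exp = 1.0)
        ch[(start + 1L):end] <- seq_chars(reg$sequence)
        islands[[isl_i]] <- data.frame(chrom = lay$chrom, start = start,
                                       end = end)
      }
      sequences[lay$chrom] <- paste(ch, collapse = "")
    }
    islands <- if (length(islands)) do.call(rbind, islands) else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }
    list(sequences = sequences, islands = islands, layout = layout)
  })
}

#' Generate gene models and enhancer intervals
#'
#' One gene per genomic slot with random strand and body length; the TSS sits
#' at the slot anchor (where a CpG island is planted for a fraction of
#' genes). Enhancers are placed in a fixed intergenic position of their slot,
#' overlapping no promoter or gene body. All intervals are 0-based half-open
#' and within chromosome bounds.
#'
#' @param config a [sim_config()] object.
#' @param genome output of [generate_genome()] (geometry is re-derived from
#'   `config`, so gene models stay consistent with the planted islands).
#' @return list with `genes` (data.frame `gene`, `chrom`, `strand`, `start`,
#'   `end`, `tss`) and `enhancers` (data.frame `chrom`, `start`, `end`,
#'   `name`).
#' @export
generate_gene_models <- function(config, genome) {
  layout <- chrom_layout(config)
  with_seed(config$seed + 1L, {
    genes <- list()
    enhancers <- list()
    gi <- 0L
    ei <- 0L
    for (lay in layout) {
      for (slot in lay$gene_slots) {
        gi <- gi + 1L
        strand <- sample(c("+", "-"), 1L)
        L <- sample(seq(config$gene_length_range[1L],
                        config$gene_length_range[2L]), 1L)
        a <- lay$anchor[slot]
        if (strand == "+") {
          start <- a; end <- a + L; tss <- a
        } else {
          end <- a + 1L; start <- end - L; tss <- a
        }
        genes[[gi]] <- data.frame(gene = sprintf("g%04d", gi),
                                  chrom = lay$chrom, strand = strand,
                                  start = start, end = end, tss = tss)
      }
      for (slot in lay$enhancer_slots) {
        ei <- ei + 1L
        start <- lay$slot_start[slot] + 12000L
        enhancers[[ei]] <- data.frame(chrom = lay$chrom, start = start,
                                      end = start + config$enhancer_length,
                                      name = sprintf("enh%04d", ei))
      }
    }
    genes <- do.call(rbind, genes)
    enhancers <- if (length(enhancers)) do.call(rbind, enhancers) else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0))
    }
    stopifnot(all(genes$start >= 0), all(genes$end <= config$chrom_len))
    list(genes = genes, enhancers = enhancers)
  })
}
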