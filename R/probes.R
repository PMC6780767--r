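# Definitional-threshold probes: embed constructed candidate regions in
# poly-A flanks and read back which ones the island caller / feature
# annotator accepts. Used to verify that the implementation realizes the
# printed island and shore/shelf definitions exactly.

probe_flank <- function() strrep("A", 1000L)

#' Measure the island caller's minimum-length boundary
#'
#' Embeds CpG-rich blocks (repeated CG dinucleotides, so the composition
#' criteria hold by construction) of the given lengths in poly-A flanks and
#' reports the largest length at which no island is called.
#'
#' @param lengths candidate block lengths in bp.
#' @param params island parameters.
#' @return list with `boundary` (bp) and `called` (logical per length).
#' @export
probe_island_length_boundary <- function(lengths = 150:250,
                                         params = island_params()) {
  flank <- probe_flank()
  called <- vapply(lengths, function(L) {
    block <- substr(strrep("CG", ceiling(L / 2)), 1L, L)
    nrow(call_cpg_islands(paste0(flank, block, flank), params)) > 0
  }, TRUE)
  list(boundary = max(lengths[!called]), called = called,
       lengths = lengths)
}

#' Measure the island caller's GC-content boundary
#'
#' Embeds 300-bp periodic candidate regions with obs/exp CpG ratio well above
#' threshold and GC content varied in 1% steps; reports the largest GC
#' percentage (re-measured on the constructed region) at which no island is
#' called.
#'
#' @param gc_percents GC-content levels in percent.
#' @param params island parameters.
#' @return list with `boundary` (percent), `gc` (achieved percentages) and
#'   `called`.
#' @export
probe_island_gc_boundary <- function(gc_percents = 40:60,
                                     params = island_params()) {
  flank <- probe_flank()
  res <- vapply(gc_percents, function(p) {
    cp <- ceiling(p / 2)
    gp <- p - cp
    dp <- floor(min(cp, gp) * 0.6)
    reg <- make_cpg_region(300L, cp * 3L, gp * 3L, dp * 3L, period = 100L)
    c(gc = 100 * gc_content(reg),
      called = nrow(call_cpg_islands(paste0(flank, reg, flank), params)) > 0)
  }, c(gc = 0, called = 0))
  list(boundary = max(res["gc", res["called", ] == 0]),
       gc = res["gc", ], called = res["called", ] == 1)
}

#' Measure the island caller's observed/expected CpG ratio boundary
#'
#' Embeds 300-bp periodic candidate regions at fixed GC content (65%, well
#' above threshold) whose CpG dyad count is tuned toward each target ratio;
#' reports the largest achieved ratio (as a percentage, re-measured on the
#' constructed region) at which no island is called. Ratios are achievable
#' only on an integer-dyad grid, so the achieved values are reported
#' alongside the calls.
#'
#' @param ratios target observed/expected ratios.
#' @param params island parameters.
#' @return list with `boundary` (percent), `obs_exp` (achieved ratios) and
#'   `called`.
#' @export
probe_island_obsexp_boundary <- function(ratios = seq(0.40, 0.80, by = 0.01),
                                         params = island_params()) {
  flank <- probe_flank()
  res <- vapply(ratios, function(r) {
    dp <- max(0L, min(25L, as.integer(round(r * 10))))
    reg <- make_cpg_region(300L, 120L, 75L, dp * 3L, period = 100L)
    c(oe = obs_exp_cpg(reg),
      called = nrow(call_cpg_islands(paste0(flank, reg, flank), params)) > 0)
  }, c(oe = 0, called = 0))
  list(boundary = 100 * max(res["oe", res["called", ] == 0]),
       obs_exp = res["oe", ], called = res["called", ] == 1)
}

#' Measure the shore and shelf distance boundaries of the feature annotator
#'
#' Plants one island on a synthetic chromosome, calls islands from sequence,
#' places probe sites at 1-bp spaced distances from the called island's
#' boundary and reports the largest distances annotated SHORE and SHELF.
#'
#' @param distances probe distances in bp.
#' @param shore_bp,shelf_bp annotator boundaries.
#' @return list with `shore_boundary` and `shelf_boundary` (bp), and
#'   `classes` (factor per distance).
#' @export
probe_feature_distance_boundary <- function(distances = 1:5000,
                                            shore_bp = 2000L,
                                            shelf_bp = 4000L) {
  reg <- cpg_region_from_targets(400L, gc = 0.64, obs_exp = 1.0)
  chrom <- paste0(probe_flank(), reg$sequence, strrep("A", 6000L))
  isl <- call_cpg_islands(chrom)
  stopifnot(nrow(isl) == 1L)
  sites <- isl$end[1L] - 1L + distances
  cls <- annotate_cpg_features(sites, isl[, c("start", "end")],
                               shore_bp = shore_bp, shelf_bp = shelf_bp)
  list(shore_boundary = max(distances[cls == "SHORE"]),
       shelf_boundary = max(distances[cls == "SHELF"]),
       classes = cls)
}
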