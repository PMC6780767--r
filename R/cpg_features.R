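#' CpG island calling parameters
#'
#' The classical composition-based CpG island definition: a genomic region of
#' more than `min_length` bp with a GC content strictly above `min_gc` and an
#' observed/expected CpG ratio strictly above `min_obs_exp`. The caller slides
#' a window of `window` bp in steps of `step` bp, merges qualifying windows,
#' trims terminal non-GC bases and revalidates the merged interval against the
#' definition.
#'
#' @param min_length minimum island length in bp (strict: a region of exactly
#'   `min_length` bp is not an island).
#' @param min_gc minimum GC fraction (strict).
#' @param min_obs_exp minimum observed/expected CpG ratio (strict).
#' @param window sliding-window width in bp; must not exceed `min_length`.
#' @param step window step in bp.
#' @return a list of class `island_params`.
#' @export
island_params <- function(min_length = 200L, min_gc = 0.5, min_obs_exp = 0.6,
                          window = 200L, step = 1L) {
  stopifnot(min_length > 0, min_gc > 0, min_gc < 1, min_obs_exp > 0,
            window > 0, step > 0, window <= min_length)
  structure(list(min_length = as.integer(min_length), min_gc = min_gc,
                 min_obs_exp = min_obs_exp, window = as.integer(window),
                 step = as.integer(step)),
            class = "island_params")
}

#' Locate CpG dinucleotides in a sequence
#'
#' A CpG dyad is palindromic, so only forward-strand occurrences are reported
#' and each dyad counts as a single site. Positions are 0-based.
#'
#' @param sequence a single chromosome sequence over A/C/G/T/N (case
#'   insensitive). `N` breaks matches.
#' @return integer vector of 0-based positions `p` with `sequence[p..p+2) == "CG"`.
#' @export
find_cpg_sites <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  hits <- which(ch[-n] == "C" & ch[-1L] == "G")
  as.integer(hits - 1L)
}

#' GC content of a sequence window
#'
#' Fraction of C+G among non-N bases; 0 if the window is all N.
#'
#' @param window non-empty sequence string.
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(window) {
  ch <- seq_chars(window)
  if (length(ch) == 0L) stop("window must be non-empty")
  denom <- sum(ch != "N")
  if (denom == 0L) return(0)
  sum(ch == "C" | ch == "G") / denom
}

#' Observed/expected CpG ratio of a sequence window
#'
#' `(#CpG * L) / (#C * #G)` with `L` the number of non-N bases; defined as 0
#' when `#C * #G == 0`.
#'
#' @param window non-empty sequence string.
#' @return non-negative ratio.
#' @export
obs_exp_cpg <- function(window) {
  ch <- seq_chars(window)
  n <- length(ch)
  if (n == 0L) stop("window must be non-empty")
  nc <- sum(ch == "C")
  ng <- sum(ch == "G")
  if (nc == 0L || ng == 0L) return(0)
  ncpg <- if (n >= 2L) sum(ch[-n] == "C" & ch[-1L] == "G") else 0L
  len <- sum(ch != "N")
  ncpg * len / (nc * ng)
}

# Composition of sequence[start..end) (0-based half-open) from precomputed
# cumulative counts; returns length (non-N), gc fraction and obs/exp ratio.
interval_composition <- function(cum, start, end) {
  # cum: list of cumsum vectors prefixed with 0.
  span <- end - start
  nN <- cum$n[end + 1L] - cum$n[start + 1L]
  len <- span - nN
  nc <- cum$c[end + 1L] - cum$c[start + 1L]
  ng <- cum$g[end + 1L] - cum$g[start + 1L]
  # dyads fully inside [start, end): dyad index i (0-based) needs i, i+1 < end
  ncpg <- if (span >= 2L) cum$cpg[end] - cum$cpg[start + 1L] else 0L
  gc <- if (len > 0) (nc + ng) / len else 0
  oe <- if (nc > 0 && ng > 0) ncpg * len / (nc * ng) else 0
  list(length = len, span = span, gc = gc, obs_exp = oe, n_frac = nN / span)
}

seq_cumulants <- function(ch) {
  n <- length(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  isCpG <- if (n >= 2L) c(isC[-n] & isG[-1L], FALSE) else logical(n)
  list(c = c(0L, cumsum(isC)),
       g = c(0L, cumsum(isG)),
       n = c(0L, cumsum(ch == "N")),
       cpg = c(0L, cumsum(isCpG)))
}

#' Call CpG islands from sequence
#'
#' Slides a window along the sequence; a window qualifies when its GC content
#' and observed/expected CpG ratio both strictly exceed the thresholds (windows
#' more than half N are disqualified). Overlapping and adjacent qualifying
#' windows are merged, merged intervals are trimmed of terminal A/T/N bases,
#' and each trimmed interval is kept only when it is itself longer than
#' `min_length` and satisfies both composition criteria when re-measured.
#'
#' @param sequence chromosome sequence string.
#' @param params an [island_params()] object.
#' @return data.frame with columns `start`, `end` (0-based half-open), `length`,
#'   `gc`, `obs_exp`, sorted and non-overlapping. Empty when the sequence is
#'   shorter than the window.
#' @export
call_cpg_islands <- function(sequence, params = island_params()) {
  stopifnot(inherits(params, "island_params"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc = numeric(0),
                      obs_exp = numeric(0))
  ch <- seq_chars(sequence)
  n <- length(ch)
  w <- params$window
  if (n < w) return(empty)
  cum <- seq_cumulants(ch)
  starts <- seq.int(1L, n - w + 1L, by = params$step)  # 1-based window starts
  ends <- starts + w - 1L
  nc <- cum$c[ends + 1L] - cum$c[starts]
  ng <- cum$g[ends + 1L] - cum$g[starts]
  nN <- cum$n[ends + 1L] - cum$n[starts]
  # dyads fully inside the window
  ncpg <- cum$cpg[ends] - cum$cpg[starts]
  len <- w - nN
  gc <- ifelse(len > 0, (nc + ng) / len, 0)
  oe <- ifelse(nc > 0 & ng > 0, ncpg * len / (nc * ng), 0)
  ok <- gc > params$min_gc & oe > params$min_obs_exp & nN <= w / 2
  if (!any(ok)) return(empty)

  # merge overlapping/adjacent qualifying windows by interval union
  qs <- starts[ok] - 1L  # 0-based qualifying window starts, sorted
  run_first <- which(c(TRUE, qs[-1L] > qs[-length(qs)] + w))
  merged_start <- qs[run_first]
  merged_end <- qs[c(run_first[-1L] - 1L, length(qs))] + w
  out <- lapply(seq_along(merged_start), function(k) {
    s0 <- as.integer(merged_start[[k]])         # 0-based merged start
    e0 <- as.integer(merged_end[[k]])           # 0-based merged end (exclusive)
    # trim terminal bases that are not C/G
    while (s0 < e0 && !(ch[s0 + 1L] %in% c("C", "G"))) s0 <- s0 + 1L
    while (e0 > s0 && !(ch[e0] %in% c("C", "G"))) e0 <- e0 - 1L
    if (e0 - s0 <= params$min_length) return(NULL)
    comp <- interval_composition(cum, s0, e0)
    if (comp$length <= params$min_length) return(NULL)
    if (!(comp$gc > params$min_gc && comp$obs_exp > params$min_obs_exp)) {
      return(NULL)
    }
    data.frame(start = s0, end = e0, length = e0 - s0,
               gc = comp$gc, obs_exp = comp$obs_exp)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Classify CpG sites by distance to the nearest CpG island
#'
#' Distance is the 1-based separation between the site and the nearest island
#' boundary base (0 for sites inside an island). Classes: `ISLAND` (d = 0),
#' `SHORE` (0 < d <= `shore_bp`), `SHELF` (`shore_bp` < d <= `shelf_bp`),
#' `OPEN_SEA` (d > `shelf_bp`). With no islands, all sites are open sea.
#'
#' @param sites integer vector of 0-based CpG positions on one chromosome.
#' @param islands data.frame with `start`, `end` (0-based half-open), sorted
#'   and non-overlapping.
#' @param shore_bp,shelf_bp class distance boundaries in bp (inclusive).
#' @return factor with levels ISLAND, SHORE, SHELF, OPEN_SEA, one per site.
#' @export
annotate_cpg_features <- function(sites, islands, shore_bp = 2000L,
                                  shelf_bp = 4000L) {
  stopifnot(shore_bp > 0, shelf_bp > shore_bp)
  lv <- c("ISLAND", "SHORE", "SHELF", "OPEN_SEA")
  if (length(sites) == 0L) return(factor(character(0), levels = lv))
  if (is.null(islands) || nrow(islands) == 0L) {
    return(factor(rep("OPEN_SEA", length(sites)), levels = lv))
  }
  if (is.unsorted(islands$start) ||
      any(islands$start[-1L] < islands$end[-nrow(islands)])) {
    stop("islands must be sorted and non-overlapping")
  }
  d <- island_distance(sites, islands)
  cls <- ifelse(d == 0, "ISLAND",
                ifelse(d <= shore_bp, "SHORE",
                       ifelse(d <= shelf_bp, "SHELF", "OPEN_SEA")))
  factor(cls, levels = lv)
}

# Distance from each 0-based site to the nearest island boundary base;
# 0 inside an island. `islands` sorted, non-overlapping.
island_distance <- function(sites, islands) {
  starts <- islands$start
  ends <- islands$end
  # index of the last island starting at or before the site
  i <- findInterval(sites, starts)
  d_left <- rep(Inf, length(sites))   # distance to island i (at/left of site)
  has_left <- i >= 1L
  if (any(has_left)) {
    e <- ends[i[has_left]]
    p <- sites[has_left]
    d_left[has_left] <- ifelse(p < e, 0, p - (e - 1L))
  }
  d_right <- rep(Inf, length(sites))  # distance to island i+1 (right of site)
  j <- i + 1L
  has_right <- j <= length(starts)
  if (any(has_right)) {
    d_right[has_right] <- starts[j[has_right]] - sites[has_right]
  }
  pmin(d_left, d_right)
}

#' Feature-class annotation for a multi-chromosome CpG table
#'
#' @param sites_df data.frame with `chrom` and `pos` (0-based CpG positions).
#' @param islands_df data.frame with `chrom`, `start`, `end`.
#' @param shore_bp,shelf_bp distance boundaries, see [annotate_cpg_features()].
#' @return `sites_df` with an added `feature_class` factor column.
#' @export
cpg_feature_classes <- function(sites_df, islands_df, shore_bp = 2000L,
                                shelf_bp = 4000L) {
  stopifnot(all(c("chrom", "pos") %in% names(sites_df)))
  cls <- factor(rep(NA_character_, nrow(sites_df)),
                levels = c("ISLAND", "SHORE", "SHELF", "OPEN_SEA"))
  for (chr in unique(sites_df$chrom)) {
    idx <- sites_df$chrom == chr
    isl <- islands_df[islands_df$chrom == chr, , drop = FALSE]
    isl <- isl[order(isl$start), , drop = FALSE]
    cls[idx] <- annotate_cpg_features(sites_df$pos[idx], isl,
                                      shore_bp = shore_bp,
                                      shelf_bp = shelf_bp)
  }
  sites_df$feature_class <- cls
  sites_df
}
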