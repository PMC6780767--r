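#' Construct a CpG-rich candidate region with exact composition
#'
#' Builds a deterministic sequence of the requested length containing exactly
#' `n_c` C bases, `n_g` G bases and `n_cpg` CpG dinucleotides, padded with A.
#' When a `period` is given (it must divide the length, and all counts must be
#' divisible by `length/period`), the sequence is periodic; a periodic region
#' whose period divides the island-caller window guarantees every fully
#' interior window sees exactly the region-level composition, which makes the
#' region ideal for probing the definitional thresholds of the island caller.
#'
#' The per-period layout is `CG`-dyads, then a G run, then a C run, then an A
#' run, which provably creates no accidental CpG within or between periods.
#'
#' @param length region length in bp.
#' @param n_c,n_g,n_cpg total C count, G count and CpG dyad count.
#' @param period optional period in bp.
#' @return sequence string of `length` bp.
#' @export
make_cpg_region <- function(length, n_c, n_g, n_cpg, period = NULL) {
  if (is.null(period)) period <- length
  if (length %% period != 0) stop("period must divide length")
  reps <- length %/% period
  if (n_c %% reps || n_g %% reps || n_cpg %% reps) {
    stop("counts must be divisible by length/period")
  }
  cp <- n_c %/% reps
  gp <- n_g %/% reps
  dp <- n_cpg %/% reps
  if (dp > min(cp, gp)) stop("n_cpg cannot exceed min(n_c, n_g)")
  if (cp + gp > period) stop("n_c + n_g cannot exceed the region length")
  pad <- period - cp - gp
  if (dp == 0L && pad == 0L && reps > 1L && cp > 0L && gp > 0L) {
    stop("cannot avoid accidental CpG at period boundaries; leave padding")
  }
  unit <- if (dp > 0L) {
    paste0(strrep("CG", dp), strrep("G", gp - dp), strrep("C", cp - dp),
           strrep("A", pad))
  } else {
    paste0(strrep("G", gp), strrep("C", cp), strrep("A", pad))
  }
  strrep(unit, reps)
}

#' Construct a region targeting a GC content and observed/expected CpG ratio
#'
#' Convenience wrapper over [make_cpg_region()]: chooses integer base counts
#' per period closest to the requested GC fraction and observed/expected
#' ratio. Because counts are integral, the achieved values can differ from the
#' targets; the achieved composition is returned alongside the sequence.
#'
#' @param length region length (multiple of `period`).
#' @param gc target GC fraction.
#' @param obs_exp target observed/expected CpG ratio.
#' @param period period in bp (default 100).
#' @return list with `sequence`, `gc`, `obs_exp` (achieved values).
#' @export
cpg_region_from_targets <- function(length, gc, obs_exp, period = 100L) {
  reps <- length %/% period
  n_p <- round(gc * period)
  cp <- ceiling(n_p / 2)
  gp <- n_p - cp
  dp <- if (cp > 0 && gp > 0) {
    round(obs_exp * (cp * reps) * (gp * reps) / (length * reps))
  } else 0L
  dp <- max(0L, min(dp, min(cp, gp)))
  s <- make_cpg_region(length, cp * reps, gp * reps, dp * reps,
                       period = period)
  list(sequence = s, gc = gc_content(s), obs_exp = obs_exp_cpg(s))
}
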