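# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Split a sequence string into an uppercase character vector.
seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
}

# Unbiased per-row variance of a numeric matrix.
row_vars <- function(x) {
  m <- ncol(x)
  if (m < 2L) stop("need at least 2 columns to compute a variance")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (m - 1)
}

# Row-wise Welch two-sample t-test. Returns delta = mean(g1) - mean(g2).
# Degenerate rows (zero variance in both groups) get p = 1 when the means are
# equal and p = 0 otherwise, and are flagged.
row_welch <- function(x, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  delta <- m1 - m2
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & delta == 0
    p[eq] <- 1
    p[degenerate & !eq] <- 0
    tstat[degenerate] <- ifelse(delta[degenerate] == 0, 0, Inf * sign(delta[degenerate]))
    df[degenerate] <- NA_real_
  }
  data.frame(delta = delta, statistic = tstat, df = df, p = p,
             degenerate = degenerate)
}

group_indices <- function(samples) {
  if (!all(c("RA", "HD") %in% samples$group)) {
    stop("both groups ('RA' and 'HD') must be present in the sample metadata")
  }
  list(ra = which(samples$group == "RA"), hd = which(samples$group == "HD"))
}
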