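# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (enumeration / direct formulas) and share no code with
# the functions they verify.

# Per-base coverage of the union of ALL substrings satisfying the island
# definition (length > min_length on non-N bases, GC > min_gc, obs/exp >
# min_obs_exp), by exhaustive scan over substring starts.
oracle_island_coverage <- function(sequence, min_length = 200L, min_gc = 0.5,
                                   min_obs_exp = 0.6) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  isN <- ch == "N"
  isCpG <- c(isC[-n] & isG[-1], FALSE)
  pc <- c(0, cumsum(isC)); pg <- c(0, cumsum(isG))
  pn <- c(0, cumsum(isN)); pd <- c(0, cumsum(isCpG))
  covered <- logical(n)
  if (n <= min_length) return(covered)
  for (s in 1:(n - min_length)) {
    e <- (s + min_length):n                  # 1-based inclusive ends
    span <- e - s + 1
    len <- span - (pn[e + 1] - pn[s])
    nc <- pc[e + 1] - pc[s]
    ng <- pg[e + 1] - pg[s]
    nd <- pd[e] - pd[s]                      # dyads fully inside [s, e]
    gc <- ifelse(len > 0, (nc + ng) / len, 0)
    oe <- ifelse(nc > 0 & ng > 0, nd * len / (nc * ng), 0)
    ok <- len > min_length & gc > min_gc & oe > min_obs_exp
    if (any(ok)) covered[s:max(e[ok])] <- TRUE
  }
  covered
}

# Direct Benjamini-Hochberg step-up: q_i = min_{j >= i} (m * p_(j) / j),
# computed on the sorted p-values and mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact p for a 2x2 table by full enumeration over all
# tables with the observed margins: sum of hypergeometric probabilities not
# exceeding the observed table's probability.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(a, c1, r1 + r2 - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, r1 + r2 - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Random genome-like sequence with mixed GC content: AT-rich, CpG-free
# background (GC varying block-wise between 0.25 and 0.40) carrying 0-3
# GC-rich island-like segments (400-800 bp, GC 0.62-0.72) with natural CpG
# rates. With a CpG-free background, every CpG site lies inside an island
# segment, so per-CpG membership agreement between the caller and the
# substring-union oracle is not dominated by the diluted margins that
# surround islands under the bare definition (where composition criteria
# remain satisfied by dilution for a few hundred bp beyond the island, an
# edge zone the windowed caller intentionally does not report).
random_mixed_gc_sequence <- function(n, block = 250L) {
  n_blocks <- ceiling(n / block)
  parts <- vapply(seq_len(n_blocks), function(i) {
    gc <- stats::runif(1, 0.25, 0.40)
    paste(sample(c("A", "C", "G", "T"), block, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, "")
  ch <- strsplit(substr(paste(parts, collapse = ""), 1, n), "")[[1]]
  in_island <- rep(FALSE, n)
  for (k in seq_len(sample(0:3, 1))) {
    len <- sample(400:800, 1)
    for (try in 1:20) {
      s <- sample(n - len, 1)
      if (!any(in_island[max(1, s - 300):min(n, s + len + 300)])) break
      s <- NA
    }
    if (is.na(s)) next
    gc <- stats::runif(1, 0.62, 0.72)
    ch[s:(s + len - 1)] <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2))
    in_island[s:(s + len - 1)] <- TRUE
  }
  # remove every CpG dyad not fully inside an island segment
  dy <- which(ch[-n] == "C" & ch[-1] == "G")
  kill <- dy[!(in_island[dy] & in_island[dy + 1])]
  if (length(kill)) ch[kill + 1] <- "T"
  paste(ch, collapse = "")
}

# Number of CpG sites on which the caller and the oracle agree about island
# membership, plus the total number of sites (for pooling across sequences).
island_membership_agreement <- function(sequence,
                                        params = methint::island_params()) {
  sites <- methint::find_cpg_sites(sequence)
  if (length(sites) == 0) return(c(agree = 0, n = 0))
  isl <- methint::call_cpg_islands(sequence, params)
  in_called <- rep(FALSE, length(sites))
  for (i in seq_len(nrow(isl))) {
    in_called <- in_called | (sites >= isl$start[i] & sites < isl$end[i])
  }
  cov <- oracle_island_coverage(sequence, params$min_length, params$min_gc,
                                params$min_obs_exp)
  c(agree = sum(in_called == cov[sites + 1]), n = length(sites))
}

# Small sample-metadata helper for statistical tests.
make_samples <- function(n_per_group, n_batches = 1L) {
  data.frame(
    sample = c(sprintf("RA%02d", seq_len(n_per_group)),
               sprintf("HD%02d", seq_len(n_per_group))),
    group = rep(c("RA", "HD"), each = n_per_group),
    batch = rep(((seq_len(n_per_group) - 1L) %% n_batches) + 1L, 2L)
  )
}
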