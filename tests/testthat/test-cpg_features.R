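test_that("CpG sites are forward-strand dyad positions", {
  expect_equal(find_cpg_sites("ACGT"), 1L)
  expect_equal(find_cpg_sites("CGCG"), c(0L, 2L))
  expect_equal(find_cpg_sites("AAAA"), integer(0))
  expect_equal(find_cpg_sites("acgt"), 1L)          # case insensitive
  expect_equal(find_cpg_sites("CNG"), integer(0))   # N breaks a dyad
  expect_equal(find_cpg_sites("C"), integer(0))
})

test_that("window composition measures match hand calculations", {
  expect_equal(gc_content("CGCG"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("NNNN"), 0)               # all-N window
  expect_equal(gc_content("ACGN"), 2 / 3)           # N excluded from counts
  expect_error(gc_content(""), "non-empty")

  expect_equal(obs_exp_cpg("CGCGCG"), 3 * 6 / (3 * 3))
  expect_equal(obs_exp_cpg("CCGG"), 1 * 4 / (2 * 2))
  expect_equal(obs_exp_cpg("AATT"), 0)              # no C or G
  expect_error(obs_exp_cpg(""), "non-empty")
})

test_that("island caller recovers an embedded CpG-rich block and applies the
           strict length threshold", {
  flank <- strrep("A", 1000)
  s300 <- paste0(flank, strrep("CG", 150), flank)
  isl <- call_cpg_islands(s300)
  expect_equal(nrow(isl), 1L)
  # the island covers the block, with at most window-size slack at the edges
  expect_lte(abs(isl$start - 1000), 200)
  expect_lte(abs(isl$end - 1300), 200)
  expect_true(isl$start <= 1000 && isl$end >= 1300 - 200)

  s150 <- paste0(flank, strrep("CG", 75), flank)
  expect_equal(nrow(call_cpg_islands(s150)), 0L)    # fails > 200 bp

  expect_equal(nrow(call_cpg_islands(strrep("A", 5000))), 0L)
  expect_equal(nrow(call_cpg_islands("ACGT")), 0L)  # shorter than window
})

test_that("composition thresholds are strict inequalities", {
  flank <- strrep("A", 1000)
  # GC exactly 50% (alternating CGAA), high obs/exp: not an island
  at_50 <- paste0(flank, strrep("CGAA", 100), flank)
  expect_equal(nrow(call_cpg_islands(at_50)), 0L)
  # obs/exp exactly 0.60 at GC 65%: not an island
  at_60 <- paste0(flank, make_cpg_region(300, 120, 75, 18, period = 100),
                  flank)
  expect_equal(obs_exp_cpg(make_cpg_region(300, 120, 75, 18, period = 100)),
               0.6)
  expect_equal(nrow(call_cpg_islands(at_60)), 0L)
  # nudging either criterion above its threshold yields an island
  above <- paste0(flank, make_cpg_region(300, 120, 75, 21, period = 100),
                  flank)
  expect_equal(nrow(call_cpg_islands(above)), 1L)
})

test_that("called islands are disjoint, definition-satisfying, and shrink
           monotonically with min_length", {
  set.seed(42)
  for (i in 1:10) {
    s <- random_mixed_gc_sequence(4000)
    isl <- call_cpg_islands(s)
    if (nrow(isl) > 1) {
      expect_true(all(isl$start[-1] >= isl$end[-nrow(isl)]))
    }
    for (j in seq_len(nrow(isl))) {
      sub <- substr(s, isl$start[j] + 1, isl$end[j])
      expect_gt(nchar(sub), 200)
      expect_gt(gc_content(sub), 0.5)
      expect_gt(obs_exp_cpg(sub), 0.6)
    }
    n_calls <- vapply(c(200L, 300L, 400L), function(ml) {
      nrow(call_cpg_islands(s, island_params(min_length = ml, window = 200L)))
    }, 0L)
    expect_true(all(diff(n_calls) <= 0))
  }
})

test_that("caller agrees with the exhaustive qualifying-substring oracle", {
  set.seed(7)
  agree <- vapply(1:15, function(i) {
    island_membership_agreement(random_mixed_gc_sequence(3000))
  }, c(agree = 0, n = 0))
  expect_gte(sum(agree["agree", ]) / sum(agree["n", ]), 0.99)
})

test_that("feature classes follow the island-distance rule with inclusive
           2 kb / 4 kb boundaries", {
  isl <- data.frame(start = 10000L, end = 10500L)
  # inside, then probes at exact boundary distances right of the island
  pos <- c(10250L, 10499L + c(1L, 2000L, 2001L, 4000L, 4001L))
  cls <- annotate_cpg_features(pos, isl)
  expect_equal(as.character(cls),
               c("ISLAND", "SHORE", "SHORE", "SHELF", "SHELF", "OPEN_SEA"))
  # and left of the island
  posL <- 10000L - c(1L, 2000L, 2001L, 4000L, 4001L)
  expect_equal(as.character(annotate_cpg_features(posL, isl)),
               c("SHORE", "SHORE", "SHELF", "SHELF", "OPEN_SEA"))
  # no islands: everything open sea
  none <- annotate_cpg_features(pos, islands = NULL)
  expect_true(all(none == "OPEN_SEA"))
  # classes partition sites: exactly one class each, no NA
  expect_false(anyNA(cls))
  expect_equal(levels(cls), c("ISLAND", "SHORE", "SHELF", "OPEN_SEA"))
})

test_that("sites between two islands take the nearest island's distance", {
  isl <- data.frame(start = c(0L, 10000L), end = c(500L, 10500L))
  # 3000 bp right of island 1, 7000 left of island 2 -> SHELF via island 1
  expect_equal(as.character(annotate_cpg_features(3499L, isl)), "SHELF")
  # midpoint-ish site nearer island 2
  expect_equal(as.character(annotate_cpg_features(9000L, isl)), "SHORE")
  expect_error(annotate_cpg_features(1L,
                                     data.frame(start = c(10L, 5L),
                                                end = c(20L, 8L))),
               "sorted")
})
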