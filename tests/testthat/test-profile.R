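# Composition and motif primitives against hand counts and the
# brute-force oracles.

test_that("composition percentages match hand tallies", {
  expect_equal(composition_profile("PAST")$pct_past, 100)
  expect_equal(composition_profile("PASTGG")$pct_past, 100 * 4 / 6)
  expect_equal(composition_profile("GGGG")$pct_past, 0)
  expect_equal(composition_profile("GGGG")$pct_pvkcyt, 0)
  # character tally of "PVKCYT": all six in PVKCYT, only P and T in PAST
  expect_equal(composition_profile("PVKCYT")$pct_pvkcyt, 100)
  expect_equal(composition_profile("PVKCYT")$pct_past, 100 * 2 / 6)
  expect_error(composition_profile(""), "non-empty")
})

test_that("X counts toward length but never a numerator", {
  p <- composition_profile("XPAST")
  expect_equal(p$length, 5L)
  expect_equal(p$pct_past, 80)
  expect_equal(sum(p$residue_fractions), 1, tolerance = 1e-9)
  expect_equal(count_ppvxkt("PPVXK"), 0L) # X cannot fill the wildcard
  expect_equal(yxy_count("YXY"), 0L)
})

test_that("composition is permutation-invariant and length-normalized", {
  withr::local_seed(11)
  for (i in 1:50) {
    s <- rand_seq(sample(5:80, 1L), hrgpscan::AA_ALPHABET_X)
    p <- composition_profile(s)
    expect_equal(sum(p$residue_fractions), 1, tolerance = 1e-9)
    shuffled <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    expect_equal(composition_profile(shuffled)$pct_past, p$pct_past)
    doubled <- composition_profile(strrep(s, 2L))
    expect_equal(doubled$pct_past, p$pct_past)
    expect_equal(doubled$pct_pvkcyt, p$pct_pvkcyt)
  }
})

test_that("S+P run tiers follow maximal-run semantics", {
  expect_equal(sp_run_tiers("SPPPP"), c(sp3 = 0L, sp4 = 1L, sp5 = 0L))
  expect_equal(sp_run_tiers("SPPPSPPPPP"), c(sp3 = 1L, sp4 = 0L, sp5 = 1L))
  expect_equal(sp_run_tiers("SSPP"), c(sp3 = 0L, sp4 = 0L, sp5 = 0L))
  # a 7-proline run collapses into the >=5 tier, counted once
  expect_equal(sp_run_tiers("SPPPPPPP"), c(sp3 = 0L, sp4 = 0L, sp5 = 1L))
})

test_that("tier totals equal the brute-force maximal-run count", {
  withr::local_seed(7)
  for (i in 1:300) {
    s <- rand_seq(sample(10:80, 1L), c("S", "P", "A", "G"))
    expect_identical(sp_run_tiers(s), oracle_sp_tiers(s), label = s)
  }
})

test_that("literal motif counting is non-overlapping left-to-right", {
  expect_equal(count_motif("SPPPSPPP", "SPPP"), 2L)
  expect_equal(count_motif("SPPPPPPP", "SPPPP"), 1L)
  expect_equal(count_motif("", "SPPP"), 0L)
  expect_error(count_motif("AAA", ""), "non-empty")
})

test_that("count_motif agrees with the naive scan oracle", {
  withr::local_seed(13)
  motifs <- c("SPPP", "SPPPP", "KKPCPP", "PPLP", "PELPK", "AP")
  for (i in 1:300) {
    s <- rand_seq(sample(5:60, 1L), c("S", "P", "K", "C", "L", "E", "A"))
    m <- sample(motifs, 1L)
    expect_identical(count_motif(s, m), oracle_count_motif(s, m),
                     label = paste(s, m))
  }
})

test_that("PPVX[KT] counting matches examples and oracle", {
  expect_equal(count_ppvxkt("PPVAK"), 1L)
  expect_equal(count_ppvxkt("PPVAKPPVGT"), 2L)
  expect_equal(count_ppvxkt("PPVAA"), 0L)
  withr::local_seed(17)
  for (i in 1:300) {
    s <- rand_seq(sample(5:60, 1L), c("P", "V", "K", "T", "A", "G"))
    expect_identical(count_ppvxkt(s), oracle_ppvxkt(s), label = s)
  }
})

test_that("fasciclin consensus matches class by class", {
  # M/T/V/F/C/P then G in the one-or-more class, D, S, final A
  expect_equal(fasciclin_scan("MTVFCPGDSA"),
               cbind(start = 0L, end = 10L))
  expect_equal(nrow(fasciclin_scan("AAAA")), 0L)
  # without the G, the one-or-more group consumes D and the final class
  # is left without a residue: no match
  expect_equal(nrow(fasciclin_scan("MTVFCPDSA")), 0L)
})

test_that("fasciclin scan agrees with an independent backtracking matcher", {
  withr::local_seed(19)
  n_hits <- 0L
  for (i in 1:400) {
    s <- rand_fasc_seq()
    got <- fasciclin_scan(s)
    want <- oracle_fasciclin(s)
    expect_equal(unname(got), unname(rbind(want)), label = s)
    n_hits <- n_hits + (nrow(got) > 0L)
  }
  expect_gt(n_hits, 10L) # the biased alphabet must actually exercise hits
})

test_that("dipeptide counts use a sliding window", {
  expect_equal(dipeptide_counts("APAP"),
               c(AP = 2L, PA = 1L, SP = 0L, TP = 0L, GP = 0L, VP = 0L))
  expect_equal(dipeptide_counts("TPVPGPSP"),
               c(AP = 0L, PA = 0L, SP = 1L, TP = 1L, GP = 1L, VP = 1L))
  expect_equal(sum(dipeptide_counts("AAAA")), 0L)
  withr::local_seed(23)
  for (i in 1:200) {
    s <- rand_seq(sample(4:50, 1L), c("A", "P", "S", "T", "G", "V"))
    got <- dipeptide_counts(s)
    for (d in names(got)) {
      expect_identical(got[[d]], oracle_dipeptide(s, d),
                       label = paste(s, d))
    }
  }
})

test_that("YXY motifs are counted position-wise with overlaps", {
  expect_equal(yxy_count("YVY"), 1L)
  expect_equal(yxy_count("YVYVY"), 2L)
  expect_equal(yxy_count("YY"), 0L)
  withr::local_seed(29)
  for (i in 1:200) {
    s <- rand_seq(sample(3:50, 1L), c("Y", "V", "A", "X"))
    expect_identical(yxy_count(s), oracle_yxy(s), label = s)
  }
})

test_that("C-terminal features respect the window", {
  expect_true(cterm_features("KKKSPPP", 10)[["cterm_sppp"]])
  expect_false(cterm_features("SPPPKKKKKKKKKKKK", 10)[["cterm_sppp"]])
  ct <- cterm_features("GSPPPPY", 10)
  expect_true(ct[["cterm_sp4or5_plus_y"]])
  # SPPPP in window but no Y at or after it
  expect_false(cterm_features("GGGSPPPP", 10)[["cterm_sp4or5_plus_y"]])
  expect_error(cterm_features("SPPP", 3), "window")
})

test_that("dispersion is the span fraction of the repeat set", {
  d <- repeat_dispersion(rbind(c(10, 14), c(85, 89)), 100)
  expect_equal(d$span_fraction, 0.79)
  expect_true(d$is_distributed)
  d1 <- repeat_dispersion(rbind(c(10, 14)), 100)
  expect_equal(d1$span_fraction, 0.04)
  expect_false(d1$is_distributed)
  expect_equal(repeat_dispersion(rbind(c(0, 70)), 70)$span_fraction, 1)
  expect_error(repeat_dispersion(matrix(integer(0), ncol = 2), 100),
               "undefined")
})

test_that("lysine-rich window detection", {
  expect_equal(lysine_rich_region(strrep("KA", 10)),
               c(start = 0L, end = 20L))
  expect_null(lysine_rich_region(strrep("A", 60)))
  # exactly 35%: 7 K in a 20-residue window
  s <- paste0(strrep("A", 10), strrep("K", 7), strrep("A", 23))
  expect_equal(unname(lysine_rich_region(s, 20, 35)[1L]), 0L)
  # window longer than the sequence: absent, not an error
  expect_null(lysine_rich_region("KKKKKK", 20))
})

test_that("annotate_motifs assembles consistent counts", {
  s <- "SPPPSPPPPAPAPYVYPPVAKKKPCPPSPPP"
  m <- annotate_motifs(s)
  expect_equal(m$sppp_count, m$sp3_count + m$sp4_count + m$sp5_count)
  expect_equal(m$spppp_count, m$sp4_count + m$sp5_count)
  expect_equal(m$dipeptide_total, sum(m$dipeptide_counts))
  expect_equal(m$kkpcpp_count, 1L)
  expect_equal(m$ppvxkt_count, 1L)
  expect_true(m$cterm_sppp)
  # all spans inside [0, length)
  for (sp in m$spans) {
    if (nrow(sp)) {
      expect_true(all(sp[, "start"] >= 0L & sp[, "end"] <= nchar(s)))
    }
  }
})
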