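# Screens and the family/subclass decision workflow.

th <- hrgp_thresholds()

test_that("screens fire independently on constructed cases", {
  # 60 aa, 40% PAST, no other signals: AG-peptide screen only
  s <- paste0(strrep("AAG", 12L), strrep("G", 24L))
  expect_equal(nchar(s), 60L)
  expect_equal(screen_protein(s, th), "PAST35_PEPTIDE")

  # fasciclin instance diluted to 4% PAST: consensus screen only
  s <- paste0("MTVFCPGDSA", strrep("G", 90L))
  expect_equal(screen_protein(s, th), "FASCICLIN")

  # nothing fires on a featureless protein
  expect_equal(screen_protein(strrep("G", 80L), th), character(0))

  # 55% PAST and 3 S+P runs: both screens fire
  s <- paste0(strrep("GSPPPG", 3L), strrep("A", 43L), strrep("G", 39L))
  expect_equal(nchar(s), 100L)
  p <- composition_profile(s)
  expect_gte(p$pct_past, 50)
  expect_lt(p$pct_pvkcyt, 45)
  expect_setequal(screen_protein(s, th), c("PAST50", "SPPP2"))
})

test_that("threshold comparisons are >= on unrounded values", {
  # exactly 50.000% PAST over 100 residues
  s50 <- paste0(strrep("A", 50L), strrep("G", 50L))
  expect_true("PAST50" %in% screen_protein(s50, th))
  s49 <- paste0(strrep("A", 49L), strrep("G", 51L))
  expect_false("PAST50" %in% screen_protein(s49, th))

  # exactly 35.000% PAST at 80 residues (inside the peptide window)
  s35 <- paste0(strrep("A", 28L), strrep("G", 52L))
  expect_true("PAST35_PEPTIDE" %in% screen_protein(s35, th))
  s34 <- paste0(strrep("A", 27L), strrep("G", 53L))
  expect_false("PAST35_PEPTIDE" %in% screen_protein(s34, th))

  # exactly 45.000% PVKCYT
  s45 <- paste0(strrep("K", 45L), strrep("G", 55L))
  expect_true("PVKCYT45" %in% screen_protein(s45, th))
  s44 <- paste0(strrep("K", 44L), strrep("G", 56L))
  expect_false("PVKCYT45" %in% screen_protein(s44, th))
})

test_that("decision workflow reproduces the canonical paths", {
  # AG peptide: 60 aa, 40% PAST, AP/PA repeats spread end to end
  s <- strrep("APATGGGGGG", 6L)
  cl <- classify_protein("agpep", s, th,
                         evidence(sp_flag = TRUE, sp_pos = 20L,
                                  sp_source = "mock"))
  expect_equal(cl$family, "AGP")
  expect_equal(cl$subclass, "AG peptide")
  expect_true(any(grepl("signal peptide", cl$evidence_notes$statement)))

  # short EXT: 150 aa, 4 distributed S+P runs
  s <- paste0(strrep(paste0(strrep("G", 30L), "SPPP"), 4L), strrep("G", 14L))
  expect_equal(nchar(s), 150L)
  cl <- classify_protein("sext", s, th)
  expect_equal(cl$family, "EXT")
  expect_equal(cl$subclass, "short EXT")

  # PERK: 700 aa, runs confined to the N-terminus, kinase domain, no SP
  s <- paste0(strrep("SPPPG", 5L), strrep("G", 675L))
  ev <- evidence(sp_flag = FALSE, sp_source = "mock",
                 domains = data.frame(name = "protein kinase",
                                      start = 100L, end = 650L,
                                      source = "mock"))
  cl <- classify_protein("perk", s, th, ev)
  expect_equal(cl$family, "EXT")
  expect_equal(cl$subclass, "PERK")
  expect_true("no signal peptide" %in% cl$flags)

  # PR peptide (PPLP): motif screen fires even though composition fails
  s <- paste0(strrep("PPLPGGGGGGGGGG", 4L), "PPVAKGGGGGGGGGGPPVGK",
              strrep("G", 44L))
  expect_equal(nchar(s), 120L)
  p <- composition_profile(s)
  expect_lt(p$pct_pvkcyt, 45)
  cl <- classify_protein("prpep", s, th)
  expect_true("PPVXKT2" %in% cl$criteria_fired)
  expect_equal(cl$family, "PRP")
  expect_equal(cl$subclass, "PR peptide (PPLP)")

  # featureless protein: NONE/none
  cl <- classify_protein("none", strrep("G", 100L), th)
  expect_equal(cl$family, "NONE")
  expect_equal(cl$subclass, "none")
})

test_that("fasciclin consensus wins regardless of composition", {
  # high-PAST protein that also carries the consensus: still FLA
  s <- paste0(strrep("APAPSATPAS", 10L), "MTVFCPGDSA",
              strrep("APAPSATPAS", 10L))
  cl <- classify_protein("fla", s, th)
  expect_equal(cl$subclass, "FLA")
})

test_that("long and domain-evidenced chimeric extensins resolve", {
  runs <- strrep("SPPPG", 4L)
  long <- paste0(runs, strrep("G", 2100L))
  expect_equal(classify_protein("l", long, th)$subclass,
               "long chimeric EXT")

  base <- paste0(runs, strrep("G", 480L))
  lrx <- evidence(domains = data.frame(name = "LRR_8", start = 100L,
                                       end = 400L, source = "mock"))
  expect_equal(classify_protein("x", base, th, lrx)$subclass, "LRX")
  fh <- evidence(domains = data.frame(name = "FH2", start = 100L,
                                      end = 400L, source = "mock"))
  expect_equal(classify_protein("x", base, th, fh)$subclass, "FH EXT")
  other <- evidence(domains = data.frame(name = "Glyco_hydro_28",
                                         start = 100L, end = 400L,
                                         source = "mock"))
  expect_equal(classify_protein("x", base, th, other)$subclass,
               "other chimeric EXT")
  # no domain adapter: degrade to unresolved-chimeric, flagged
  cl <- classify_protein("x", base, th)
  expect_equal(cl$subclass, "unresolved-chimeric")
  expect_true(any(grepl("without domain evidence", cl$flags)))
})

test_that("plastocyanin evidence yields PAG on the AGP path", {
  s <- strrep("APAPSATPAS", 20L)
  pag <- evidence(domains = data.frame(name = "plastocyanin-like",
                                       start = 10L, end = 120L,
                                       source = "mock"))
  expect_equal(classify_protein("pag", s, th, pag)$subclass, "PAG")
  expect_equal(classify_protein("pag", s, th)$subclass, "classical AGP")
})

test_that("AGP/PRP double fires follow the density tie-break", {
  # dipeptide-dense, no PRP motifs: AGP
  s <- strrep("APAPSATPAS", 15L) # PVKCYT 40%, below threshold
  cl <- classify_protein("agp", s, th)
  expect_equal(cl$family, "AGP")

  # both motif systems dense: flagged ambiguous, larger count wins
  s <- paste0(strrep("APAP", 10L), "PPVAKPPVAK",
              strrep("APAP", 10L))
  cl <- classify_protein("amb", s, th)
  expect_true("ambiguous AGP/PRP" %in% cl$flags)
  expect_equal(cl$family, "AGP") # ~39 dipeptides vs 2 PRP repeats

  # PRP-motif-dense without the AGP dipeptides: PRP
  s <- paste0(strrep("PPVEKKVE", 30L)) # 240 aa, distributed repeats
  cl <- classify_protein("prp", s, th)
  expect_equal(cl$family, "PRP")
  expect_equal(cl$subclass, "PRP")
})

test_that("results are structurally consistent and deterministic", {
  ps <- synth_proteome(synth_spec(seed = 3L, decoy = 40L))
  ev <- synth_mock_evidence(ps)
  res1 <- classify_proteome(ps$records, th, ev)
  res2 <- classify_proteome(ps$records, th, ev)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), nrow(ps$records))
  # family NONE if and only if subclass none
  expect_identical(res1$family == "NONE", res1$subclass == "none")
  # criteria fired whenever a family was assigned
  assigned <- res1$family != "NONE"
  expect_true(all(lengths(res1$criteria_fired[assigned]) > 0L))
})

test_that("raising the classical-AGP threshold can only shrink the set", {
  ps <- synth_proteome(synth_spec(seed = 5L, decoy = 30L))
  sets50 <- screen_proteome(ps$records, th)$sets$PAST50
  sets60 <- screen_proteome(ps$records,
                            hrgp_thresholds(past_classical_pct = 60))$
    sets$PAST50
  expect_true(all(sets60 %in% sets50))
  sets100 <- screen_proteome(ps$records,
                             hrgp_thresholds(past_classical_pct = 100))$
    sets$PAST50
  expect_true(all(sets100 %in% sets60))
})

test_that("screen_proteome returns exact id sets", {
  ps <- synth_proteome(synth_spec(
    classical_agp = 4L, lysine_rich_agp = 0L, ag_peptide = 3L, fla = 2L,
    classical_ext = 2L, short_ext = 0L, chimeric_ext = 0L, prp = 0L,
    pr_peptide_pplp = 0L, pr_peptide_pelpk = 0L, hybrid = 0L,
    decoy = 10L, seed = 9L))
  sc <- screen_proteome(ps$records, th)
  planted <- split(ps$truth$id, ps$truth$class)
  expect_true(all(planted$classical_agp %in% sc$sets$PAST50))
  expect_true(all(planted$ag_peptide %in% sc$sets$PAST35_PEPTIDE))
  expect_equal(sort(sc$sets$FASCICLIN), sort(planted$fla))
  expect_equal(sort(sc$sets$SPPP2), sort(planted$classical_ext))
  expect_false(any(planted$decoy %in% unlist(sc$sets)))
  expect_equal(unname(sc$counts), unname(lengths(sc$sets)))

  empty <- tibble::tibble(id = character(0), description = character(0),
                          sequence = character(0))
  expect_true(all(screen_proteome(empty, th)$counts == 0L))
})
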