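test_that("cleavage removes tracts and G donors and sets the amide state", {
  # hand trace of a G-donated dibasic site
  p <- "EDAQWLRFAAGKRSSS"
  seg <- cleave(p, find_processing_sites(p))
  expect_equal(seg$seq, "EDAQWLRFAA")
  expect_equal(seg$c_state, "amide")

  # plain dibasic site: no donor, free acid, K retained on the segment
  p2 <- "KQPPGVWRRAAA"
  seg2 <- cleave(p2, find_processing_sites(p2))
  expect_equal(seg2$seq, "KQPPGVW")
  expect_equal(seg2$c_state, "free_acid")

  expect_equal(nrow(cleave("AAAAAA", find_processing_sites("AAAAAA"))), 0L)
})

test_that("N-terminal trimming follows the Q / P / X-P / preferred-residue rules", {
  expect_equal(trim_n_terminus("EDAQWLRGRF")$display, "pQWLRGRFamide")
  expect_equal(trim_n_terminus("EDAQWLRGRF")$n_state, "pyroglutamate")
  # S trimmed, then L retained because the second residue is P
  t2 <- trim_n_terminus("SLPRS")
  expect_equal(t2$display, "LPRSamide")
  expect_equal(t2$n_state, "proline_protected")
  # R is not trimmable
  expect_equal(trim_n_terminus("RPRS")$display, "RPRSamide")
  # free-acid carry-through (K is not trimmable, so it survives)
  expect_equal(trim_n_terminus("KQPPGVW", c_state = "free_acid")$display,
               "KQPPGVW")
  # blocked trimming is flagged
  expect_true(trim_n_terminus("WAAA")$trim_blocked)
  # products below min_len are rejected
  expect_null(trim_n_terminus("EDAQ"))
})

test_that("trimming is idempotent and display strings round-trip", {
  set.seed(9)
  pool <- c(cnidopep:::TRIMMABLE_DEFAULT, "Q", "P", "K", "R", "W", "H")
  for (i in 1:50) {
    seg <- paste(sample(pool, sample(3:12, 1), replace = TRUE),
                 collapse = "")
    mp <- trim_n_terminus(seg)
    if (is.null(mp)) next
    again <- trim_n_terminus(mp$core)
    expect_equal(again$core, mp$core)
    expect_equal(again$n_state, mp$n_state)
    parsed <- parse_display(mp$display)
    expect_equal(parsed$core, mp$core)
    expect_equal(parsed$c_state, mp$c_state)
  }
})

test_that("published peptides are fixed points of the trimming rules", {
  for (d in published_peptides) {
    parsed <- parse_display(d)
    mp <- trim_n_terminus(parsed$core, c_state = parsed$c_state)
    expect_false(is.null(mp), label = d)
    expect_equal(mp$display, d)
    expect_equal(mp$n_state, parsed$n_state, label = d)
  }
})

test_that("mature_all reproduces generator copy counts and site variants", {
  # an 11-copy RPRSamide precursor, spacers restricted to fully trimmable
  # flanking residues as reported for the staurozoan gene
  spec <- precursor_spec("calva_like", "RPRS", 11, "Staurozoa",
                         spacer_pool = c("D", "V", "F", "A"))
  g <- generate_precursor(spec, seed = 42)
  ann <- mature_all(classify(screen_protein(g$record),
                             predict_signal_peptide(g$record)))
  expect_equal(ann$copy_counts, c(RPRSamide = 11L))

  # mixed amidating / plain sites on identical cores report both variants
  spec2 <- precursor_spec("mix", "QPPGVW", 12, "Scyphozoa",
                          site_weights = c(GKR = 1, RR = 1),
                          spacer_pool = c("S", "N", "E", "D", "T"))
  g2 <- generate_precursor(spec2, seed = 8)
  ann2 <- mature_all(classify(screen_protein(g2$record),
                              predict_signal_peptide(g2$record)))
  expect_setequal(names(ann2$copy_counts), c("pQPPGVWamide", "pQPPGVW"))
  expect_equal(sum(ann2$copy_counts), 12L)

  # no hit clusters -> empty counts
  miss <- classify(screen_protein("MKTAAAAQQQWWWNNNAAA"),
                   predict_signal_peptide(
                     paste0("MKTLVLLALLAVALA", strrep("A", 20))))
  expect_length(mature_all(miss)$copy_counts, 0L)
})

test_that("the amide flag tracks the G donor exactly over simulated precursors", {
  for (sd in 1:5) {
    spec <- precursor_spec(paste0("p", sd), "QPPGVW", 8,
                           site_weights = c(GKR = 1, RR = 1, GR = 1,
                                            RKK = 1))
    g <- generate_precursor(spec, seed = sd)
    truth <- g$truth
    amide_truth <- truth$c_state == "amide"
    amide_display <- grepl("amide$", truth$display)
    expect_equal(amide_display, amide_truth)
    # and the pipeline agrees with the truth displays
    ann <- mature_all(classify(screen_protein(g$record),
                               predict_signal_peptide(g$record)))
    expect_equal(sort(ann$mature_peptides$display), sort(truth$display))
  }
})
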