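ev_row <- function(model = "m1", source = "dfam", acc = "A1",
                   desc = "Gypsy LTR retrotransposon", label = "Gypsy",
                   a = 0L, b = 200L, evalue = 1e-30, pseudo = NA) {
  tag_te_relatedness(data.frame(
    model_id = model, source = source, accession = acc, description = desc,
    family_label = label, m_start = a, m_end = b, frame = 1L,
    evalue = evalue, pseudo = pseudo, stringsAsFactors = FALSE))
}

accepted_model <- function(seq = NULL) {
  set.seed(606)
  m <- consensus_models("m1", seq %||% random_dna(1200))
  m$status <- "accepted"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TE-relatedness tagging follows the keyword vocabulary", {
  expect_true(ev_row(desc = "reverse transcriptase (RNA-dependent DNA polymerase)",
                     label = NA)$te_related)
  expect_true(ev_row(desc = "apurinic endonuclease", label = NA)$te_related)
  expect_true(ev_row(desc = "gag-pol polyprotein", label = NA)$te_related)
  expect_false(ev_row(desc = "serine/threonine protein kinase",
                      label = NA)$te_related)
  # word boundaries: "polymerase" must not fire the "pol" keyword
  expect_false(ev_row(desc = "DNA-directed RNA polymerase II",
                      label = NA)$te_related)
  # vocabulary is a data file, re-loadable from a custom path
  f <- withr::local_tempfile()
  writeLines(c("# custom", "kinase"), f)
  ev <- tag_te_relatedness(ev_row(desc = "protein kinase", label = NA),
                           keywords = te_keywords(f))
  expect_true(ev$te_related)
})

test_that("evidence vetting drops masked-region and too-short rows", {
  cfg <- pipeline_config()
  m <- accepted_model()
  mask <- structure(list(seq_len = 1200L,
                         intervals = data.frame(start = 50L, end = 400L)),
                    class = "mask_track")
  # fully inside the mask -> dropped
  expect_equal(nrow(screen_evidence(m, ev_row(a = 100L, b = 200L), mask,
                                    cfg)), 0L)
  # disjoint from the mask -> kept
  expect_equal(nrow(screen_evidence(m, ev_row(a = 500L, b = 700L), mask,
                                    cfg)), 1L)
  # overlap exactly 0.5 is not strictly greater -> kept
  mask2 <- structure(list(seq_len = 1200L,
                          intervals = data.frame(start = 0L, end = 50L)),
                     class = "mask_track")
  expect_equal(nrow(screen_evidence(m, ev_row(a = 0L, b = 100L), mask2,
                                    cfg)), 1L)
  # shorter than 30 nt -> dropped regardless of the mask
  expect_equal(nrow(screen_evidence(m, ev_row(a = 500L, b = 520L), mask,
                                    cfg)), 0L)
})

test_that("curation accepts on TE evidence unless Dfam/InterPro conflict", {
  m <- accepted_model()
  # dfam Gypsy + interpro RT -> accepted
  ev <- rbind(ev_row(),
              ev_row(source = "interpro", acc = "I1",
                     desc = "reverse transcriptase", label = NA))
  d <- curate_model(m, ev)
  expect_equal(d$verdict, "accepted")
  expect_true(nzchar(d$supporting_evidence))
  # dfam Gypsy + only a kinase interpro row -> conflict
  ev <- rbind(ev_row(),
              ev_row(source = "interpro", acc = "I2",
                     desc = "serine/threonine kinase", label = NA))
  d <- curate_model(m, ev)
  expect_equal(d$verdict, "discarded")
  expect_equal(d$reason, "dfam_interpro_conflict")
  # dfam alone (no interpro rows) -> accepted, absence is not a conflict
  expect_equal(curate_model(m, ev_row())$verdict, "accepted")
  # zero evidence -> no_te_evidence
  d <- curate_model(m, ev_row()[0, ])
  expect_equal(d$verdict, "discarded")
  expect_equal(d$reason, "no_te_evidence")
})

test_that("the conflict rule is order-independent (shuffle property)", {
  m <- accepted_model()
  ev <- rbind(ev_row(),
              ev_row(source = "interpro", acc = "I1", desc = "kinase",
                     label = NA),
              ev_row(source = "sprot", acc = "S1", desc = "integrase",
                     label = NA),
              ev_row(source = "interpro", acc = "I2",
                     desc = "ribonuclease H", label = NA))
  base <- curate_model(m, ev)$verdict
  set.seed(88)
  for (k in 1:20) {
    expect_equal(curate_model(m, ev[sample(nrow(ev)), ])$verdict, base)
  }
})

test_that("classification follows the family-label majority and flags", {
  m <- accepted_model()
  # 3 Gypsy rows + 1 unlabeled RT row -> LTR Gypsy-like
  ev <- rbind(ev_row(acc = "A1"), ev_row(acc = "A2", source = "sprot"),
              ev_row(acc = "A3", source = "known_te"),
              ev_row(source = "interpro", acc = "I1",
                     desc = "reverse transcriptase", label = NA))
  expect_equal(classify_model(m, ev)$family, "LTR_Gypsy_like")
  # R2 + RT/endonuclease domains -> LINE-like
  ev <- rbind(ev_row(acc = "B1", desc = "R2 retrotransposon", label = "R2"),
              ev_row(source = "interpro", acc = "B2",
                     desc = "apurinic endonuclease", label = "LINE"))
  expect_equal(classify_model(m, ev)$family, "LINE_like")
  # unlabeled RT row only: structural flag decides
  ev <- ev_row(source = "interpro", acc = "C1",
               desc = "reverse transcriptase", label = NA)
  expect_equal(classify_model(m, ev, ltr_structure_flag = TRUE)$family,
               "LTR_unclassified")
  expect_equal(classify_model(m, ev, ltr_structure_flag = FALSE)$family,
               "nonLTR_unclassified")
  # tie broken by lowest e-value; SINE flag overrides
  ev <- rbind(ev_row(acc = "G1", evalue = 1e-40),
              ev_row(acc = "L1", desc = "LINE retrotransposon",
                     label = "LINE", evalue = 1e-10))
  expect_equal(classify_model(m, ev)$family, "LTR_Gypsy_like")
  expect_equal(classify_model(m, ev, sine_flag = TRUE)$family,
               "SINE_candidate")
  # classifying a non-accepted model is a contract violation
  m2 <- accepted_model()
  m2$status <- "candidate"
  expect_error(classify_model(m2, ev), "not accepted")
})

test_that("curation never accepts without surviving TE evidence (fuzz)", {
  cfg <- pipeline_config()
  set.seed(99)
  sources <- c("dfam", "interpro", "sprot", "known_te")
  descs <- c("reverse transcriptase", "integrase", "protein kinase",
             "ribosomal protein", "Gypsy retrotransposon", "cytochrome c")
  for (k in 1:40) {
    m <- accepted_model()
    n <- sample(0:6, 1)
    ev <- if (n == 0) ev_row()[0, ] else do.call(rbind, lapply(seq_len(n),
      function(i) ev_row(source = sample(sources, 1), acc = paste0("X", i),
                         desc = sample(descs, 1), label = NA,
                         a = sample(0:900, 1) * 1L,
                         b = 1000L + sample(0:200, 1))))
    mask <- model_mask(m, cfg)
    vetted <- screen_evidence(m, ev, mask, cfg)
    d <- curate_model(m, vetted)
    if (d$verdict == "accepted") {
      expect_gt(sum(vetted$te_related), 0)
      expect_true(nzchar(d$supporting_evidence))
    }
  }
})
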