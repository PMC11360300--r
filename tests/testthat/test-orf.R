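test_that("the in-frame ATG scanner respects the canonical frame", {
  f <- fx()
  for (nm in c("VII-ab3", "VII-Pb3", "VII-a2a")) {
    t <- f$iso[[nm]]
    mrna <- spliceTranscript(f$locus, t)
    anchor <- transcriptFrameAnchor(f$locus, t)
    expect_identical(findInitiatingAtg(mrna, anchor), 115L)
  }
  expect_true(is.na(findInitiatingAtg("CCCCCCGGGTTT", 1)))
  ## an out-of-frame ATG upstream of the in-frame one is skipped
  s <- paste0(strrep("C", 49), "ATG", strrep("C", 62), "ATGGGG")
  expect_identical(substr(s, 50, 52), "ATG")
  expect_identical(substr(s, 115, 117), "ATG")
  expect_identical(findInitiatingAtg(s, 142), 115L)
  expect_identical(findInitiatingAtg(s, 143), 50L)
})

test_that("translation equals an independent codon-table oracle", {
  f <- fx()
  for (t in f$iso) {
    if (t@tag == "decoy") next
    mrna <- as.character(spliceTranscript(f$locus, t))
    ann <- translateChain(f$locus, t)
    oracle <- naiveTranslate(mrna, ann@atgPosition)
    expect_identical(ann@peptide, oracle)
    expect_identical(substr(ann@peptide, 1, 1), "M")
  }
})

test_that("the poison transcript reproduces the printed 67-residue ORF", {
  f <- fx()
  for (nm in c("VII-Pb3", "VII-Paca")) {
    t <- f$iso[[nm]]
    ann <- translateChain(f$locus, t)
    expect_identical(ann@peptide, PRINTED_POISON_PEPTIDE)
    expect_identical(nchar(ann@peptide), 67L)
    mrna <- spliceTranscript(f$locus, t)
    expect_identical(as.character(Biostrings::subseq(
      mrna, ann@stopPosition, ann@stopPosition + 2L)), "TAG")
  }
})

test_that("frame bookkeeping closes: ORF length is a codon multiple", {
  f <- fx()
  for (nm in PLANTED_NAMES) {
    ann <- translateChain(f$locus, f$iso[[nm]])
    expect_identical((ann@stopPosition + 2L - ann@atgPosition + 1L) %% 3L,
                     0L)
    expect_identical(nchar(ann@peptide) * 3L,
                     ann@stopPosition - ann@atgPosition)
  }
})

test_that("NMD classification partitions the eight isoforms as 5 + 3", {
  f <- fx()
  anns <- lapply(PLANTED_NAMES, function(nm) {
    t <- f$iso[[nm]]
    classifyNmd(f$locus, t, translateChain(f$locus, t))
  })
  names(anns) <- PLANTED_NAMES
  cls <- vapply(anns, function(a) a@codingClass, character(1))
  expect_true(all(cls %in% c("coding", "NMD_candidate")))
  expect_setequal(names(cls)[cls == "coding"],
                  c("VII-ab3", "VII-b3", "VII-a2a", "VII-a2b", "VII-b2a"))
  expect_setequal(names(cls)[cls == "NMD_candidate"],
                  c("VII-Pb3", "VII-Paca", "VII-ab2a"))
  for (a in anns) expect_identical(a@nmdCandidate, a@ptc)
})

test_that("the alpha+beta combination shifts the frame inside beta", {
  f <- fx()
  annAB <- translateChain(f$locus, f$iso[["VII-ab3"]])
  expect_true("E_beta" %in% annAB@frameShiftExons)
  annB <- translateChain(f$locus, f$iso[["VII-b3"]])
  expect_length(annB@frameShiftExons, 0L)
  ## unique C-terminus relative to the beta-only short isoform
  tailAB <- substr(annAB@peptide, nchar(annAB@peptide) - 9,
                   nchar(annAB@peptide))
  tailB <- substr(annB@peptide, nchar(annB@peptide) - 9,
                  nchar(annB@peptide))
  expect_false(identical(tailAB, tailB))
  ## and the frameshifted 2a chain terminates upstream of the tail exon
  annAB2a <- classifyNmd(f$locus, f$iso[["VII-ab2a"]],
                         translateChain(f$locus, f$iso[["VII-ab2a"]]))
  expect_identical(annAB2a@codingClass, "NMD_candidate")
  expect_true("E_TM2" %in% annAB2a@frameShiftExons)
})

test_that("domain annotation maps residues to the modular architecture", {
  f <- fx()
  for (nm in c("VII-ab3", "VII-b3", "VII-a2a", "VII-a2b", "VII-b2a")) {
    t <- f$iso[[nm]]
    ann <- classifyNmd(f$locus, t, translateChain(f$locus, t))
    dom <- annotateDomains(f$locus, t, ann)
    ## class-specific N-terminal is always residues 1-8, then 17 shared
    expect_identical(dom$aa_start[dom$role == "NTERM_CLASS_VII"], 1L)
    expect_identical(dom$aa_end[dom$role == "NTERM_CLASS_VII"], 8L)
    expect_identical(dom$aa_end[dom$role == "SHARED_FIRSTEXON"] -
                       dom$aa_start[dom$role == "SHARED_FIRSTEXON"] + 1L,
                     17L)
    ## spans are ordered and non-overlapping
    expect_true(all(diff(dom$aa_start) > 0))
    expect_true(all(dom$aa_start[-1] > dom$aa_end[-nrow(dom)]))
  }
  tm <- vapply(c("VII-a2a", "VII-a2b", "VII-b2a", "VII-ab3", "VII-b3"),
               function(nm) {
    t <- f$iso[[nm]]
    ann <- classifyNmd(f$locus, t, translateChain(f$locus, t))
    attr(annotateDomains(f$locus, t, ann), "tm_present")
  }, logical(1))
  expect_identical(unname(tm), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  secreted <- vapply(c("VII-ab3", "VII-b3"), function(nm) {
    t <- f$iso[[nm]]
    ann <- classifyNmd(f$locus, t, translateChain(f$locus, t))
    attr(annotateDomains(f$locus, t, ann), "secreted")
  }, logical(1))
  expect_true(all(secreted))
})

test_that("the catalogue arithmetic extends the 28 reference isoforms", {
  cat0 <- isoformCatalogue(28)
  expect_identical(catalogueTotal(cat0), 28L)
  cat2 <- updateCatalogue(cat0, c(a = "coding", b = "coding"))
  expect_identical(catalogueTotal(cat2), 30L)
  f <- fx()
  cls <- vapply(PLANTED_NAMES, function(nm) {
    t <- f$iso[[nm]]
    classifyNmd(f$locus, t, translateChain(f$locus, t))@codingClass
  }, character(1))
  cat5 <- updateCatalogue(cat0, cls)
  expect_identical(catalogueTotal(cat5), 33L)
  expect_error(updateCatalogue(cat5, cls), "duplication")
  expect_error(updateCatalogue(cat0, c(a = "coding", a = "coding")),
               "duplication")
})
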