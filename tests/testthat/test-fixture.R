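test_that("fixture geometry is reproduced and independently scannable", {
  locus <- fx()$locus
  fe <- getExon(locus, "E_VII")
  expect_identical(intervalLength(fe@interval), 190L)
  expect_identical(fe@meta$shared_offset, 139L)
  expect_identical(139L + 51L, 190L)
  ## independent scan: the first ATG in the first exon sits at 115-117
  expect_identical(as.integer(
    gregexpr("ATG", fe@sequence, fixed = TRUE)[[1]][1]), 115L)
  ## no ATG in any frame upstream of the initiating codon
  expect_false(grepl("ATG", substr(fe@sequence, 1, 114), fixed = TRUE))
  pe <- getExon(locus, "E_P")
  expect_identical(intervalLength(pe@interval), 111L)
  expect_identical(substr(pe@sequence, 67, 69), "TAG")
  ## forward primer is embedded in the unique 5' region
  expect_true(grepl(locus@meta$primers$forward,
                    substr(fe@sequence, 1, 139), fixed = TRUE))
})

test_that("infeasible configurations raise construction errors", {
  expect_error(fixtureConfig(egfAlphaLen = 75), "congruence")
  expect_error(fixtureConfig(egfAlphaLen = 76, egfBetaLen = 63),
               "congruence")
  expect_error(fixtureConfig(egfCommonLen = 65), "congruence")
  expect_error(fixtureConfig(atgPosition = 100), "fixture-construction")
  expect_error(fixtureConfig(poisonExonLen = 110), "fixture-construction")
  expect_error(fixtureConfig(tm2Len = 60), "fixture-construction")
})

test_that("the locus build is deterministic per seed", {
  l1 <- buildFixtureLocus(fixtureConfig(seed = 42))
  l2 <- buildFixtureLocus(fixtureConfig(seed = 42))
  for (id in names(l1@exons))
    expect_identical(l1@exons[[id]]@sequence, l2@exons[[id]]@sequence)
  l3 <- buildFixtureLocus(fixtureConfig(seed = 43))
  expect_false(identical(getExon(l1, "E_L3")@sequence,
                         getExon(l3, "E_L3")@sequence))
})

test_that("the isoform set matches the study catalogue", {
  iso <- fx()$iso
  expect_true("VII-a2a" %in% names(iso))
  expect_identical(iso[["VII-b2b"]]@tag, "low_abundance")
  expect_identical(iso[["VII-Pa2a"]]@tag, "low_abundance")
  tags <- vapply(iso, function(t) t@tag, character(1))
  expect_identical(sum(tags == "decoy"), 2L)
  expect_setequal(names(iso)[tags == "planted"], PLANTED_NAMES)
})

test_that("alternative congruent exon lengths preserve the classification", {
  locus <- buildFixtureLocus(fixtureConfig(seed = 7, egfAlphaLen = 82,
                                           egfBetaLen = 67, tm2Len = 105,
                                           tailALen = 126, tailBLen = 60,
                                           linker3Len = 150))
  iso <- buildFixtureIsoforms(locus)
  cls <- vapply(PLANTED_NAMES, function(nm) {
    t <- iso[[nm]]
    classifyNmd(locus, t, translateChain(locus, t))@codingClass
  }, character(1))
  expect_identical(sum(cls == "coding"), 5L)
  expect_identical(sum(cls == "NMD_candidate"), 3L)
  expect_setequal(names(cls)[cls == "NMD_candidate"],
                  c("VII-Pb3", "VII-Paca", "VII-ab2a"))
})
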