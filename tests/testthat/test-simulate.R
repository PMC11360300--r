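test_that("a degenerate error model yields exact amplicon copies", {
  f <- fx()
  err0 <- errorModel(substitution = 0, insertion = 0, deletion = 0,
                     junctionWobbleProb = 0, truncationProb = 0)
  lib <- librarySpec("mono", 60, list(
    short = c("VII-ab3" = 0.5, "VII-b3" = 0.5)))
  reads <- simulateReads(f$locus, f$iso, lib, f$amps, err0, seed = 9)
  truthAmp <- lapply(c("VII-ab3", "VII-b3"), function(nm)
    ampliconSequence(f$locus, f$iso[[nm]], f$amps$short)$sequence)
  names(truthAmp) <- c("VII-ab3", "VII-b3")
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    expected <- truthAmp[[reads$isoform_truth[i]]]
    expect_true(s == expected ||
                  s == ampliso:::revCompChar(expected))
    expect_identical(nchar(reads$quality[i]), nchar(s))
  }
})

test_that("simulation is byte-identical for a fixed seed", {
  f <- fx()
  lib <- defaultLibrarySpecs(depth = 40)$monocyte
  r1 <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(), seed = 3)
  r2 <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(), seed = 3)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeReadsFastq(r1, f1); writeReadsFastq(r2, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  r3 <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(), seed = 4)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("truth-label counts follow the planted binomial fractions", {
  f <- fx()
  lib <- librarySpec("mono", 2000, list(
    short = c("VII-ab3" = 0.10, "VII-b3" = 0.90)))
  reads <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(),
                         seed = 11)
  n <- sum(reads$isoform_truth == "VII-ab3")
  sd3 <- 3 * sqrt(2000 * 0.10 * 0.90)
  expect_gt(n, 200 - sd3)
  expect_lt(n, 200 + sd3)
})

test_that("FASTQ round trip preserves reads and truth labels", {
  f <- fx()
  lib <- defaultLibrarySpecs(depth = 25)$imac
  reads <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(),
                         seed = 5)
  path <- tempfile(fileext = ".fastq")
  writeReadsFastq(reads, path)
  back <- readReadsFastq(path)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$quality, reads$quality)
  expect_identical(back$isoform_truth, reads$isoform_truth)
  expect_identical(back$library, reads$library)
})

test_that("invalid library specs and missing primer sites are rejected", {
  f <- fx()
  expect_error(librarySpec("x", 10, list(short = c("VII-b3" = 0.5))),
               "sum to 1")
  expect_error(librarySpec("x", -1, list()), "depth")
  ## a2a has no linker-3 exon, so it carries no short-amplicon site
  lib <- librarySpec("x", 10, list(short = c("VII-a2a" = 1)))
  expect_error(simulateReads(f$locus, f$iso, lib, f$amps, errorModel(),
                             seed = 1),
               "amplicon-mismatch")
})

test_that("dilution series follow the efficiency slope law", {
  s <- simulateDilutionSeries(qpcrSimConfig(efficiency = 2, ctNoiseSd = 0))
  slopes <- diff(s$ct) / diff(s$log10_concentration)
  expect_equal(unique(round(slopes, 4)), round(-1 / log10(2), 4))
  expect_equal(abs(slopes[1]), 3.3219, tolerance = 1e-4)
  expect_error(qpcrSimConfig(efficiency = 1), "invalid-efficiency")
  expect_error(qpcrSimConfig(efficiency = 0.9), "invalid-efficiency")
  expect_error(qpcrSimConfig(dilutionLog10 = c(0, -1)), "3 points")
  s1 <- simulateDilutionSeries(qpcrSimConfig(ctNoiseSd = 0.2, seed = 8))
  s2 <- simulateDilutionSeries(qpcrSimConfig(ctNoiseSd = 0.2, seed = 8))
  expect_identical(s1$ct, s2$ct)
})
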