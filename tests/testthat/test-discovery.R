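test_that("amplicon assignment orients reads and detects primer decay", {
  f <- fx()
  amp <- ampliconSequence(f$locus, f$iso[["VII-a2a"]], f$amps$long)
  r <- data.frame(read_id = c("fwd", "rc"),
                  sequence = c(amp$sequence,
                               ampliso:::revCompChar(amp$sequence)),
                  stringsAsFactors = FALSE)
  out <- assignAmplicons(r, f$amps)
  expect_identical(out$amplicon, c("long", "long"))
  expect_identical(out$orientation, c("+", "-"))
  expect_identical(out$sequence[2], amp$sequence)  # reoriented
  expect_true(startsWith(out$sequence[1], "TTAGTTCCAAGGCAGGCTGT"))
  ## three substitutions in the forward primer exceed the mismatch budget
  bad <- amp$sequence
  substr(bad, 2, 2) <- "C"; substr(bad, 5, 5) <- "C"
  substr(bad, 8, 8) <- "G"
  out <- assignAmplicons(data.frame(read_id = "bad", sequence = bad,
                                    stringsAsFactors = FALSE), f$amps)
  expect_identical(out$assign_reason, "no_forward_primer")
  ## a read without any reverse-primer site is rejected with a reason
  trunc <- substr(amp$sequence, 1, nchar(amp$sequence) - 60)
  out <- assignAmplicons(data.frame(read_id = "t", sequence = trunc,
                                    stringsAsFactors = FALSE), f$amps)
  expect_identical(out$assign_reason, "no_reverse_primer")
})

test_that("zero-error reads call their true chain with exact junctions", {
  f <- fx()
  err0 <- errorModel(substitution = 0, insertion = 0, deletion = 0,
                     junctionWobbleProb = 0, truncationProb = 0)
  lib <- librarySpec("mono", 40, list(
    short = c("VII-Pb3" = 0.5, "VII-b3" = 0.5),
    long = c("VII-b2a" = 1)))
  reads <- simulateReads(f$locus, f$iso, lib, f$amps, err0, seed = 21)
  asg <- assignAmplicons(reads, f$amps)
  ok <- asg[asg$assign_reason == "pass", ]
  expect_identical(nrow(ok), nrow(reads))
  calls <- callExonChains(ok, f$locus, f$amps)
  truth <- vapply(ok$isoform_truth, function(nm)
    paste(f$iso[[nm]]@chain, collapse = "+"), character(1))
  expect_identical(unname(calls$chain), unname(truth))
  for (o in ampliso:::parseOffsets(calls$offsets))
    expect_true(all(o == 0L))
  expect_true(all(calls$identity == 1))
  expect_true(all(calls$full_length))
})

test_that("a junction-wobbled read keeps its exon list with one offset", {
  f <- fx()
  amp <- ampliconSequence(f$locus, f$iso[["VII-b3"]], f$amps$short)
  j <- amp$junctions[2]
  wob <- paste0(substr(amp$sequence, 1, j), "GCA",
                substr(amp$sequence, j + 1, nchar(amp$sequence)))
  call <- callExonChains(data.frame(read_id = "w", sequence = wob,
                                    amplicon = "short",
                                    stringsAsFactors = FALSE),
                         f$locus, f$amps)
  expect_identical(call$chain,
                   paste(f$iso[["VII-b3"]]@chain, collapse = "+"))
  offs <- ampliso:::parseOffsets(call$offsets)[[1]]
  expect_identical(sum(offs != 0L), 1L)
  expect_identical(offs[2], 3L)
  ## truncation ahead of the reverse primer clears the full-length flag
  trunc <- substr(amp$sequence, 1, nchar(amp$sequence) - 40)
  call <- callExonChains(data.frame(read_id = "t", sequence = trunc,
                                    amplicon = "short",
                                    stringsAsFactors = FALSE),
                         f$locus, f$amps)
  expect_false(call$full_length)
})

test_that("QC gates fire at their documented thresholds", {
  thr <- qcThresholds()
  calls <- rbind(
    makeCall("ok", identity = 0.99, offsets = "0,0,0"),
    makeCall("id94", identity = 0.94),
    makeCall("id95", identity = 0.95),          # strict: > 0.95 required
    makeCall("trunc", full_length = FALSE),
    makeCall("lowq", mean_quality = 8),
    makeCall("jbad", chain = paste(rep("E", 11), collapse = "+"),
             offsets = paste(c(rep(0, 8), 9, 9), collapse = ",")),
    makeCall("jok", chain = paste(rep("E", 21), collapse = "+"),
             offsets = paste(c(rep(0, 19), 9), collapse = ",")))
  out <- qcFilter(calls, thr)
  expect_identical(out$qc_reason,
                   c("pass", "identity", "identity", "full_length",
                     "quality", "junctions", "pass"))   # 19/20 > 0.90
  ## junction accuracy of exactly 0.90 fails the strict gate
  tenj <- makeCall("j9", chain = paste(rep("E", 11), collapse = "+"),
                   offsets = paste(c(rep(0, 9), 9), collapse = ","))
  expect_false(qcFilter(tenj, thr)$qc_pass)    # 9/10 = 0.90 exactly
  ## quality gate is skipped when qualities are absent
  nq <- makeCall("noq", mean_quality = NA)
  expect_true(qcFilter(nq, thr)$qc_pass)
})

test_that("clustering groups identical chains and flags wobble artifacts", {
  f <- fx()
  base <- "E_VII+E_2+E_EGFc+E_beta+E_L3"
  calls <- rbind(
    makeCall("a", chain = base, offsets = "0,0,0,0"),
    makeCall("b", chain = base, offsets = "0,0,0,0"),
    makeCall("c", chain = base, offsets = "0,2,0,0"))  # read-level wobble
  cl <- clusterAndCollapse(calls, f$locus)
  expect_identical(nrow(cl$chains), 1L)
  expect_identical(cl$counts$count, 3L)                # merged by snapping
  ## a minor chain on the annotated +3 boundary variant, single library
  calls <- rbind(
    do.call(rbind, lapply(1:30, function(i)
      makeCall(paste0("m", i), chain = base, offsets = "0,0,0,0"))),
    makeCall("v1", chain = "E_VII+E_2+E_EGFc+E_beta.v3+E_L3",
             offsets = "0,0,0,0"),
    makeCall("v2", chain = "E_VII+E_2+E_EGFc+E_beta.v3+E_L3",
             offsets = "0,0,0,0"))
  cl <- clusterAndCollapse(calls, f$locus)
  v <- cl$chains[grepl("beta.v3", cl$chains$chain, fixed = TRUE), ]
  expect_true(v$wobble_minor)
  expect_true(v$artifact)
  ## the same minor chain seen in two libraries is retained, not artifact
  calls$library[calls$read_id == "v2"] <- "progenitor"
  calls <- rbind(calls,
                 do.call(rbind, lapply(1:30, function(i)
                   makeCall(paste0("p", i), chain = base,
                            offsets = "0,0,0,0",
                            library = "progenitor"))))
  cl <- clusterAndCollapse(calls, f$locus)
  v <- cl$chains[grepl("beta.v3", cl$chains$chain, fixed = TRUE), ]
  expect_true(v$wobble_minor)
  expect_false(v$artifact)
  q <- quantifyAndFilter(cl, f$locus)
  expect_identical(
    q$candidates$status[grepl("beta.v3", q$candidates$chain,
                              fixed = TRUE)], "low_abundance")
})

test_that("the 5% filter is inclusive, per cell, per amplicon", {
  f <- fx()
  base <- "E_VII+E_2+E_EGFc+E_beta+E_L3"
  other <- "E_VII+E_2+E_EGFc+E_alpha+E_beta+E_L3"
  mk <- function(chain, n, lib = "monocyte", amp = "short")
    do.call(rbind, lapply(seq_len(n), function(i)
      makeCall(paste(chain, lib, amp, i), chain = chain,
               offsets = "0,0,0,0", library = lib, amplicon = amp)))
  ## 5 of 100 reads reaches the threshold; 4 of 100 does not
  cl <- clusterAndCollapse(rbind(mk(other, 95), mk(base, 5)), f$locus)
  q <- quantifyAndFilter(cl, f$locus)
  expect_identical(q$candidates$status[q$candidates$chain == base],
                   "high_confidence")
  cl <- clusterAndCollapse(rbind(mk(other, 96), mk(base, 4)), f$locus)
  q <- quantifyAndFilter(cl, f$locus)
  expect_identical(q$candidates$status[q$candidates$chain == base],
                   "low_abundance")
  ## 12% in one amplicon suffices even at 0% in the other
  cl <- clusterAndCollapse(rbind(mk(other, 88), mk(base, 12),
                                 mk(other, 50, amp = "long")), f$locus)
  q <- quantifyAndFilter(cl, f$locus)
  expect_identical(q$candidates$status[q$candidates$chain == base],
                   "high_confidence")
  ## raising the threshold never adds a high-confidence isoform
  hcAt <- function(mf) {
    q <- quantifyAndFilter(cl, f$locus, minFraction = mf)
    q$candidates$chain[q$candidates$status == "high_confidence"]
  }
  prev <- hcAt(0.01)
  for (mf in c(0.05, 0.10, 0.13, 0.5)) {
    cur <- hcAt(mf)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("counts are conserved from QC through quantification", {
  f <- fx()
  lib <- defaultLibrarySpecs(depth = 120)$progenitor
  reads <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(),
                         seed = 31)
  asg <- assignAmplicons(reads, f$amps)
  ok <- asg[asg$assign_reason == "pass", ]
  calls <- qcFilter(callExonChains(ok, f$locus, f$amps))
  cl <- clusterAndCollapse(calls, f$locus)
  q <- quantifyAndFilter(cl, f$locus)
  byCell <- tapply(cl$counts$count,
                   paste(cl$counts$library, cl$counts$amplicon), sum)
  qcByCell <- table(paste(calls$library[calls$qc_pass],
                          calls$amplicon[calls$qc_pass]))
  expect_identical(as.integer(byCell[names(qcByCell)]),
                   as.integer(qcByCell))
  fr <- q$fractions
  sums <- tapply(fr$fraction, paste(fr$library, fr$amplicon), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("zero-error discovery recovers the planted set end to end", {
  f <- fx()
  err0 <- errorModel(substitution = 0, insertion = 0, deletion = 0,
                     junctionWobbleProb = 0, truncationProb = 0)
  libs <- defaultLibrarySpecs(depth = 250)
  reads <- do.call(rbind, lapply(seq_along(libs), function(i)
    simulateReads(f$locus, f$iso, libs[[i]], f$amps, err0,
                  seed = 70 + i)))
  asg <- assignAmplicons(reads, f$amps)
  calls <- qcFilter(callExonChains(asg[asg$assign_reason == "pass", ],
                                   f$locus, f$amps))
  ## oracle equivalence: every called chain equals its truth chain (the
  ## caller reports primary exons; boundary-variant decoys resolve at the
  ## snapping stage, so compare those post-snap)
  truthIso <- asg$isoform_truth[asg$assign_reason == "pass"]
  truth <- vapply(truthIso, function(nm)
    paste(f$iso[[nm]]@chain, collapse = "+"), character(1))
  plain <- !grepl("^decoy", truthIso)
  expect_identical(unname(calls$chain[plain]), unname(truth[plain]))
  cl <- clusterAndCollapse(calls, f$locus)
  for (nm in c("decoy.b3.w3", "decoy.a2a.w4"))
    expect_true(paste(f$iso[[nm]]@chain, collapse = "+") %in%
                  cl$chains$chain)
  q <- quantifyAndFilter(cl, f$locus)
  hc <- q$candidates[q$candidates$status == "high_confidence", ]
  expect_setequal(hc$name, PLANTED_NAMES)
})

test_that("noisy recovery is stable across seeds", {
  f <- fx()
  libs <- defaultLibrarySpecs(depth = 600)
  for (s in 101:105) {
    reads <- do.call(rbind, lapply(seq_along(libs), function(i)
      simulateReads(f$locus, f$iso, libs[[i]], f$amps, errorModel(),
                    seed = s + 7 * i)))
    asg <- assignAmplicons(reads, f$amps)
    calls <- qcFilter(callExonChains(asg[asg$assign_reason == "pass", ],
                                     f$locus, f$amps))
    q <- quantifyAndFilter(clusterAndCollapse(calls, f$locus), f$locus)
    hc <- q$candidates[q$candidates$status == "high_confidence", ]
    expect_setequal(hc$name, PLANTED_NAMES)
  }
})

test_that("identical inputs give identical candidate tables", {
  f <- fx()
  lib <- defaultLibrarySpecs(depth = 150)$monocyte
  run <- function() {
    reads <- simulateReads(f$locus, f$iso, lib, f$amps, errorModel(),
                           seed = 77)
    asg <- assignAmplicons(reads, f$amps)
    calls <- qcFilter(callExonChains(asg[asg$assign_reason == "pass", ],
                                     f$locus, f$amps))
    quantifyAndFilter(clusterAndCollapse(calls, f$locus), f$locus)
  }
  expect_identical(run(), run())
})
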