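## Peptide segmentation of the poison open reading frame, as printed:
## 8 class-specific residues + 17 shared first-exon residues + 20 spacer
## residues + 22 poison-exon residues = 67 aa, terminating at an amber TAG.
PEP_NTERM  <- "MSYHLFFS"
PEP_SHARED <- "EIITGMPASTEGAYVSS"
PEP_SPACER <- "ESPIRISVSTEGANTSSFIT"
PEP_POISON <- "DECCHGGQYHNTAKSICLILMF"

## A common EGF-like segment used for the shared EGF exon (invented,
## stop-free, 22 residues = 66 nt).
PEP_EGF_COMMON <- "GTSHLVKCAEKEKTFCVNGGEC"

## Primer set: forward in the class-specific 5' UTR; reverse primers define
## the short (linker-3) and long (a-tail) amplicons.
PRIMER_FWD       <- "TTAGTTCCAAGGCAGGCTGT"
PRIMER_REV_SHORT <- "GATGCAGCAACAAGAAAGCA"
PRIMER_REV_LONG  <- "TTTCCTGTTTTCTATTTGCAGAAC"

#' Fixture locus configuration
#'
#' The five printed architecture dimensions (139-nt unique + 51-nt shared
#' first exon, initiating ATG at transcript position 115, 59-nt spacer exon,
#' 111-nt poison exon) are fixed: the poison-ORF peptide arithmetic
#' (8 + 17 + 20 + 22 = 67 residues) only holds for them, and the
#' constructor rejects other values. The EGF, transmembrane, tail and
#' linker-3 exon lengths are tunable under the frame congruences
#' `egfAlphaLen %% 3 == egfBetaLen %% 3 != 0` (the source of the
#' alpha+beta frame shift) and `egfCommonLen %% 3 == 0`.
#'
#' @param seed Integer seed for the constrained-random exon filler.
#' @param egfCommonLen,egfAlphaLen,egfBetaLen,tm2Len,tailALen,tailBLen,linker3Len
#'   Exon lengths in nucleotides.
#' @param firstExonUniqueLen,firstExonSharedLen,atgPosition,spacerExonLen,poisonExonLen
#'   Printed architecture dimensions; fixed to 139/51/115/59/111.
#' @return A validated `fixture_config` list.
#' @export
fixtureConfig <- function(seed = 1150L,
                          egfCommonLen = 66L, egfAlphaLen = 76L,
                          egfBetaLen = 64L, tm2Len = 120L,
                          tailALen = 132L, tailBLen = 81L,
                          linker3Len = 160L,
                          firstExonUniqueLen = 139L,
                          firstExonSharedLen = 51L,
                          atgPosition = 115L, spacerExonLen = 59L,
                          poisonExonLen = 111L) {
  cfg <- list(seed = as.integer(seed),
              egfCommonLen = as.integer(egfCommonLen),
              egfAlphaLen = as.integer(egfAlphaLen),
              egfBetaLen = as.integer(egfBetaLen),
              tm2Len = as.integer(tm2Len), tailALen = as.integer(tailALen),
              tailBLen = as.integer(tailBLen),
              linker3Len = as.integer(linker3Len),
              firstExonUniqueLen = as.integer(firstExonUniqueLen),
              firstExonSharedLen = as.integer(firstExonSharedLen),
              atgPosition = as.integer(atgPosition),
              spacerExonLen = as.integer(spacerExonLen),
              poisonExonLen = as.integer(poisonExonLen))
  fe <- cfg$firstExonUniqueLen + cfg$firstExonSharedLen
  if (cfg$atgPosition + 2L > fe)
    stop("fixture-construction error: ATG does not fit in the first exon",
         call. = FALSE)
  fixedDims <- c(firstExonUniqueLen = 139L, firstExonSharedLen = 51L,
                 atgPosition = 115L, spacerExonLen = 59L,
                 poisonExonLen = 111L)
  for (nm in names(fixedDims))
    if (cfg[[nm]] != fixedDims[[nm]])
      stop("fixture-construction error: ", nm, " must be ", fixedDims[[nm]],
           " (locus architecture is fixed by the printed peptide ",
           "arithmetic)", call. = FALSE)
  if (cfg$egfCommonLen %% 3L != 0L || cfg$egfCommonLen < 30L)
    stop("infeasible congruence constraints: egfCommonLen must be a ",
         "multiple of 3 and >= 30", call. = FALSE)
  s <- cfg$egfAlphaLen %% 3L
  if (s == 0L)
    stop("infeasible congruence constraints: egfAlphaLen must not be a ",
         "multiple of 3 (the alpha+beta frame shift requires it)",
         call. = FALSE)
  if (cfg$egfBetaLen %% 3L != s)
    stop("infeasible congruence constraints: egfAlphaLen and egfBetaLen ",
         "must be congruent mod 3", call. = FALSE)
  if (cfg$egfAlphaLen < 45L || cfg$egfBetaLen < 45L)
    stop("fixture-construction error: EGF exons must be >= 45 nt",
         call. = FALSE)
  if (cfg$tm2Len < 75L)
    stop("fixture-construction error: tm2Len must be >= 75 nt (the ",
         "frameshift stop must sit > 50 nt upstream of the tail junction)",
         call. = FALSE)
  if (cfg$tailALen < 100L || cfg$tailBLen < 45L || cfg$linker3Len < 120L)
    stop("fixture-construction error: terminal exons too short for their ",
         "stop and primer-site layout", call. = FALSE)
  if (max(unlist(cfg[-1])) > 360L)
    stop("fixture-construction error: exon lengths above 360 nt exceed the ",
         "fixture's genomic spacing", call. = FALSE)
  structure(cfg, class = "fixture_config")
}

#' Build the fixture locus
#'
#' Constructs the modular class-VII locus: a 190-nt first exon (139-nt
#' class-specific 5' region carrying the forward primer site, 51-nt shared
#' portion), the initiating ATG at transcript positions 115-117, a 59-nt
#' spacer exon, a 111-nt poison exon whose inclusion introduces an amber
#' TAG, a shared EGF exon plus distinct alpha and beta EGF cassettes whose
#' lengths are congruent mod 3 but not multiples of 3, a transmembrane
#' exon, a/b cytoplasmic tail exons and a linker-3 terminal exon, plus two
#' annotated boundary-variant (wobble) exons used to plant decoys. All
#' printed dimensions are re-asserted by independent scans of the built
#' sequence, not merely set.
#'
#' @param cfg A [fixtureConfig()] list.
#' @return A [LocusModel-class].
#' @export
buildFixtureLocus <- function(cfg = fixtureConfig()) {
  withr::with_seed(cfg$seed, buildFixtureLocusImpl(cfg))
}

buildFixtureLocusImpl <- function(cfg) {
  s <- cfg$egfAlphaLen %% 3L         # alpha/beta carry phase (1 or 2)
  tPhase <- (s + cfg$tm2Len) %% 3L   # tail-exon entering phase

  ## --- first exon: UTR + class-specific codons + shared portion ----------
  atg <- cfg$atgPosition
  utr <- makeUtrSeq(atg - 1L, embed = list(list(pos = 21L,
                                                seq = PRIMER_FWD)))
  ntermNt <- backTranslate(PEP_NTERM)                    # codons 1-8
  sharedCodon9 <- CODON_PREF[[substr(PEP_SHARED, 1, 1)]] # bridges 139|140
  sharedRest <- backTranslate(substr(PEP_SHARED, 2, nchar(PEP_SHARED)))
  carry26 <- substr(CODON_PREF[[substr(PEP_SPACER, 1, 1)]], 1, 1)
  firstExonSeq <- paste0(utr, ntermNt, sharedCodon9, sharedRest, carry26)

  ## --- spacer exon: completes codon 26, codons 27-45 ---------------------
  spacerSeq <- paste0(substr(CODON_PREF[[substr(PEP_SPACER, 1, 1)]], 2, 3),
                      backTranslate(substr(PEP_SPACER, 2,
                                           nchar(PEP_SPACER))))

  ## --- poison exon: 22 codons, amber TAG at nt 67-69, then filler --------
  poisonCore <- paste0(backTranslate(PEP_POISON), "TAG")
  poisonFiller <- paste0(sample(c("A", "C", "G", "T"),
                                cfg$poisonExonLen - nchar(poisonCore),
                                replace = TRUE), collapse = "")
  poisonSeq <- paste0(poisonCore, poisonFiller)

  ## --- EGF exons ---------------------------------------------------------
  egfcSeq <- backTranslate(PEP_EGF_COMMON)
  if (nchar(egfcSeq) != cfg$egfCommonLen)
    egfcSeq <- makeConstrainedSeq(cfg$egfCommonLen,
      noStop = list(codonStartsAtPhase(cfg$egfCommonLen, 0L)))
  alphaSeq <- makeConstrainedSeq(cfg$egfAlphaLen,
    noStop = list(codonStartsAtPhase(cfg$egfAlphaLen, 0L)),
    carryTail = 2L)
  ## beta is read in phase 0 (single-EGF chains) and in phase s (after
  ## alpha): stop-free in both, so alpha+beta chains read through into the
  ## terminal exon in a shifted frame
  betaSeq <- makeConstrainedSeq(cfg$egfBetaLen,
    noStop = list(codonStartsAtPhase(cfg$egfBetaLen, 0L),
                  codonStartsAtPhase(cfg$egfBetaLen, s)),
    carryTail = 2L)

  ## --- transmembrane exon: clean in the annotated frame, early stop in
  ##     the alpha+beta-shifted frame (> 50 nt upstream of the tail
  ##     junction, hence an NMD candidate) ---------------------------------
  shifted <- (2L * s) %% 3L
  tmFresh <- codonStartsAtPhase(cfg$tm2Len, s)
  tmShift <- codonStartsAtPhase(cfg$tm2Len, shifted)
  tmStopAt <- tmShift[3L]
  tm2Seq <- makeConstrainedSeq(cfg$tm2Len,
    noStop = list(tmFresh, tmShift[tmShift < tmStopAt]),
    forcedStops = list(list(pos = tmStopAt, codon = "TAA")),
    carryTail = 2L)

  ## --- tail a: annotated-frame stop mid-exon, long reverse primer site in
  ##     the 3' UTR --------------------------------------------------------
  revLongSite <- as.character(reverseComplement(DNAString(PRIMER_REV_LONG)))
  aSitePos <- cfg$tailALen - nchar(revLongSite) - 7L
  aFresh <- codonStartsAtPhase(cfg$tailALen, tPhase)
  aStopAt <- aFresh[which.min(abs(aFresh - (aSitePos - 40L)))]
  tailASeq <- makeConstrainedSeq(cfg$tailALen,
    noStop = list(aFresh[aFresh < aStopAt]),
    forcedStops = list(list(pos = aStopAt, codon = "TAA")),
    embed = list(list(pos = aSitePos, seq = revLongSite)))

  ## --- tail b: cassette before tail a; its stop sits within 50 nt of the
  ##     b|a junction so 2b isoforms remain coding under the NMD rule ------
  bFresh <- codonStartsAtPhase(cfg$tailBLen, tPhase)
  bStopAt <- max(bFresh[bFresh <= cfg$tailBLen - 8L])
  tailBSeq <- makeConstrainedSeq(cfg$tailBLen,
    noStop = list(bFresh[bFresh < bStopAt]),
    forcedStops = list(list(pos = bStopAt, codon = "TAA")))

  ## --- linker-3 terminal exon: distinct stops in the annotated frame
  ##     (beta-type chains) and the alpha+beta-shifted frame (unique
  ##     C-terminus), short reverse primer site in the 3' UTR --------------
  revShortSite <- as.character(reverseComplement(DNAString(PRIMER_REV_SHORT)))
  l3SitePos <- cfg$linker3Len - nchar(revShortSite) - 21L
  l3Fresh <- codonStartsAtPhase(cfg$linker3Len, s)
  l3Shift <- codonStartsAtPhase(cfg$linker3Len, shifted)
  l3StopA <- l3Fresh[9L]
  l3StopB <- l3Shift[which.min(abs(l3Shift - (l3StopA + 23L)))]
  l3Seq <- makeConstrainedSeq(cfg$linker3Len,
    noStop = list(l3Fresh[l3Fresh < l3StopA],
                  l3Shift[l3Shift < l3StopB]),
    forcedStops = list(list(pos = l3StopA, codon = "TAA"),
                       list(pos = l3StopB, codon = "TAG")),
    embed = list(list(pos = l3SitePos, seq = revShortSite)))

  ## --- wobble decoy extras: 5' extensions that neither repeat the
  ##     upstream exon's 3' end nor the parent exon's 5' start -------------
  pickExtra <- function(n, avoid) {
    repeat {
      x <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
      if (!x %in% avoid) return(x)
    }
  }
  betaExtra <- pickExtra(3L, c(substr(egfcSeq, nchar(egfcSeq) - 2L,
                                      nchar(egfcSeq)),
                               substr(betaSeq, 1L, 3L)))
  tailAExtra <- pickExtra(4L, c(substr(tm2Seq, nchar(tm2Seq) - 3L,
                                       nchar(tm2Seq)),
                                substr(tailASeq, 1L, 4L)))

  contig <- "locusVII_fixture"
  mk <- function(id, gstart, seqStr, roles, phase, meta = list())
    exon(id, genomicInterval(contig, gstart, gstart + nchar(seqStr)),
         seqStr, roles, phase = phase, meta = meta)
  exons <- list(
    mk("E_VII", 1000L, firstExonSeq,
       c("NTERM_CLASS_VII", "SHARED_FIRSTEXON", "UTR"), 0L,
       meta = list(shared_offset = cfg$firstExonUniqueLen,
                   atg = cfg$atgPosition)),
    mk("E_2", 1500L, spacerSeq, "SPACER", 1L),
    mk("E_P", 2000L, poisonSeq, "POISON", 0L),
    mk("E_EGFc", 2500L, egfcSeq, "EGF_COMMON", 0L),
    mk("E_alpha", 3000L, alphaSeq, "EGF_ALPHA", 0L),
    mk("E_beta", 3500L, betaSeq, "EGF_BETA", 0L),
    mk("E_beta.v3", 3497L, paste0(betaExtra, betaSeq), "EGF_BETA", 0L,
       meta = list(variant_of = "E_beta", shift = 3L)),
    mk("E_TM2", 4000L, tm2Seq, "TM2", s),
    mk("E_tailB", 4500L, tailBSeq, "TAIL_B", tPhase),
    mk("E_tailA", 5000L, tailASeq, c("TAIL_A", "UTR"), tPhase),
    mk("E_tailA.v4", 4996L, paste0(tailAExtra, tailASeq),
       c("TAIL_A", "UTR"), tPhase,
       meta = list(variant_of = "E_tailA", shift = 4L)),
    mk("E_L3", 5600L, l3Seq, c("LINKER3_TERMINAL", "UTR"), s))

  ## frame anchor: a canonical codon start inside the shared portion of the
  ## first exon (codon 10, transcript position atg+27, 0-based offset)
  anchorOffset <- cfg$atgPosition + 27L - 1L
  locus <- locusModel(contig, exons,
    frameAnchor = list(exon = "E_VII", offset = anchorOffset),
    nameOverrides = list("VII-Paca" = c("E_VII", "E_2", "E_P", "E_EGFc",
                                        "E_alpha", "E_L3")),
    meta = list(config = unclass(cfg),
                primers = list(forward = PRIMER_FWD,
                               reverse_short = PRIMER_REV_SHORT,
                               reverse_long = PRIMER_REV_LONG)))
  assertFixtureGeometry(locus)
  locus
}

## Construction/assertion split: every printed dimension is re-measured on
## the built object by an independent scan.
assertFixtureGeometry <- function(locus) {
  cfg <- locus@meta$config
  fe <- getExon(locus, "E_VII")
  stopifnot(intervalLength(fe@interval) ==
              cfg$firstExonUniqueLen + cfg$firstExonSharedLen)
  firstAtg <- gregexpr("ATG", fe@sequence, fixed = TRUE)[[1]][1]
  if (firstAtg != cfg$atgPosition)
    stop("fixture-construction error: first ATG scans at ", firstAtg,
         " not ", cfg$atgPosition, call. = FALSE)
  if (regexpr(PRIMER_FWD, substr(fe@sequence, 1, cfg$firstExonUniqueLen),
              fixed = TRUE) < 0)
    stop("fixture-construction error: forward primer not in the unique 5' ",
         "region", call. = FALSE)
  pe <- getExon(locus, "E_P")
  stopifnot(intervalLength(pe@interval) == cfg$poisonExonLen,
            substr(pe@sequence, 67, 69) == "TAG")
  invisible(TRUE)
}

#' Build the fixture isoform set
#'
#' Returns the eight study isoforms (alpha-beta-3, beta-3, alpha-2a,
#' alpha-2b, beta-2a, alpha-beta-2a, P-beta-3 and the nonstandard P-alpha-ca
#' stand-in) tagged `planted`, the two sub-threshold variants beta-2b and
#' P-alpha-2a tagged `low_abundance`, and two junction-wobble decoy
#' transcripts built on annotated boundary-variant exons, tagged `decoy`.
#'
#' @param locus A fixture [LocusModel-class] from [buildFixtureLocus()].
#' @return Named list of [TranscriptModel-class] objects.
#' @export
buildFixtureIsoforms <- function(locus) {
  planted <- c("VII-ab3", "VII-b3", "VII-a2a", "VII-a2b", "VII-b2a",
               "VII-ab2a", "VII-Pb3", "VII-Paca")
  low <- c("VII-b2b", "VII-Pa2a")
  iso <- lapply(c(planted, low), function(nm) {
    t <- chainFromName(locus, nm)
    t@tag <- if (nm %in% low) "low_abundance" else "planted"
    t
  })
  names(iso) <- c(planted, low)
  iso$decoy.b3.w3 <- transcriptModel("decoy.b3.w3",
    c("E_VII", "E_2", "E_EGFc", "E_beta.v3", "E_L3"), tag = "decoy")
  iso$decoy.a2a.w4 <- transcriptModel("decoy.a2a.w4",
    c("E_VII", "E_2", "E_EGFc", "E_alpha", "E_TM2", "E_tailA.v4"),
    tag = "decoy")
  for (t in iso) validateChain(locus, t)
  iso
}
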