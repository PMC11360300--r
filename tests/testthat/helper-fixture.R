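## Shared fixture objects, built once per test run
.fx_cache <- new.env(parent = emptyenv())

fx <- function() {
  if (is.null(.fx_cache$locus)) {
    .fx_cache$locus <- buildFixtureLocus()
    .fx_cache$iso <- buildFixtureIsoforms(.fx_cache$locus)
    .fx_cache$amps <- fixtureAmplicons(.fx_cache$locus)
  }
  list(locus = .fx_cache$locus, iso = .fx_cache$iso, amps = .fx_cache$amps)
}

PLANTED_NAMES <- c("VII-ab3", "VII-b3", "VII-a2a", "VII-a2b", "VII-b2a",
                   "VII-ab2a", "VII-Pb3", "VII-Paca")

PRINTED_POISON_PEPTIDE <- paste0(
  "MSYHLFFSEIITGMPASTEGAYVSSESPIRISVSTEGANTSSFITDECCHGGQYHNTAKSICLILMF")

## Independent translation oracle: plain character-level codon lookup,
## sharing no code with the package path (which uses Biostrings::translate)
.GC_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

naiveTranslate <- function(seq, from) {
  seq <- as.character(seq)
  out <- character(0)
  i <- from
  while (i + 2L <= nchar(seq)) {
    aa <- .GC_TABLE[[substr(seq, i, i + 2L)]]
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3L
  }
  paste0(out, collapse = "")
}

## a chain call row in the callExonChains() layout, for constructed tests
makeCall <- function(read_id = "r1", chain = "E_VII+E_2",
                     offsets = "0", identity = 0.99, full_length = TRUE,
                     mean_quality = 15, amplicon = "short",
                     library = "monocyte", mapped = TRUE) {
  data.frame(read_id = read_id, chain = chain, offsets = offsets,
             identity = identity, exon_identity = NA_character_,
             full_length = full_length, mean_quality = mean_quality,
             amplicon = amplicon, library = library, mapped = mapped,
             qc_pass = TRUE, qc_reason = "pass", stringsAsFactors = FALSE)
}
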