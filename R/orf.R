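#' CodingAnnotation: ORF and classification record for one transcript
#'
#' @slot transcriptId Transcript label.
#' @slot atgPosition 1-based transcript coordinate of the initiating ATG
#'   (`NA` when no in-frame ATG exists).
#' @slot stopPosition 1-based transcript coordinate of the stop-codon start
#'   (`NA` when translation reads through to the transcript end).
#' @slot peptide Translated amino-acid string (empty when noncoding).
#' @slot frameShiftExons Exon ids read out of their annotated codon phase.
#' @slot ptc Logical: premature termination codon under the NMD rule.
#' @slot nmdCandidate Logical: flagged for nonsense-mediated decay.
#' @slot codingClass `"coding"`, `"NMD_candidate"` or `"noncoding"`.
#' @export
setClass("CodingAnnotation",
         representation(transcriptId = "character",
                        atgPosition = "integer", stopPosition = "integer",
                        peptide = "character", frameShiftExons = "character",
                        ptc = "logical", nmdCandidate = "logical",
                        codingClass = "character"),
         prototype(atgPosition = NA_integer_, stopPosition = NA_integer_,
                   peptide = "", frameShiftExons = character(),
                   ptc = NA, nmdCandidate = NA,
                   codingClass = NA_character_))

setValidity("CodingAnnotation", function(object) {
  msg <- character()
  if (nzchar(object@peptide) && is.na(object@atgPosition))
    msg <- c(msg, "peptide requires an initiating ATG")
  if (isTRUE(object@ptc) && is.na(object@stopPosition))
    msg <- c(msg, "a premature termination codon requires a stop position")
  if (isTRUE(object@nmdCandidate) && !isTRUE(object@ptc))
    msg <- c(msg, "an NMD candidate must carry a PTC")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CodingAnnotation", function(object) {
  cat(sprintf("CodingAnnotation %s: %s\n", object@transcriptId,
              ifelse(is.na(object@codingClass), "(unclassified)",
                     object@codingClass)))
  if (!is.na(object@atgPosition))
    cat(sprintf("  ATG at %d; stop at %s; peptide %d aa%s\n",
                object@atgPosition,
                ifelse(is.na(object@stopPosition), "none",
                       object@stopPosition), nchar(object@peptide),
                if (length(object@frameShiftExons))
                  paste0("; frame shift in ",
                         paste(object@frameShiftExons, collapse = ","))
                else ""))
})

#' Find the initiating ATG in the canonical frame
#'
#' Scans a spliced mRNA for the first ATG whose reading frame matches the
#' canonical coding frame propagated from the locus frame anchor.
#'
#' @param mrna A [Biostrings::DNAString] or character mRNA.
#' @param anchor 1-based transcript coordinate that is a canonical codon
#'   start (see [transcriptFrameAnchor()]).
#' @return 1-based position of the first in-frame ATG, or `NA` if absent.
#' @export
findInitiatingAtg <- function(mrna, anchor) {
  s <- as.character(mrna)
  hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  inframe <- hits[(hits - as.integer(anchor)) %% 3L == 0L]
  if (!length(inframe)) return(NA_integer_)
  as.integer(inframe[1])
}

orfEnd <- function(ann, mrnaLen) {
  if (is.na(ann@stopPosition)) mrnaLen else ann@stopPosition + 2L
}

#' Translate a transcript chain with frame tracking
#'
#' Splices the chain, finds the initiating ATG in the canonical frame,
#' translates to the first stop codon (standard nuclear code), and records
#' which exons are read out of their annotated codon phase.
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class].
#' @return A [CodingAnnotation-class] (class `"noncoding"` with empty
#'   peptide when no in-frame ATG exists; `ptc`/`nmdCandidate` remain `NA`
#'   until [classifyNmd()]).
#' @export
translateChain <- function(locus, transcript) {
  mrna <- spliceTranscript(locus, transcript)
  anchor <- transcriptFrameAnchor(locus, transcript)
  atg <- findInitiatingAtg(mrna, anchor)
  if (is.na(atg))
    return(new("CodingAnnotation", transcriptId = transcript@id,
               codingClass = "noncoding", ptc = FALSE,
               nmdCandidate = FALSE))
  nAfter <- length(mrna) - atg + 1L
  cds <- Biostrings::subseq(mrna, atg, atg + (nAfter %/% 3L) * 3L - 1L)
  aa <- as.character(Biostrings::translate(cds))
  stopAt <- regexpr("*", aa, fixed = TRUE)[1]
  if (stopAt > 0) {
    peptide <- substr(aa, 1, stopAt - 1L)
    stopPos <- atg + 3L * (stopAt - 1L)
  } else {
    peptide <- aa
    stopPos <- NA_integer_
  }
  ann <- new("CodingAnnotation", transcriptId = transcript@id,
             atgPosition = as.integer(atg),
             stopPosition = as.integer(stopPos), peptide = peptide)
  lay <- transcriptLayout(locus, transcript)
  endPos <- orfEnd(ann, length(mrna))
  shifts <- character()
  for (i in seq_along(lay$exon)) {
    st <- lay$start[i]
    if (st <= atg || st > endPos) next
    e <- getExon(locus, lay$exon[i])
    if (is.na(e@phase)) next
    actual <- (st - atg) %% 3L
    if (actual != e@phase) shifts <- c(shifts, e@id)
  }
  ann@frameShiftExons <- shifts
  ann
}

#' Classify a transcript under the NMD rule
#'
#' A stop codon ending more than `ruleDistance` nt upstream of the final
#' exon-exon junction is a premature termination codon; such transcripts
#' are NMD candidates, all other stop-bearing transcripts are coding.
#'
#' @param locus A [LocusModel-class].
#' @param transcript The annotated [TranscriptModel-class].
#' @param ann The [CodingAnnotation-class] from [translateChain()].
#' @param ruleDistance Rule distance in nt (default 50, the standard rule).
#' @return The updated [CodingAnnotation-class] with `ptc`, `nmdCandidate`
#'   and `codingClass` set.
#' @export
classifyNmd <- function(locus, transcript, ann, ruleDistance = 50L) {
  if (identical(ann@codingClass, "noncoding")) return(ann)
  lay <- transcriptLayout(locus, transcript)
  junctions <- lay$junctions
  if (is.na(ann@stopPosition) || !length(junctions)) {
    ann@ptc <- FALSE
  } else {
    stopEnd <- ann@stopPosition + 2L
    lastJ <- max(junctions)
    ann@ptc <- (lastJ - stopEnd) > ruleDistance
  }
  ann@nmdCandidate <- ann@ptc
  ann@codingClass <- if (ann@ptc) "NMD_candidate" else "coding"
  validObject(ann)
  ann
}

#' Annotate protein domains on a translated isoform
#'
#' Maps translated residue spans to exon domain roles. Each residue is
#' assigned to the exon containing the centre nucleotide of its codon, so
#' junction-bridging codons belong to the downstream exon; within a first
#' exon carrying both the class-specific and shared roles, the split falls
#' at the unique/shared boundary. A transmembrane domain is called only
#' when the TM exon is completely translated in its annotated frame;
#' coding isoforms without such a call are flagged as secreted forms.
#'
#' @param locus A [LocusModel-class].
#' @param transcript The [TranscriptModel-class].
#' @param ann A classified [CodingAnnotation-class].
#' @return Data frame with columns `role`, `aa_start`, `aa_end`,
#'   `complete`, plus attributes `tm_present` and `secreted`.
#' @export
annotateDomains <- function(locus, transcript, ann) {
  if (!nzchar(ann@peptide))
    stop("annotateDomains requires a translated isoform", call. = FALSE)
  lay <- transcriptLayout(locus, transcript)
  mrnaLen <- lay$end[length(lay$end)]
  nres <- nchar(ann@peptide)
  centre <- ann@atgPosition + 3L * (seq_len(nres) - 1L) + 1L
  exIdx <- findInterval(centre - 1L, lay$end) + 1L
  roleOf <- character(nres)
  for (i in seq_len(nres)) {
    e <- getExon(locus, lay$exon[exIdx[i]])
    roles <- setdiff(e@roles, "UTR")
    if (all(c("NTERM_CLASS_VII", "SHARED_FIRSTEXON") %in% e@roles)) {
      exPos <- centre[i] - lay$start[exIdx[i]] + 1L +
        if (exIdx[i] == 1L) transcript@tssOffset else 0L
      bnd <- e@meta$shared_offset
      roleOf[i] <- if (!is.null(bnd) && exPos <= bnd) "NTERM_CLASS_VII"
                   else "SHARED_FIRSTEXON"
    } else roleOf[i] <- roles[1]
  }
  runs <- rle(paste(roleOf, exIdx, sep = "|"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  endPos <- orfEnd(ann, mrnaLen)
  out <- data.frame(role = sub("\\|.*", "", runs$values),
                    aa_start = starts, aa_end = ends, complete = NA,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    i <- exIdx[starts[r]]
    e <- getExon(locus, lay$exon[i])
    st <- lay$start[i]
    inFrame <- is.na(e@phase) ||
      (st > ann@atgPosition && (st - ann@atgPosition) %% 3L == e@phase) ||
      st <= ann@atgPosition
    covered <- ann@atgPosition <= st && endPos >= lay$end[i]
    out$complete[r] <- inFrame && covered
  }
  tm <- any(out$role == "TM2" & out$complete)
  attr(out, "tm_present") <- tm
  attr(out, "secreted") <- identical(ann@codingClass, "coding") && !tm
  out
}

#' IsoformCatalogue: reference coding count plus accepted novel isoforms
#'
#' @slot referenceCount Integer count of previously annotated coding
#'   isoforms (28 for the reference locus).
#' @slot accepted Character vector of accepted novel coding isoform names.
#' @export
setClass("IsoformCatalogue",
         representation(referenceCount = "integer", accepted = "character"),
         prototype(referenceCount = 28L, accepted = character()))

#' Construct an IsoformCatalogue
#'
#' @param referenceCount Reference coding isoform count (default 28).
#' @param accepted Initial accepted set (default empty).
#' @return An [IsoformCatalogue-class].
#' @export
isoformCatalogue <- function(referenceCount = 28L, accepted = character()) {
  new("IsoformCatalogue", referenceCount = as.integer(referenceCount),
      accepted = accepted)
}

#' Total coding isoform count of a catalogue
#'
#' @param cat An [IsoformCatalogue-class].
#' @return `referenceCount + length(accepted)`.
#' @export
catalogueTotal <- function(cat) cat@referenceCount + length(cat@accepted)

#' @export
setMethod("show", "IsoformCatalogue", function(object) {
  cat(sprintf("IsoformCatalogue: %d reference + %d accepted = %d coding\n",
              object@referenceCount, length(object@accepted),
              catalogueTotal(object)))
  if (length(object@accepted))
    cat("  accepted:", paste(object@accepted, collapse = ", "), "\n")
})

#' Add accepted coding isoforms to a catalogue
#'
#' @param cat An [IsoformCatalogue-class].
#' @param annotations Either a character vector of isoform names with a
#'   parallel `codingClass` argument, or a named character vector/list of
#'   coding classes keyed by isoform name; only class `"coding"` entries
#'   are accepted.
#' @param codingClass Optional character vector parallel to `annotations`.
#' @return The updated catalogue; duplicate names raise a duplication
#'   error.
#' @export
updateCatalogue <- function(cat, annotations, codingClass = NULL) {
  if (is.null(codingClass)) {
    codingClass <- unlist(annotations)
    nms <- names(codingClass)
  } else nms <- as.character(annotations)
  if (anyDuplicated(nms))
    stop("duplication error: repeated isoform names", call. = FALSE)
  add <- nms[codingClass == "coding"]
  if (any(add %in% cat@accepted))
    stop("duplication error: isoform already in catalogue", call. = FALSE)
  cat@accepted <- c(cat@accepted, add)
  cat
}
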