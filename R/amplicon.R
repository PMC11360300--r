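#' Amplicon specification
#'
#' An amplicon is delimited by the shared forward primer in the
#' class-specific 5' UTR and one of two reverse primers: the short amplicon
#' ends in the linker-3 terminal exon, the long amplicon in the a-tail exon.
#'
#' @param name Amplicon label (`"short"` or `"long"`).
#' @param forward Forward primer sequence (plus-strand, >= 18 nt).
#' @param reverse Reverse primer sequence (reverse-complement of the
#'   plus-strand site, >= 18 nt).
#' @param terminalRole Domain role of the exon carrying the reverse primer
#'   site.
#' @return An `amplicon_spec` list.
#' @export
ampliconSpec <- function(name, forward, reverse, terminalRole) {
  if (nchar(forward) < 18L || nchar(reverse) < 18L)
    stop("primers must be at least 18 nt", call. = FALSE)
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse), terminalRole = terminalRole),
            class = "amplicon_spec")
}

#' Amplicon specifications of the fixture locus
#'
#' @param locus A fixture [LocusModel-class].
#' @return Named list with the `short` and `long` [ampliconSpec()] objects.
#' @export
fixtureAmplicons <- function(locus) {
  pr <- locus@meta$primers
  if (is.null(pr))
    stop("locus carries no primer metadata", call. = FALSE)
  fe <- getExon(locus, "E_VII")
  uniq <- fe@meta$shared_offset
  if (regexpr(pr$forward, substr(fe@sequence, 1, uniq), fixed = TRUE) < 0)
    stop("forward primer must lie within the class-VII unique 5' region",
         call. = FALSE)
  list(short = ampliconSpec("short", pr$forward, pr$reverse_short,
                            "LINKER3_TERMINAL"),
       long = ampliconSpec("long", pr$forward, pr$reverse_long, "TAIL_A"))
}

revCompChar <- function(x)
  as.character(reverseComplement(DNAString(x)))

#' Amplicon subsequence of an isoform
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class].
#' @param spec An [ampliconSpec()].
#' @return List with `sequence` (character), `fwdStart` (1-based transcript
#'   coordinate of the forward primer) and `junctions` (junction positions
#'   in amplicon coordinates). Raises an amplicon-mismatch error when either
#'   primer site is absent from the spliced transcript.
#' @export
ampliconSequence <- function(locus, transcript, spec) {
  s <- as.character(spliceTranscript(locus, transcript))
  fpos <- regexpr(spec$forward, s, fixed = TRUE)[1]
  site <- revCompChar(spec$reverse)
  rpos <- regexpr(site, s, fixed = TRUE)[1]
  if (fpos < 0 || rpos < 0)
    stop("amplicon-mismatch error: isoform '", transcript@id,
         "' lacks a primer site for amplicon '", spec$name, "'",
         call. = FALSE)
  endPos <- rpos + nchar(site) - 1L
  lay <- transcriptLayout(locus, transcript)
  j <- lay$junctions
  j <- j[j >= fpos & j < endPos] - fpos + 1L
  list(sequence = substr(s, fpos, endPos), fwdStart = fpos, junctions = j)
}
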