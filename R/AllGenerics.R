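#' @import methods
#' @importFrom stats lm coef rnorm runif setNames median
#' @importFrom utils head tail write.table read.delim packageVersion
#' @importFrom BiocGenerics start end strand
#' @importFrom S4Vectors mcols elementNROWS
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Length of a genomic interval
#'
#' Intervals are 0-based, half-open, so the length is simply `end - start`.
#'
#' @param x A [GenomicInterval-class] object.
#' @return Integer length in base pairs (always >= 1 for a valid interval).
#' @examples
#' intervalLength(genomicInterval("chr8", 32676084, 32676195))
#' @export
setGeneric("intervalLength", function(x) standardGeneric("intervalLength"))

#' Splice a transcript model into its mature sequence
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class] whose chain refers to exons of
#'   `locus`.
#' @return A [Biostrings::DNAString] with the concatenated exon sequences,
#'   the first exon truncated at the transcript's TSS offset.
#' @export
setGeneric("spliceTranscript",
           function(locus, transcript) standardGeneric("spliceTranscript"))

#' Derive the isoform name of a transcript chain
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class] starting at the class-defining
#'   first exon.
#' @return An [IsoformName-class].
#' @export
setGeneric("nameIsoform",
           function(locus, transcript) standardGeneric("nameIsoform"))

#' Reconstruct the exon chain encoded by an isoform name
#'
#' @param locus A [LocusModel-class].
#' @param name An [IsoformName-class] or a character rendering such as
#'   `"VII-ab3"`.
#' @return A [TranscriptModel-class] (the inverse of [nameIsoform()] on
#'   supported names).
#' @export
setGeneric("chainFromName",
           function(locus, name) standardGeneric("chainFromName"))

#' @rdname exonIds
#' @export
setGeneric("exonIds", function(x) standardGeneric("exonIds"))

#' @rdname exonChain
#' @export
setGeneric("exonChain", function(x) standardGeneric("exonChain"))
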