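#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Write transcript models as GTF
#'
#' Emits gene/transcript/exon features with `transcript_id`,
#' `isoform_name` and (when provided) `coding_class` attributes; exon
#' coordinates are converted from the internal 0-based half-open
#' convention to 1-based closed GTF coordinates.
#'
#' @param locus A [LocusModel-class].
#' @param transcripts List of [TranscriptModel-class].
#' @param path Output GTF file.
#' @param codingClass Optional named character vector of coding classes
#'   keyed by transcript id.
#' @param geneId Gene attribute (default the locus contig).
#' @return Invisibly `path`.
#' @export
writeLocusGtf <- function(locus, transcripts, path, codingClass = NULL,
                          geneId = NULL) {
  if (is.null(geneId)) geneId <- locus@contig
  rows <- list()
  for (t in transcripts) {
    validateChain(locus, t)
    ivs <- lapply(t@chain, function(id) getExon(locus, id)@interval)
    st <- vapply(ivs, function(iv) iv@start + 1L, integer(1))
    en <- vapply(ivs, function(iv) iv@end, integer(1))
    cc <- if (!is.null(codingClass) && t@id %in% names(codingClass))
      codingClass[[t@id]] else NA_character_
    rows[[t@id]] <- data.frame(
      start = c(min(st), st), end = c(max(en), en),
      type = c("transcript", rep("exon", length(st))),
      transcript_id = t@id,
      isoform_name = ifelse(is.na(t@name), t@id, t@name),
      coding_class = cc, exon_number = c(NA, seq_along(st)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(locus@contig, IRanges(df$start, df$end), strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "ampliso"
  S4Vectors::mcols(gr)$gene_id <- geneId
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$isoform_name <- df$isoform_name
  if (!all(is.na(df$coding_class)))
    S4Vectors::mcols(gr)$coding_class <- df$coding_class
  S4Vectors::mcols(gr)$exon_number <- df$exon_number
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models back from a GTF
#'
#' Exon features are grouped by `transcript_id` and matched to locus exons
#' by exact coordinates, recovering the exon-id chains written by
#' [writeLocusGtf()].
#'
#' @param path GTF file.
#' @param locus The [LocusModel-class] the file refers to.
#' @return Named list of [TranscriptModel-class].
#' @export
readTranscriptsGtf <- function(path, locus) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  byStart <- vapply(locus@exons, function(e) e@interval@start + 1L,
                    integer(1))
  byEnd <- vapply(locus@exons, function(e) e@interval@end, integer(1))
  tids <- S4Vectors::mcols(gr)$transcript_id
  out <- list()
  for (tid in unique(tids)) {
    sel <- which(tids == tid)
    sel <- sel[order(BiocGenerics::start(gr)[sel])]
    chain <- vapply(sel, function(i) {
      hit <- which(byStart == BiocGenerics::start(gr)[i] &
                     byEnd == BiocGenerics::end(gr)[i])
      if (!length(hit))
        stop("GTF exon ", BiocGenerics::start(gr)[i], "-",
             BiocGenerics::end(gr)[i], " does not match any locus exon",
             call. = FALSE)
      names(locus@exons)[hit[1]]
    }, character(1))
    nm <- S4Vectors::mcols(gr)$isoform_name[sel[1]]
    out[[tid]] <- transcriptModel(tid, chain,
                                  name = if (is.null(nm)) NA_character_
                                         else nm)
  }
  out
}

#' Write spliced transcript sequences as FASTA
#'
#' @param locus A [LocusModel-class].
#' @param transcripts List of [TranscriptModel-class].
#' @param path Output FASTA.
#' @return Invisibly `path`.
#' @export
writeTranscriptsFasta <- function(locus, transcripts, path) {
  seqs <- DNAStringSet(lapply(transcripts, function(t)
    spliceTranscript(locus, t)))
  names(seqs) <- vapply(transcripts, function(t) t@id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write annotated peptides as protein FASTA
#'
#' @param annotations List of [CodingAnnotation-class] (noncoding entries
#'   are skipped).
#' @param path Output FASTA.
#' @return Invisibly `path`.
#' @export
writePeptidesFasta <- function(annotations, path) {
  annotations <- Filter(function(a) nzchar(a@peptide), annotations)
  seqs <- Biostrings::AAStringSet(vapply(annotations, function(a)
    a@peptide, character(1)))
  names(seqs) <- vapply(annotations, function(a)
    sprintf("%s coding_class=%s", a@transcriptId, a@codingClass),
    character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
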