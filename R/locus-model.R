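#' @importFrom BiocGenerics start end strand
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

## Domain roles recognised by the locus grammar. Every exon carries at least
## one; the EGF alpha and beta cassettes are distinct exons.
DOMAIN_ROLES <- c("NTERM_CLASS_VII", "SHARED_FIRSTEXON", "SPACER", "POISON",
                  "EGF_COMMON", "EGF_ALPHA", "EGF_BETA", "LINKER3_TERMINAL",
                  "TM2", "TAIL_A", "TAIL_B", "UTR")

#' Exon: a locus building block
#'
#' @slot id Accession-like exon label.
#' @slot interval A [GenomicInterval-class] giving its genomic placement.
#' @slot sequence Character DNA sequence over A/C/G/T; its length must equal
#'   the interval length.
#' @slot roles Character vector of domain roles (see `ampliso:::DOMAIN_ROLES`).
#' @slot phase Integer codon phase at which the exon is entered in its
#'   annotated (canonical) reading context: the number of nucleotides of the
#'   pending codon carried in from upstream exons. `NA` for pure-UTR exons.
#' @slot meta List of free-form metadata (e.g. `shared_offset` for a first
#'   exon split into a class-specific and a shared portion, or `variant_of`
#'   and `shift` for alternative-boundary variant exons).
#' @export
setClass("Exon",
         representation(id = "character", interval = "GenomicInterval",
                        sequence = "character", roles = "character",
                        phase = "integer", meta = "list"),
         prototype(phase = NA_integer_, meta = list()))

setValidity("Exon", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "exon id must be a single non-empty label")
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "exon sequence must be non-empty")
  else {
    if (grepl("[^ACGT]", object@sequence))
      msg <- c(msg, "exon sequence must be over {A,C,G,T}")
    if (nchar(object@sequence) != intervalLength(object@interval))
      msg <- c(msg, "sequence length must equal interval length")
  }
  if (length(object@roles) < 1L)
    msg <- c(msg, "every exon carries at least one role")
  if (!all(object@roles %in% DOMAIN_ROLES))
    msg <- c(msg, paste0("unknown roles: ",
                         paste(setdiff(object@roles, DOMAIN_ROLES),
                               collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an Exon
#'
#' @param id Exon label.
#' @param interval [GenomicInterval-class].
#' @param sequence DNA string (character); length must match the interval.
#' @param roles Character vector of domain roles.
#' @param phase Annotated entering codon phase (0, 1, 2) or `NA`.
#' @param meta Optional metadata list.
#' @return An [Exon-class].
#' @export
exon <- function(id, interval, sequence, roles, phase = NA, meta = list()) {
  new("Exon", id = id, interval = interval,
      sequence = toupper(as.character(sequence)),
      roles = roles, phase = as.integer(phase), meta = meta)
}

exonLength <- function(e) nchar(e@sequence)

#' @export
setMethod("show", "Exon", function(object) {
  cat(sprintf("Exon %s [%d bp] roles=%s phase=%s\n", object@id,
              exonLength(object), paste(object@roles, collapse = "+"),
              ifelse(is.na(object@phase), "NA", object@phase)))
})

#' LocusModel: an ordered, annotated exon collection
#'
#' The central reference object: exons ordered by genomic start on the
#' transcribed (+) strand, non-overlapping except for alternative-boundary
#' variant exons, plus a frame anchor `(exon id, 0-based offset)` marking a
#' position at which the canonical coding frame is 0 (a codon start).
#'
#' @slot contig Contig label the exon intervals refer to.
#' @slot exons Named list of [Exon-class] objects, ordered by interval start.
#' @slot frameAnchor List with elements `exon` (id) and `offset` (0-based
#'   offset within that exon of a canonical codon start).
#' @slot nameOverrides List mapping rendered nonstandard isoform names to
#'   exon-id chains (used for published names whose terminal exon composition
#'   is not resolvable from roles alone, e.g. a "ca" terminal).
#' @slot meta Free-form metadata list (e.g. primer coordinates).
#' @export
setClass("LocusModel",
         representation(contig = "character", exons = "list",
                        frameAnchor = "list", nameOverrides = "list",
                        meta = "list"),
         prototype(nameOverrides = list(), meta = list()))

setValidity("LocusModel", function(object) {
  msg <- character()
  if (!length(object@exons)) {
    msg <- c(msg, "locus must contain at least one exon")
    return(msg)
  }
  if (!all(vapply(object@exons, is, logical(1), "Exon")))
    msg <- c(msg, "exons must all be Exon objects")
  ids <- unname(vapply(object@exons, function(e) e@id, character(1)))
  if (anyDuplicated(ids)) msg <- c(msg, "exon ids must be unique")
  if (!identical(names(object@exons), ids))
    msg <- c(msg, "exon list must be named by exon id")
  starts <- vapply(object@exons, function(e) start(e@interval), integer(1))
  ## variant exons may overlap their parent; primary exons must be strictly
  ## increasing and non-overlapping
  primary <- vapply(object@exons,
                    function(e) is.null(e@meta$variant_of), logical(1))
  ps <- starts[primary]
  pe <- vapply(object@exons[primary], function(e) end(e@interval), integer(1))
  if (is.unsorted(ps, strictly = TRUE))
    msg <- c(msg, "primary exons must be strictly increasing by start")
  else if (any(head(pe, -1) > tail(ps, -1)))
    msg <- c(msg, "primary exons must not overlap")
  fa <- object@frameAnchor
  if (!all(c("exon", "offset") %in% names(fa)))
    msg <- c(msg, "frameAnchor must have elements 'exon' and 'offset'")
  else if (!fa$exon %in% ids)
    msg <- c(msg, "frameAnchor must refer to an existing exon")
  else if (fa$offset < 0 ||
           fa$offset >= exonLength(object@exons[[fa$exon]]))
    msg <- c(msg, "frameAnchor offset must fall inside its exon")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusModel
#'
#' @param contig Contig label.
#' @param exons List of [Exon-class] objects (will be ordered by start and
#'   named by id).
#' @param frameAnchor List `list(exon = <id>, offset = <0-based offset>)`.
#' @param nameOverrides Optional list mapping rendered names to exon chains.
#' @param meta Optional metadata list.
#' @return A [LocusModel-class].
#' @export
locusModel <- function(contig, exons, frameAnchor, nameOverrides = list(),
                       meta = list()) {
  ord <- order(vapply(exons, function(e) start(e@interval), integer(1)),
               vapply(exons, function(e) end(e@interval), integer(1)))
  exons <- exons[ord]
  names(exons) <- vapply(exons, function(e) e@id, character(1))
  frameAnchor$offset <- as.integer(frameAnchor$offset)
  new("LocusModel", contig = contig, exons = exons,
      frameAnchor = frameAnchor, nameOverrides = nameOverrides, meta = meta)
}

#' Exon identifiers of a locus
#'
#' @param x A [LocusModel-class] (ordered exon ids) or
#'   [TranscriptModel-class] (its chain).
#' @return Character vector of exon ids.
#' @name exonIds
#' @export
setMethod("exonIds", "LocusModel", function(x) names(x@exons))

#' Look up an exon by id
#'
#' @param locus A [LocusModel-class].
#' @param id Exon id.
#' @return The [Exon-class]; raises a chain-resolution error if absent.
#' @export
getExon <- function(locus, id) {
  e <- locus@exons[[id]]
  if (is.null(e))
    stop("chain-resolution error: unknown exon id '", id, "'", call. = FALSE)
  e
}

#' @export
setMethod("show", "LocusModel", function(object) {
  cat(sprintf("LocusModel on %s with %d exons\n", object@contig,
              length(object@exons)))
  for (e in object@exons)
    cat(sprintf("  %-10s %7d-%-7d %4d bp  phase=%-2s %s\n", e@id,
                start(e@interval), end(e@interval), exonLength(e),
                ifelse(is.na(e@phase), "NA", e@phase),
                paste(e@roles, collapse = "+")))
  cat(sprintf("  frame anchor: %s offset %d\n", object@frameAnchor$exon,
              object@frameAnchor$offset))
})

#' TranscriptModel: a named exon chain
#'
#' The unit of discovery and annotation: an ordered chain of locus exon ids
#' with a TSS offset into the first exon (0 for the fixture class-VII
#' transcripts) and optionally an isoform name.
#'
#' @slot id Transcript label.
#' @slot chain Character vector of exon ids, in locus order.
#' @slot tssOffset Integer 0-based offset into the first exon.
#' @slot name Rendered isoform name (`NA_character_` when unset).
#' @slot tag Simulation provenance tag: `"planted"`, `"low_abundance"`,
#'   `"decoy"` or `""`.
#' @export
setClass("TranscriptModel",
         representation(id = "character", chain = "character",
                        tssOffset = "integer", name = "character",
                        tag = "character"),
         prototype(tssOffset = 0L, name = NA_character_, tag = ""))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!length(object@chain)) msg <- c(msg, "chain must be non-empty")
  if (length(object@tssOffset) != 1L || is.na(object@tssOffset) ||
      object@tssOffset < 0L)
    msg <- c(msg, "tssOffset must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param id Transcript label.
#' @param chain Character vector of exon ids.
#' @param tssOffset 0-based offset into the first exon (default 0).
#' @param name Optional rendered isoform name.
#' @param tag Optional provenance tag.
#' @return A [TranscriptModel-class].
#' @export
transcriptModel <- function(id, chain, tssOffset = 0, name = NA_character_,
                            tag = "") {
  new("TranscriptModel", id = id, chain = as.character(chain),
      tssOffset = as.integer(tssOffset), name = name, tag = tag)
}

#' Exon chain of a transcript
#'
#' @param x A [TranscriptModel-class].
#' @return Character vector of exon ids.
#' @name exonChain
#' @export
setMethod("exonChain", "TranscriptModel", function(x) x@chain)

#' @rdname exonIds
#' @export
setMethod("exonIds", "TranscriptModel", function(x) x@chain)

#' @export
setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s%s: %s (tssOffset=%d)%s\n", object@id,
              ifelse(is.na(object@name), "", paste0(" [", object@name, "]")),
              paste(object@chain, collapse = " > "), object@tssOffset,
              ifelse(nzchar(object@tag), paste0(" <", object@tag, ">"), "")))
})

#' Check a transcript chain against a locus
#'
#' Verifies that every exon id resolves and that the chain follows the locus
#' genomic order (strictly increasing starts).
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateChain <- function(locus, transcript) {
  ex <- lapply(transcript@chain, function(id) getExon(locus, id))
  starts <- vapply(ex, function(e) start(e@interval), integer(1))
  if (is.unsorted(starts, strictly = TRUE))
    stop("chain '", transcript@id,
         "' is not strictly increasing in genomic start", call. = FALSE)
  if (transcript@tssOffset >= exonLength(ex[[1L]]))
    stop("tssOffset exceeds first exon of chain '", transcript@id, "'",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname spliceTranscript
#' @export
setMethod("spliceTranscript", c("LocusModel", "TranscriptModel"),
          function(locus, transcript) {
  validateChain(locus, transcript)
  seqs <- vapply(transcript@chain,
                 function(id) getExon(locus, id)@sequence, character(1))
  full <- paste0(seqs, collapse = "")
  DNAString(substr(full, transcript@tssOffset + 1L, nchar(full)))
})

## 1-based transcript coordinate of each exon start within a spliced chain,
## plus junction positions (transcript coordinate of the last base of each
## exon except the final one).
transcriptLayout <- function(locus, transcript) {
  lens <- vapply(transcript@chain,
                 function(id) exonLength(getExon(locus, id)), integer(1))
  lens[1L] <- lens[1L] - transcript@tssOffset
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(exon = transcript@chain, start = starts, end = ends,
       junctions = head(ends, -1L))
}

#' Transcript coordinate of the canonical frame anchor
#'
#' Propagates the locus frame anchor into 1-based transcript coordinates for
#' a chain containing the anchor exon.
#'
#' @param locus A [LocusModel-class].
#' @param transcript A [TranscriptModel-class].
#' @return 1-based transcript position that is a canonical codon start.
#' @export
transcriptFrameAnchor <- function(locus, transcript) {
  fa <- locus@frameAnchor
  idx <- match(fa$exon, transcript@chain)
  if (is.na(idx))
    stop("frame anchor exon '", fa$exon, "' not in chain '",
         transcript@id, "'", call. = FALSE)
  lay <- transcriptLayout(locus, transcript)
  pos <- lay$start[idx] + fa$offset -
    if (idx == 1L) transcript@tssOffset else 0L
  if (pos < 1L)
    stop("frame anchor lies upstream of the transcript start", call. = FALSE)
  as.integer(pos)
}
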