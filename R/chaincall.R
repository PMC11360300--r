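#' @importFrom data.table data.table := setorder rbindlist setnames .N .SD
NULL

## mismatch count of `primer` against `reads` at a fixed 1-based offset,
## plus the mismatch count restricted to the primer's 3'-terminal `tail3p`
## positions (ungapped comparison; vectorised across reads per position)
primerMismatch <- function(reads, primer, offset, tail3p = 5L,
                           tailAtStart = FALSE) {
  k <- nchar(primer)
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  total <- integer(length(reads))
  tail <- integer(length(reads))
  tailIdx <- if (tailAtStart) seq_len(tail3p) else (k - tail3p + 1L):k
  for (i in seq_len(k)) {
    mm <- substring(reads, offset + i - 1L, offset + i - 1L) != pc[i]
    total <- total + mm
    if (i %in% tailIdx) tail <- tail + mm
  }
  list(total = total, tail = tail)
}

## best (minimum-mismatch) anchored match of `primer` over small offsets;
## returns total and 3'-tail mismatches and the chosen offset per read
bestPrimerMatch <- function(reads, primer, offsets = 0:5, tail3p = 5L,
                            fromEnd = FALSE, tailAtStart = FALSE) {
  n <- length(reads)
  best <- rep.int(.Machine$integer.max, n)
  bestTail <- rep.int(.Machine$integer.max, n)
  bestOff <- rep.int(NA_integer_, n)
  k <- nchar(primer)
  lens <- nchar(reads)
  for (o in offsets) {
    start <- if (fromEnd) lens - o - k + 1L else rep.int(o + 1L, n)
    ok <- start >= 1L
    mm <- primerMismatch(reads, primer, pmax(start, 1L), tail3p,
                         tailAtStart)
    mm$total[!ok] <- .Machine$integer.max
    upd <- mm$total < best
    best[upd] <- mm$total[upd]
    bestTail[upd] <- mm$tail[upd]
    bestOff[upd] <- o
  }
  list(total = best, tail = bestTail, offset = bestOff)
}

#' Assign reads to amplicons and orient them
#'
#' A read is oriented by locating the shared forward primer (allowing up to
#' `maxMismatch` substitutions, none in the primer's 3'-terminal 5 nt)
#' at the start of the read or of its reverse complement. The amplicon is
#' then identified from the reverse-primer site at the read's 3' end under
#' the same rule; reads matching neither or both reverse primers are
#' rejected with a reason code.
#'
#' @param reads Data frame with at least `read_id` and `sequence` (the
#'   [simulateReads()] layout).
#' @param specs List of [ampliconSpec()] sharing one forward primer.
#' @param maxMismatch Maximum primer mismatches (default 2).
#' @return The input data frame with added columns `orientation`
#'   (`"+"`/`"-"`), `amplicon`, and `assign_reason` (`"pass"` or a
#'   rejection code); rejected rows have `amplicon = NA`. Sequences and
#'   qualities of `-` reads are reverse-complemented into forward
#'   orientation.
#' @export
assignAmplicons <- function(reads, specs, maxMismatch = 2L) {
  fwd <- unique(vapply(specs, `[[`, character(1), "forward"))
  if (length(fwd) != 1L)
    stop("amplicon specs must share one forward primer", call. = FALSE)
  seqs <- reads$sequence
  rcseqs <- as.character(reverseComplement(DNAStringSet(seqs)))
  fOk <- function(s) {
    m <- bestPrimerMatch(s, fwd)
    m$total <= maxMismatch & m$tail == 0L
  }
  plus <- fOk(seqs)
  minus <- fOk(rcseqs)
  orientation <- ifelse(plus, "+", ifelse(minus, "-", NA))
  oriented <- ifelse(!is.na(orientation) & orientation == "-", rcseqs, seqs)
  quality <- reads$quality
  if (!is.null(quality)) {
    flip <- !is.na(orientation) & orientation == "-"
    quality[flip] <- vapply(quality[flip], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1))
  }
  hitMat <- vapply(specs, function(sp) {
    site <- revCompChar(sp$reverse)
    m <- bestPrimerMatch(oriented, site, fromEnd = TRUE, tailAtStart = TRUE)
    m$total <= maxMismatch & m$tail == 0L
  }, logical(length(oriented)))
  if (is.null(dim(hitMat))) hitMat <- matrix(hitMat, nrow = 1L)
  nHit <- rowSums(hitMat)
  ampNames <- vapply(specs, `[[`, character(1), "name")
  amplicon <- ifelse(nHit == 1L, ampNames[max.col(hitMat, "first")],
                     NA_character_)
  reason <- rep.int("pass", length(oriented))
  reason[is.na(orientation)] <- "no_forward_primer"
  reason[!is.na(orientation) & nHit == 0L] <- "no_reverse_primer"
  reason[!is.na(orientation) & nHit > 1L] <- "ambiguous_amplicon"
  amplicon[reason != "pass"] <- NA_character_
  out <- reads
  out$sequence <- oriented
  if (!is.null(out$quality)) out$quality <- quality
  out$orientation <- orientation
  out$amplicon <- amplicon
  out$assign_reason <- reason
  out
}

## k-mer index over the primary (non-variant) exons of a locus; k-mers
## occurring in more than one exon are dropped as ambiguous seeds
buildExonIndex <- function(locus, k = 15L) {
  primary <- Filter(function(e) is.null(e@meta$variant_of), locus@exons)
  tabs <- lapply(primary, function(e) {
    n <- nchar(e@sequence)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table(kmer = substring(e@sequence, starts, starts + k - 1L),
               exon = e@id, expos = starts)
  })
  dt <- rbindlist(tabs)
  multi <- dt[, list(nex = length(unique(exon))), by = "kmer"]
  dt <- dt[dt$kmer %in% multi$kmer[multi$nex == 1L], ]
  pd <- Biostrings::PDict(DNAStringSet(dt$kmer))
  lens <- vapply(primary, exonLength, integer(1))
  names(lens) <- names(primary)
  list(k = k, table = dt, pdict = pd, exonLengths = lens)
}

## locate the amplicon reference for a called chain: spliced chain trimmed
## to the forward-primer start and the reverse-primer site end
chainReference <- function(locus, chain, spec) {
  t <- transcriptModel(paste(chain, collapse = "+"), chain)
  s <- as.character(spliceTranscript(locus, t))
  fpos <- regexpr(spec$forward, s, fixed = TRUE)[1]
  site <- revCompChar(spec$reverse)
  rpos <- regexpr(site, s, fixed = TRUE)[1]
  from <- if (fpos > 0) fpos else 1L
  to <- if (rpos > 0) rpos + nchar(site) - 1L else nchar(s)
  lay <- transcriptLayout(locus, t)
  list(sequence = substr(s, from, to), from = from, to = to, layout = lay)
}

#' Call exon chains for oriented reads
#'
#' The bespoke splice-aware matcher replacing a genome aligner at desk
#' scale: exact k-mer seeds on the primary exon sequences identify the
#' exons a read covers and their order; seed diagonals nearest each
#' junction measure the signed deviation (nt) of the read's junction from
#' the annotated exon boundary; a global-local alignment of the read
#' against the spliced chain reference yields the overall and per-exon
#' identities; full-length status requires both primer sites within 10 nt
#' of the read ends. Deterministic throughout.
#'
#' @param reads Data frame of assigned, forward-oriented reads (columns
#'   `read_id`, `sequence`, `amplicon`; optionally `quality`, `library`).
#' @param locus A [LocusModel-class].
#' @param specs Named list of [ampliconSpec()].
#' @param k Seed length (default 15).
#' @param minAnchors Minimum exact seeds for an exon to be called
#'   (default 2).
#' @param index Optional pre-built index from `ampliso:::buildExonIndex`.
#' @return Data frame (one row per read) with columns `read_id`, `chain`
#'   (`+`-collapsed exon ids; `NA` when unmapped), `offsets`
#'   (comma-collapsed signed junction deviations), `identity`,
#'   `exon_identity` (comma-collapsed), `full_length`, `mean_quality`,
#'   `amplicon`, `library`, `mapped`.
#' @export
callExonChains <- function(reads, locus, specs, k = 15L, minAnchors = 2L,
                           index = NULL) {
  if (is.null(index)) index <- buildExonIndex(locus, k)
  n <- nrow(reads)
  empty <- data.frame(read_id = character(), chain = character(),
                      offsets = character(), identity = numeric(),
                      exon_identity = character(), full_length = logical(),
                      mean_quality = numeric(), amplicon = character(),
                      library = character(), mapped = logical(),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  seqs <- reads$sequence
  lens <- nchar(seqs)
  bounds <- cumsum(lens + 1L)
  starts0 <- c(0L, head(bounds, -1L))          # read i occupies starts0+1..
  subject <- DNAString(paste0(seqs, collapse = "N"))
  m <- Biostrings::matchPDict(index$pdict, subject)
  nh <- S4Vectors::elementNROWS(m)
  hit <- data.table(pat = rep(seq_along(nh), nh),
                    pos = unlist(BiocGenerics::start(m), use.names = FALSE))
  hit$read <- findInterval(hit$pos - 1L, bounds) + 1L
  hit$rpos <- hit$pos - starts0[hit$read]
  hit$exon <- index$table$exon[hit$pat]
  hit$expos <- index$table$expos[hit$pat]
  hit$d <- hit$rpos - hit$expos

  occ <- hit[, list(nAnchor = .N,
                    dL = d[which.min(expos)],
                    dR = d[which.max(expos)],
                    med = as.numeric(stats::median(rpos))),
             by = c("read", "exon")]
  occ <- occ[occ$nAnchor >= minAnchors, ]
  setorder(occ, read, med)

  chains <- occ[, list(chain = paste(exon, collapse = "+"),
                       offsets = {
                         if (.N > 1L) {
                           lenA <- index$exonLengths[exon[-.N]]
                           paste(dL[-1L] - dR[-.N] - lenA, collapse = ",")
                         } else ""
                       }), by = "read"]

  out <- data.frame(read_id = reads$read_id, chain = NA_character_,
                    offsets = NA_character_, identity = NA_real_,
                    exon_identity = NA_character_, full_length = NA,
                    mean_quality = NA_real_,
                    amplicon = reads$amplicon,
                    library = if (is.null(reads$library)) NA_character_
                              else reads$library,
                    mapped = FALSE, stringsAsFactors = FALSE)
  out$chain[chains$read] <- chains$chain
  out$offsets[chains$read] <- chains$offsets
  out$mapped[chains$read] <- TRUE
  if (!is.null(reads$quality))
    out$mean_quality <- vapply(reads$quality, function(q)
      if (is.na(q) || !nzchar(q)) NA_real_ else mean(utf8ToInt(q) - 33),
      numeric(1), USE.NAMES = FALSE)

  ## identity + per-exon identity + full-length, per (chain, amplicon) group
  grp <- split(which(out$mapped),
               paste(out$chain[out$mapped], out$amplicon[out$mapped],
                     sep = "\r"))
  for (g in grp) {
    chain <- strsplit(out$chain[g[1]], "+", fixed = TRUE)[[1]]
    spec <- specs[[out$amplicon[g[1]]]]
    ref <- tryCatch(chainReference(locus, chain, spec),
                    error = function(e) NULL)
    if (is.null(ref)) {           # chain violates locus order: unmapped
      out$mapped[g] <- FALSE
      out$chain[g] <- NA_character_
      next
    }
    aln <- Biostrings::pairwiseAlignment(DNAStringSet(seqs[g]),
                                         DNAString(ref$sequence),
                                         type = "global-local")
    nm <- Biostrings::nmatch(aln)
    out$identity[g] <- nm / Biostrings::nchar(aln)
    out$exon_identity[g] <- perExonIdentity(aln, ref, length(chain), g)
    fm <- bestPrimerMatch(seqs[g], spec$forward, offsets = 0:10)
    site <- revCompChar(spec$reverse)
    rm_ <- bestPrimerMatch(seqs[g], site, offsets = 0:10, fromEnd = TRUE,
                           tailAtStart = TRUE)
    out$full_length[g] <- fm$total <= 4L & rm_$total <= 4L
  }
  out
}

## per-exon match identity from the vectorised PairwiseAlignments
## accessors: aligned subject columns per exon, minus mismatches and
## deleted bases, over columns plus inserted bases (insertions are
## attributed to the exon of their approximate subject position)
perExonIdentity <- function(aln, ref, nExon, g) {
  exonEnds <- ref$layout$end - ref$from + 1L
  exonStarts <- c(1L, head(exonEnds, -1L) + 1L)
  exonEnds[nExon] <- min(exonEnds[nExon], ref$to - ref$from + 1L)
  n <- length(g)
  sFrom <- BiocGenerics::start(Biostrings::subject(aln))
  sTo <- BiocGenerics::end(Biostrings::subject(aln))
  binOf <- function(pos) pmin(findInterval(pos - 1L, exonEnds) + 1L, nExon)
  tally <- function(id, pos) {
    m <- matrix(0L, n, nExon)
    if (length(id)) {
      b <- binOf(pos)
      dt <- data.table(id = id, b = b)[, list(k = .N), by = c("id", "b")]
      m[cbind(dt$id, dt$b)] <- dt$k
    }
    m
  }
  mmt <- Biostrings::mismatchTable(aln)
  mmM <- tally(mmt$PatternId, mmt$SubjectStart)
  dl <- Biostrings::deletion(Biostrings::indel(aln))
  dlN <- S4Vectors::elementNROWS(dl)
  dlId <- rep(seq_len(n), dlN)
  dlStart <- unlist(BiocGenerics::start(dl), use.names = FALSE)
  dlWidth <- unlist(BiocGenerics::width(dl), use.names = FALSE)
  delM <- tallyW(n, nExon, dlId, binOf(dlStart + sFrom[dlId] - 1L), dlWidth)
  il <- Biostrings::insertion(Biostrings::indel(aln))
  ilN <- S4Vectors::elementNROWS(il)
  ilId <- rep(seq_len(n), ilN)
  ilStart <- unlist(BiocGenerics::start(il), use.names = FALSE)
  ilWidth <- unlist(BiocGenerics::width(il), use.names = FALSE)
  insM <- tallyW(n, nExon, ilId,
                 binOf(pmin(ilStart + sFrom[ilId] - 1L,
                            exonEnds[nExon])), ilWidth)
  cols <- sapply(seq_len(nExon), function(e)
    pmax(0L, pmin(exonEnds[e], sTo) - pmax(exonStarts[e], sFrom) + 1L))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = n)
  ident <- (cols - mmM - delM) / (cols + insM)
  ident[cols == 0L] <- NA
  apply(round(ident, 4), 1, paste, collapse = ",")
}

tallyW <- function(n, nExon, id, b, w) {
  m <- matrix(0L, n, nExon)
  if (length(id)) {
    dt <- data.table(id = id, b = b, w = w)[, list(k = sum(w)),
                                            by = c("id", "b")]
    m[cbind(dt$id, dt$b)] <- dt$k
  }
  m
}
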