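#' Nanopore-like error model
#'
#' Per-base substitution/insertion/deletion rates, per-read junction-wobble
#' and truncation probabilities, and a mean Phred quality. The defaults are
#' nanopore-amplicon-like and deliberately pessimistic relative to modern
#' basecallers; they are configuration, not constants.
#'
#' @param substitution,insertion,deletion Per-base error probabilities.
#' @param junctionWobbleProb Per-read probability that one splice junction
#'   is shifted by up to `wobbleMaxShift` nt.
#' @param wobbleMaxShift Maximum junction shift in nt (>= 1).
#' @param truncationProb Per-read probability of truncation at one end.
#' @param meanQuality Mean Phred base quality of simulated reads.
#' @return An `error_model` list.
#' @export
errorModel <- function(substitution = 0.02, insertion = 0.01,
                       deletion = 0.01, junctionWobbleProb = 0.02,
                       wobbleMaxShift = 6L, truncationProb = 0.05,
                       meanQuality = 14) {
  rates <- c(substitution, insertion, deletion, junctionWobbleProb,
             truncationProb)
  if (any(rates < 0 | rates > 1))
    stop("error-model rates must lie in [0,1]", call. = FALSE)
  if (wobbleMaxShift < 1L)
    stop("wobbleMaxShift must be >= 1", call. = FALSE)
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion,
                 junctionWobbleProb = junctionWobbleProb,
                 wobbleMaxShift = as.integer(wobbleMaxShift),
                 truncationProb = truncationProb,
                 meanQuality = meanQuality),
            class = "error_model")
}

#' Library specification for the read simulator
#'
#' @param id Library label (e.g. `"monocyte"`, `"progenitor"`, `"imac"`).
#' @param depth Reads per amplicon.
#' @param fractions Named list, one element per amplicon name, each a named
#'   numeric vector of isoform fractions that must sum to 1 (decoys and
#'   sub-threshold isoforms are explicit entries).
#' @return A `library_spec` list.
#' @export
librarySpec <- function(id, depth, fractions) {
  if (depth < 0L) stop("depth must be >= 0", call. = FALSE)
  for (amp in names(fractions)) {
    f <- fractions[[amp]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-6)
      stop("fractions for amplicon '", amp,
           "' must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(id = id, depth = as.integer(depth), fractions = fractions),
            class = "library_spec")
}

#' Default three-library study design
#'
#' Mirrors the study's presence/absence layout: the two short isoforms in
#' every library; the poison-exon isoforms and the single long isoform in
#' monocytes; the full long-isoform complement in the iPSC-derived
#' progenitors and macrophages; beta-2b and P-alpha-2a planted at 2%
#' (sub-threshold); one single-library wobble decoy per amplicon at <= 2%.
#'
#' @param depth Reads per library per amplicon (default 2000).
#' @return Named list of [librarySpec()] objects.
#' @export
defaultLibrarySpecs <- function(depth = 2000L) {
  list(
    monocyte = librarySpec("monocyte", depth, list(
      short = c("VII-ab3" = 0.32, "VII-b3" = 0.28, "VII-Paca" = 0.21,
                "VII-Pb3" = 0.17, "decoy.b3.w3" = 0.02),
      long = c("VII-a2a" = 0.98, "VII-Pa2a" = 0.02))),
    progenitor = librarySpec("progenitor", depth, list(
      short = c("VII-ab3" = 0.55, "VII-b3" = 0.45),
      long = c("VII-a2a" = 0.25, "VII-a2b" = 0.24, "VII-b2a" = 0.23,
               "VII-ab2a" = 0.26, "VII-b2b" = 0.02))),
    imac = librarySpec("imac", depth, list(
      short = c("VII-ab3" = 0.52, "VII-b3" = 0.48),
      long = c("VII-a2a" = 0.34, "VII-a2b" = 0.32, "VII-b2a" = 0.30,
               "VII-b2b" = 0.02, "decoy.a2a.w4" = 0.02))))
}

mutateRead <- function(seq, err) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- runif(n) >= err$deletion
  chars <- chars[keep]
  n <- length(chars)
  if (!n) return("")
  sub <- which(runif(n) < err$substitution)
  if (length(sub)) {
    alt <- c("A", "C", "G", "T")
    repl <- vapply(chars[sub], function(b)
      sample(setdiff(alt, b), 1L), character(1))
    chars[sub] <- repl
  }
  ins <- which(runif(n) < err$insertion)
  if (length(ins)) {
    newb <- sample(c("A", "C", "G", "T"), length(ins), replace = TRUE)
    out <- character(n + length(ins))
    pos <- seq_len(n) + findInterval(seq_len(n), ins + 0.5)
    out[pos] <- chars
    out[setdiff(seq_len(n + length(ins)), pos)] <- newb
    chars <- out
  }
  paste0(chars, collapse = "")
}

applyWobble <- function(seq, junctions, err) {
  if (!length(junctions) || runif(1) >= err$junctionWobbleProb)
    return(seq)
  j <- if (length(junctions) == 1L) junctions else sample(junctions, 1L)
  w <- sample.int(err$wobbleMaxShift, 1L)
  if (runif(1) < 0.5) {
    ## insertion-type wobble: extra template bases at the junction
    paste0(substr(seq, 1, j),
           paste0(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = ""),
           substr(seq, j + 1L, nchar(seq)))
  } else {
    ## deletion-type wobble: junction placed w nt into the upstream exon
    keepTo <- max(j - w, 1L)
    paste0(substr(seq, 1, keepTo), substr(seq, j + 1L, nchar(seq)))
  }
}

applyTruncation <- function(seq, err) {
  if (runif(1) >= err$truncationProb) return(seq)
  n <- nchar(seq)
  cut <- ceiling(n * runif(1, 0.1, 0.6))
  if (runif(1) < 0.5) substr(seq, cut + 1L, n)    # 5' truncation
  else substr(seq, 1, n - cut)                    # 3' truncation
}

phredString <- function(len, meanQ) {
  q <- pmin(pmax(round(rnorm(len, meanQ, 3)), 2L), 41L)
  intToUtf8(q + 33L)
}

#' Simulate nanopore-like amplicon reads for one library
#'
#' Each read is a copy of the amplicon subsequence of one isoform drawn by
#' its planted fraction, optionally junction-wobbled, optionally truncated,
#' error-mutated per base, reverse-complemented with probability 0.5 and
#' given Phred qualities. Fully deterministic for a fixed seed; truth labels
#' are retained per read.
#'
#' @param locus A [LocusModel-class].
#' @param isoforms Named list of [TranscriptModel-class] (names must cover
#'   the library's fraction tables).
#' @param lib A [librarySpec()].
#' @param amplicons List of [ampliconSpec()] (e.g. [fixtureAmplicons()]).
#' @param err An [errorModel()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `read_id`, `sequence`, `quality`,
#'   `library`, `amplicon_truth`, `isoform_truth`.
#' @export
simulateReads <- function(locus, isoforms, lib, amplicons,
                          err = errorModel(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (spec in amplicons) {
      fr <- lib$fractions[[spec$name]]
      if (is.null(fr)) next
      missing <- setdiff(names(fr), names(isoforms))
      if (length(missing))
        stop("unknown isoforms in library spec: ",
             paste(missing, collapse = ", "), call. = FALSE)
      amps <- lapply(names(fr), function(nm)
        ampliconSequence(locus, isoforms[[nm]], spec))
      names(amps) <- names(fr)
      if (lib$depth == 0L) next
      draw <- sample(names(fr), lib$depth, replace = TRUE, prob = fr)
      seqs <- character(lib$depth)
      quals <- character(lib$depth)
      for (i in seq_len(lib$depth)) {
        a <- amps[[draw[i]]]
        s <- applyWobble(a$sequence, a$junctions, err)
        s <- applyTruncation(s, err)
        s <- mutateRead(s, err)
        if (runif(1) < 0.5) s <- revCompChar(s)
        seqs[i] <- s
        quals[i] <- phredString(nchar(s), err$meanQuality)
      }
      out[[spec$name]] <- data.frame(
        read_id = sprintf("%s_%s_r%05d", lib$id, spec$name,
                          seq_len(lib$depth)),
        sequence = seqs, quality = quals, library = lib$id,
        amplicon_truth = spec$name, isoform_truth = draw,
        stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' Truth labels are retained in the header after reserved tags
#' (`truth=`, `lib=`, `amp=`).
#'
#' @param reads Data frame from [simulateReads()].
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
writeReadsFastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s truth=%s lib=%s amp=%s", reads$read_id,
                         reads$isoform_truth, reads$library,
                         reads$amplicon_truth)
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ written by [writeReadsFastq()]
#'
#' @param path FASTQ file.
#' @return Data frame in the [simulateReads()] layout (truth columns are
#'   `NA` when the reserved tags are absent).
#' @export
readReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  hdr <- names(x)
  tag <- function(t) {
    m <- regmatches(hdr, regexec(paste0(t, "=(\\S+)"), hdr))
    vapply(m, function(g) if (length(g)) g[2] else NA_character_,
           character(1))
  }
  data.frame(read_id = sub(" .*", "", hdr),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             library = tag("lib"), amplicon_truth = tag("amp"),
             isoform_truth = tag("truth"), stringsAsFactors = FALSE)
}
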