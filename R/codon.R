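## Deterministic back-translation: one fixed codon per residue so that the
## golden fixture sequences are reproducible constants.
CODON_PREF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Back-translate a peptide with the package's fixed codon table
#'
#' Uses one deterministic codon per residue (the table is part of the
#' fixture definition, so golden sequences are stable across runs).
#'
#' @param peptide Character amino-acid string (standard one-letter code,
#'   no stops).
#' @return Character DNA string of length `3 * nchar(peptide)`.
#' @export
backTranslate <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  bad <- setdiff(aa, names(CODON_PREF))
  if (length(bad))
    stop("cannot back-translate residues: ", paste(bad, collapse = ","),
         call. = FALSE)
  paste0(CODON_PREF[aa], collapse = "")
}

## 1-based fresh codon start positions inside an exon entered at codon
## phase `p` (p = number of pending-codon nucleotides carried in from
## upstream): the first 3-p bases complete the pending codon, fresh codons
## start at 4-p and every 3 thereafter.
codonStartsAtPhase <- function(len, p) {
  first <- if (p == 0L) 1L else 4L - p
  if (first > len - 2L) return(integer(0))
  seq.int(first, len - 2L, by = 3L)
}

codonsAt <- function(seq, starts) {
  if (!length(starts)) return(character(0))
  substring(seq, starts, starts + 2L)
}

## Constrained random exon sequence generator.
##  - noStop: list of integer vectors; each vector is a set of codon-start
##    positions that must not spell a stop codon
##  - forcedStops: list of list(pos=, codon=) written into the sequence
##  - embed: list of list(pos=, seq=) fixed subsequences (primer sites,
##    boundary-variant extras)
##  - carryTail: number of trailing bases restricted to {A,C,G} so that
##    codons bridging into the next exon can never spell a stop (all stop
##    codons begin with T)
## Violating codons are repaired by targeted resampling; positions covered
## by forced stops or embeds are immutable, and an unsatisfiable constraint
## set raises a fixture-construction error.
makeConstrainedSeq <- function(len, noStop = list(), forcedStops = list(),
                               embed = list(), carryTail = 0L,
                               maxIter = 500L) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  fixed <- logical(len)
  for (em in embed) {
    idx <- em$pos + seq_len(nchar(em$seq)) - 1L
    if (max(idx) > len)
      stop("fixture-construction error: embed exceeds exon", call. = FALSE)
    s[idx] <- strsplit(em$seq, "")[[1]]
    fixed[idx] <- TRUE
  }
  for (fs in forcedStops) {
    idx <- fs$pos + 0:2
    if (max(idx) > len)
      stop("fixture-construction error: forced stop exceeds exon",
           call. = FALSE)
    if (any(fixed[idx]))
      stop("fixture-construction error: forced stop overlaps embed",
           call. = FALSE)
    s[idx] <- strsplit(fs$codon, "")[[1]]
    fixed[idx] <- TRUE
  }
  if (carryTail > 0L) {
    idx <- (len - carryTail + 1L):len
    free <- idx[!fixed[idx]]
    s[free] <- sample(c("A", "C", "G"), length(free), replace = TRUE)
    bad <- idx[fixed[idx] & s[idx] == "T"]
    if (length(bad))
      stop("fixture-construction error: carry tail fixed to T",
           call. = FALSE)
  }
  carryIdx <- if (carryTail > 0L) (len - carryTail + 1L):len else integer(0)
  for (iter in seq_len(maxIter)) {
    seqStr <- paste0(s, collapse = "")
    bad <- integer(0)
    for (starts in noStop) {
      hit <- starts[codonsAt(seqStr, starts) %in% STOP_CODONS]
      bad <- c(bad, hit)
    }
    if (!length(bad)) return(seqStr)
    for (p in unique(bad)) {
      idx <- p + 0:2
      free <- idx[!fixed[idx] & !(idx %in% carryIdx)]
      freeCarry <- idx[!fixed[idx] & idx %in% carryIdx]
      if (!length(free) && !length(freeCarry))
        stop("fixture-construction error: unsatisfiable stop constraint at ",
             p, call. = FALSE)
      if (length(free))
        s[free] <- sample(c("A", "C", "G", "T"), length(free),
                          replace = TRUE)
      if (length(freeCarry))
        s[freeCarry] <- sample(c("A", "C", "G"), length(freeCarry),
                               replace = TRUE)
    }
  }
  stop("fixture-construction error: constraint repair did not converge",
       call. = FALSE)
}

## Random UTR with no ATG in any frame (repaired in place); an optional
## embedded primer site is immutable.
makeUtrSeq <- function(len, embed = list(), maxIter = 500L) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  fixed <- logical(len)
  for (em in embed) {
    idx <- em$pos + seq_len(nchar(em$seq)) - 1L
    s[idx] <- strsplit(em$seq, "")[[1]]
    fixed[idx] <- TRUE
  }
  for (iter in seq_len(maxIter)) {
    seqStr <- paste0(s, collapse = "")
    hits <- gregexpr("ATG", seqStr, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(seqStr)
    for (p in hits) {
      idx <- (p + 0:2)[!fixed[p + 0:2]]
      if (!length(idx))
        stop("fixture-construction error: embedded sequence contains ATG",
             call. = FALSE)
      s[idx] <- sample(c("C", "G"), length(idx), replace = TRUE)
    }
  }
  stop("fixture-construction error: UTR repair did not converge",
       call. = FALSE)
}
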