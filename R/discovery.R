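#' Alignment-QC thresholds
#'
#' The discovery gates: overall identity strictly above `minIdentity`,
#' full-length primer recovery, fraction of junctions placed within
#' `junctionTol` nt strictly above `minJunctionAccuracy`, and mean base
#' quality of at least `minMeanQuality` (applied only when qualities are
#' present).
#'
#' @param minIdentity Minimum alignment identity (default 0.95, strict).
#' @param requireFullLength Require both primer sites near the read ends.
#' @param minJunctionAccuracy Minimum fraction of within-tolerance
#'   junctions (default 0.90, strict).
#' @param minMeanQuality Minimum mean Phred quality (default 10).
#' @param junctionTol Junction placement tolerance in nt (default 6).
#' @return A `qc_thresholds` list.
#' @export
qcThresholds <- function(minIdentity = 0.95, requireFullLength = TRUE,
                         minJunctionAccuracy = 0.90, minMeanQuality = 10,
                         junctionTol = 6L) {
  if (minIdentity <= 0 || minIdentity > 1 ||
      minJunctionAccuracy <= 0 || minJunctionAccuracy > 1)
    stop("QC fractions must lie in (0,1]", call. = FALSE)
  structure(list(minIdentity = minIdentity,
                 requireFullLength = requireFullLength,
                 minJunctionAccuracy = minJunctionAccuracy,
                 minMeanQuality = minMeanQuality,
                 junctionTol = as.integer(junctionTol)),
            class = "qc_thresholds")
}

parseOffsets <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Apply the alignment-QC gates to chain calls
#'
#' @param calls Data frame from [callExonChains()].
#' @param thr A [qcThresholds()] list.
#' @return `calls` with added columns `qc_pass` (logical) and `qc_reason`
#'   (`"pass"`, `"unmapped"`, `"identity"`, `"full_length"`, `"junctions"`
#'   or `"quality"`; the first failing gate is reported).
#' @export
qcFilter <- function(calls, thr = qcThresholds()) {
  offs <- parseOffsets(calls$offsets)
  jAcc <- vapply(offs, function(o)
    if (!length(o)) 1 else mean(abs(o) <= thr$junctionTol), numeric(1))
  reason <- rep.int("pass", nrow(calls))
  qualBad <- !is.na(calls$mean_quality) &
    calls$mean_quality < thr$minMeanQuality
  reason[qualBad] <- "quality"
  reason[jAcc <= thr$minJunctionAccuracy] <- "junctions"
  if (thr$requireFullLength)
    reason[!is.na(calls$full_length) & !calls$full_length] <- "full_length"
  reason[!is.na(calls$identity) &
           calls$identity <= thr$minIdentity] <- "identity"
  reason[!calls$mapped] <- "unmapped"
  calls$qc_pass <- reason == "pass"
  calls$qc_reason <- reason
  calls
}

## boundary-variant map of a locus: for each primary exon, the annotated
## variant exon ids and their 5'-boundary shifts
variantMap <- function(locus) {
  vs <- Filter(function(e) !is.null(e@meta$variant_of), locus@exons)
  if (!length(vs)) return(list())
  out <- list()
  for (e in vs) {
    p <- e@meta$variant_of
    out[[p]] <- rbind(out[[p]],
                      data.frame(id = e@id, shift = e@meta$shift,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Cluster chain calls and collapse junction wobble
#'
#' QC-passing reads are grouped by exon chain after snapping each junction
#' offset to the nearest annotated boundary within `wobbleTol` nt: the
#' primary exon boundary (offset 0) or an annotated boundary-variant exon,
#' in which case the chain is rewritten to that variant. Read-level random
#' wobble therefore merges into the majority chain, while systematically
#' shifted chains survive as distinct candidates; a candidate that differs
#' from a better-supported one only by such boundary-variant substitutions
#' and is detected in exactly one library is flagged as a likely
#' sequencing artifact.
#'
#' @param calls QC-passed calls (rows of [qcFilter()] output with
#'   `qc_pass`), carrying `library` and `amplicon` columns.
#' @param locus A [LocusModel-class].
#' @param wobbleTol Snap tolerance in nt (default 6).
#' @return List with `counts` (data frame: `chain`, `library`, `amplicon`,
#'   `count`) and `chains` (data frame: `chain`, `parent`, `wobble_minor`,
#'   `artifact`, `n_libraries`, `total`).
#' @export
clusterAndCollapse <- function(calls, locus, wobbleTol = 6L) {
  calls <- calls[calls$qc_pass & calls$mapped, , drop = FALSE]
  vmap <- variantMap(locus)
  snapChain <- function(chain, offs) {
    ids <- strsplit(chain, "+", fixed = TRUE)[[1]]
    if (length(offs) != length(ids) - 1L) return(chain)
    res <- offs
    for (j in seq_along(offs)) {
      into <- ids[j + 1L]
      targets <- data.frame(id = into, shift = 0L,
                            stringsAsFactors = FALSE)
      if (!is.null(vmap[[into]])) targets <- rbind(targets, vmap[[into]])
      dist <- abs(offs[j] - targets$shift)
      b <- which.min(dist)
      if (dist[b] <= wobbleTol) {
        ids[j + 1L] <- targets$id[b]
        res[j] <- 0L
      }
    }
    key <- paste(ids, collapse = "+")
    if (any(res != 0L))
      key <- paste0(key, "@", paste(res, collapse = ","))
    key
  }
  offs <- parseOffsets(calls$offsets)
  snapped <- vapply(seq_len(nrow(calls)), function(i)
    snapChain(calls$chain[i], offs[[i]]), character(1))
  dt <- data.table(chain = snapped, library = calls$library,
                   amplicon = calls$amplicon)
  counts <- dt[, list(count = .N), by = c("chain", "library", "amplicon")]
  info <- counts[, list(total = sum(count),
                        n_libraries = length(unique(library))),
                 by = "chain"]
  parentOf <- function(chain) {
    base <- sub("@.*$", "", chain)
    ids <- strsplit(base, "+", fixed = TRUE)[[1]]
    prim <- vapply(ids, function(id) {
      e <- locus@exons[[id]]
      if (!is.null(e) && !is.null(e@meta$variant_of)) e@meta$variant_of
      else id
    }, character(1))
    paste(prim, collapse = "+")
  }
  info$parent <- vapply(info$chain, parentOf, character(1))
  parentTotal <- info$total[match(info$parent, info$chain)]
  info$wobble_minor <- info$parent != info$chain &
    (is.na(parentTotal) | parentTotal >= info$total)
  info$artifact <- info$wobble_minor & info$n_libraries == 1L
  list(counts = as.data.frame(counts),
       chains = as.data.frame(info[, c("chain", "parent", "wobble_minor",
                                       "artifact", "n_libraries", "total")]))
}

#' Quantify candidates and apply the high-confidence fraction filter
#'
#' Fractions are computed per (library, amplicon) cell over the QC-passing
#' assigned reads of that cell (cells with zero reads are absent, not
#' zero). A candidate is `high_confidence` when it reaches `minFraction`
#' in at least one cell of either amplicon and is not artifact-flagged;
#' otherwise `low_abundance`.
#'
#' @param cands Output of [clusterAndCollapse()].
#' @param locus A [LocusModel-class] (used to name candidate chains).
#' @param minFraction High-confidence threshold (default 0.05, inclusive).
#' @return List with `fractions` (data frame: `chain`, `library`,
#'   `amplicon`, `count`, `fraction`) and `candidates` (data frame:
#'   `chain`, `name`, `status`, `max_fraction`, `n_libraries`, `total`,
#'   `wobble_minor`).
#' @export
quantifyAndFilter <- function(cands, locus, minFraction = 0.05) {
  counts <- data.table(cands$counts)
  counts[, `:=`(cellTotal = sum(count)), by = c("library", "amplicon")]
  counts$fraction <- counts$count / counts$cellTotal
  info <- cands$chains
  mf <- counts[, list(max_fraction = max(fraction)), by = "chain"]
  info$max_fraction <- mf$max_fraction[match(info$chain, mf$chain)]
  info$status <- ifelse(info$artifact, "artifact",
                        ifelse(!is.na(info$max_fraction) &
                                 info$max_fraction >= minFraction,
                               "high_confidence", "low_abundance"))
  info$name <- vapply(info$chain, function(ch) {
    if (grepl("@", ch, fixed = TRUE)) return(NA_character_)
    ids <- strsplit(ch, "+", fixed = TRUE)[[1]]
    hasVariant <- any(vapply(ids, function(id) {
      e <- locus@exons[[id]]
      !is.null(e) && !is.null(e@meta$variant_of)
    }, logical(1)))
    if (hasVariant) return(NA_character_)
    nm <- tryCatch(renderIsoformName(
      nameIsoform(locus, transcriptModel(ch, ids))), error = function(e)
        NA_character_)
    nm
  }, character(1))
  ord <- order(-info$total)
  list(fractions = as.data.frame(counts[, c("chain", "library", "amplicon",
                                            "count", "fraction")]),
       candidates = info[ord, c("chain", "name", "status", "max_fraction",
                                "n_libraries", "total", "wobble_minor")])
}
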