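#' GenomicInterval: a 0-based half-open interval on a contig
#'
#' Coordinates follow the 0-based half-open convention, so that a printed
#' pair such as chr8:32,676,084-32,676,195 spans exactly
#' `end - start = 111` bases.
#'
#' @slot contig Character contig label.
#' @slot start Integer, 0-based inclusive start.
#' @slot end Integer, exclusive end; must exceed `start`.
#' @slot strand Either `"+"` or `"-"`.
#' @export
setClass("GenomicInterval",
         representation(contig = "character", start = "integer",
                        end = "integer", strand = "character"),
         prototype(contig = "contig", start = 0L, end = 1L, strand = "+"))

setValidity("GenomicInterval", function(object) {
  msg <- character()
  if (length(object@contig) != 1L || !nzchar(object@contig))
    msg <- c(msg, "contig must be a single non-empty label")
  if (length(object@start) != 1L || length(object@end) != 1L ||
      is.na(object@start) || is.na(object@end))
    msg <- c(msg, "start and end must be single non-missing integers")
  else if (object@end <= object@start)
    msg <- c(msg, "invalid interval: end must be greater than start")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomicInterval
#'
#' @param contig Contig label.
#' @param start 0-based inclusive start.
#' @param end Exclusive end (`end > start`).
#' @param strand `"+"` (default) or `"-"`.
#' @return A [GenomicInterval-class].
#' @examples
#' iv <- genomicInterval("chr8", 32676084, 32676195)
#' intervalLength(iv)  # 111
#' @export
genomicInterval <- function(contig, start, end, strand = "+") {
  new("GenomicInterval", contig = as.character(contig),
      start = as.integer(start), end = as.integer(end),
      strand = as.character(strand))
}

#' @rdname intervalLength
#' @export
setMethod("intervalLength", "GenomicInterval", function(x) {
  validObject(x)
  x@end - x@start
})

#' @export
setMethod("show", "GenomicInterval", function(object) {
  cat(sprintf("GenomicInterval %s:%d-%d(%s) [%d bp]\n", object@contig,
              object@start, object@end, object@strand,
              intervalLength(object)))
})

#' @describeIn GenomicInterval 0-based start accessor
#' @param x,object A `GenomicInterval`.
#' @export
setMethod("start", "GenomicInterval", function(x) x@start)

#' @describeIn GenomicInterval exclusive end accessor
#' @export
setMethod("end", "GenomicInterval", function(x) x@end)

#' @describeIn GenomicInterval strand accessor
#' @export
setMethod("strand", "GenomicInterval", function(x) x@strand)
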