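#' IsoformName: the modular isoform nomenclature
#'
#' Names are composed of a class token (roman numeral; the fixture locus is
#' class VII), an optional poison-exon prefix `P`, an EGF token
#' (alpha, beta, alphabeta or none) and a terminal token (`3` for the
#' linker-3 terminal exon, `2a`/`2b` for transmembrane isoforms with the a or
#' b cytoplasmic tail, `ca` for the nonstandard published terminal).
#' Greek letters are stored as ASCII tokens and rendered as Unicode only in
#' `show()`; file outputs use the ASCII rendering (e.g. `VII-Pb3`,
#' `VII-ab3`, `VII-a2a`).
#'
#' @slot classToken Character, e.g. `"VII"`.
#' @slot poisonFlag Logical, `TRUE` when the chain contains the poison exon.
#' @slot egfToken One of `"alpha"`, `"beta"`, `"alphabeta"`, `"none"`.
#' @slot terminalToken One of `"3"`, `"2a"`, `"2b"`, `"ca"`.
#' @slot nonstandardTerminal Logical flag set for names realized through a
#'   locus name-override (no role-resolvable terminal exon).
#' @export
setClass("IsoformName",
         representation(classToken = "character", poisonFlag = "logical",
                        egfToken = "character", terminalToken = "character",
                        nonstandardTerminal = "logical"),
         prototype(classToken = "VII", poisonFlag = FALSE,
                   egfToken = "none", terminalToken = "3",
                   nonstandardTerminal = FALSE))

EGF_TOKENS <- c(none = "", alpha = "a", beta = "b", alphabeta = "ab")
TERMINAL_TOKENS <- c("3", "2a", "2b", "ca")

setValidity("IsoformName", function(object) {
  msg <- character()
  if (!grepl("^[IVX]+$", object@classToken))
    msg <- c(msg, "classToken must be a roman numeral")
  if (!object@egfToken %in% names(EGF_TOKENS))
    msg <- c(msg, "egfToken must be one of alpha/beta/alphabeta/none")
  if (!object@terminalToken %in% TERMINAL_TOKENS)
    msg <- c(msg, "terminalToken must be one of 3/2a/2b/ca")
  if (length(msg)) msg else TRUE
})

#' Construct an IsoformName
#'
#' @param classToken Roman-numeral class token (default `"VII"`).
#' @param poisonFlag Logical poison-exon flag.
#' @param egfToken `"alpha"`, `"beta"`, `"alphabeta"` or `"none"`.
#' @param terminalToken `"3"`, `"2a"`, `"2b"` or `"ca"`.
#' @param nonstandardTerminal Logical.
#' @return An [IsoformName-class].
#' @export
isoformName <- function(classToken = "VII", poisonFlag = FALSE,
                        egfToken = "none", terminalToken = "3",
                        nonstandardTerminal = FALSE) {
  new("IsoformName", classToken = classToken, poisonFlag = poisonFlag,
      egfToken = egfToken, terminalToken = terminalToken,
      nonstandardTerminal = nonstandardTerminal)
}

#' Render an isoform name to its ASCII form
#'
#' Rendering is deterministic: `class-token "-" ["P"] egf terminal`, e.g.
#' `VII-Pb3`, `VII-ab3`, `VII-a2a`, `VII-Paca`.
#'
#' @param n An [IsoformName-class].
#' @param unicode If `TRUE`, render the EGF token with Greek letters
#'   (report style); files always use the ASCII form.
#' @return Character rendering.
#' @export
renderIsoformName <- function(n, unicode = FALSE) {
  stopifnot(is(n, "IsoformName"))
  egf <- EGF_TOKENS[[n@egfToken]]
  if (unicode) {
    egf <- chartr("ab", "αβ", egf)
    term <- chartr("ab", "αβ", n@terminalToken)
  } else term <- n@terminalToken
  paste0(n@classToken, "-", if (n@poisonFlag) "P" else "", egf, term)
}

#' Parse an ASCII isoform name
#'
#' Inverse of [renderIsoformName()]: `parseIsoformName(renderIsoformName(n))`
#' reproduces `n` for every valid name.
#'
#' @param x Character such as `"VII-Pb3"`. Unicode Greek letters are accepted
#'   and normalised to ASCII tokens.
#' @return An [IsoformName-class].
#' @export
parseIsoformName <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("αβ", "ab", x)
  m <- regmatches(x, regexec("^([IVX]+)-(P?)(ab|a|b|)(3|2a|2b|ca)$", x))[[1]]
  if (!length(m))
    stop("cannot parse isoform name '", x, "'", call. = FALSE)
  egf <- names(EGF_TOKENS)[match(m[4], EGF_TOKENS)]
  isoformName(classToken = m[2], poisonFlag = m[3] == "P",
              egfToken = egf, terminalToken = m[5],
              nonstandardTerminal = m[5] == "ca")
}

#' @export
setMethod("show", "IsoformName", function(object) {
  cat("IsoformName", renderIsoformName(object, unicode = TRUE),
      sprintf("(ascii: %s)%s\n", renderIsoformName(object),
              if (object@nonstandardTerminal) " [nonstandard terminal]"
              else ""))
})

chainSignature <- function(chain) paste(chain, collapse = "+")

rolesOfChain <- function(locus, chain) {
  lapply(chain, function(id) getExon(locus, id)@roles)
}

#' @rdname nameIsoform
#' @export
setMethod("nameIsoform", c("LocusModel", "TranscriptModel"),
          function(locus, transcript) {
  validateChain(locus, transcript)
  chain <- transcript@chain
  ## published nonstandard names win over role-derived ones
  if (length(locus@nameOverrides)) {
    sig <- chainSignature(chain)
    hit <- vapply(locus@nameOverrides, function(ch)
      identical(chainSignature(ch), sig), logical(1))
    if (any(hit)) {
      n <- parseIsoformName(names(locus@nameOverrides)[which(hit)[1L]])
      n@nonstandardTerminal <- TRUE
      return(n)
    }
  }
  roles <- rolesOfChain(locus, chain)
  if (!"NTERM_CLASS_VII" %in% roles[[1L]])
    stop("chain does not start at the class-VII first exon", call. = FALSE)
  has <- function(role) any(vapply(roles, function(r) role %in% r,
                                   logical(1)))
  egf <- if (has("EGF_ALPHA") && has("EGF_BETA")) "alphabeta"
         else if (has("EGF_ALPHA")) "alpha"
         else if (has("EGF_BETA")) "beta" else "none"
  lastRoles <- roles[[length(roles)]]
  term <- if (has("TM2")) {
    if (has("TAIL_B")) "2b" else if (has("TAIL_A")) "2a" else NA
  } else if ("LINKER3_TERMINAL" %in% lastRoles) "3" else NA
  if (is.na(term))
    stop("unnameable chain: no terminal-role exon in '",
         transcript@id, "'", call. = FALSE)
  isoformName(classToken = "VII", poisonFlag = has("POISON"),
              egfToken = egf, terminalToken = term)
})

exonWithRoles <- function(locus, required, excluded = character()) {
  hit <- Filter(function(e)
    is.null(e@meta$variant_of) && all(required %in% e@roles) &&
      !any(excluded %in% e@roles), locus@exons)
  if (!length(hit))
    stop("unsupported name: locus has no exon with roles ",
         paste(required, collapse = "+"), call. = FALSE)
  hit[[1L]]@id
}

#' @rdname chainFromName
#' @export
setMethod("chainFromName", c("LocusModel", "IsoformName"),
          function(locus, name) {
  validObject(name)
  rendered <- renderIsoformName(name)
  if (!is.null(locus@nameOverrides[[rendered]])) {
    return(transcriptModel(id = rendered,
                           chain = locus@nameOverrides[[rendered]],
                           name = rendered, tag = "nonstandard-terminal"))
  }
  if (name@terminalToken == "ca")
    stop("unsupported name '", rendered,
         "': terminal token 'ca' has no matching exon in this locus",
         call. = FALSE)
  chain <- exonWithRoles(locus, "NTERM_CLASS_VII")
  chain <- c(chain, exonWithRoles(locus, "SPACER"))
  if (name@poisonFlag) chain <- c(chain, exonWithRoles(locus, "POISON"))
  if (name@egfToken != "none") {
    chain <- c(chain, exonWithRoles(locus, "EGF_COMMON"))
    if (name@egfToken %in% c("alpha", "alphabeta"))
      chain <- c(chain, exonWithRoles(locus, "EGF_ALPHA"))
    if (name@egfToken %in% c("beta", "alphabeta"))
      chain <- c(chain, exonWithRoles(locus, "EGF_BETA"))
  }
  chain <- switch(name@terminalToken,
    "3"  = c(chain, exonWithRoles(locus, "LINKER3_TERMINAL")),
    "2a" = c(chain, exonWithRoles(locus, "TM2"),
             exonWithRoles(locus, "TAIL_A")),
    "2b" = c(chain, exonWithRoles(locus, "TM2"),
             exonWithRoles(locus, "TAIL_B"),
             exonWithRoles(locus, "TAIL_A")))
  t <- transcriptModel(id = rendered, chain = chain, name = rendered)
  validateChain(locus, t)
  t
})

#' @rdname chainFromName
#' @export
setMethod("chainFromName", c("LocusModel", "character"),
          function(locus, name) chainFromName(locus, parseIsoformName(name)))
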