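#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the single top-level seed (all
#' stage seeds are derived from it), the fixture configuration, error
#' model, library design, QC thresholds, the high-confidence fraction
#' threshold, the wobble snap tolerance, the NMD rule distance and the
#' reference catalogue count.
#'
#' @param seed Top-level integer seed.
#' @param fixture A [fixtureConfig()].
#' @param error An [errorModel()].
#' @param libraries Named list of [librarySpec()]
#'   (default [defaultLibrarySpecs()]).
#' @param qc A [qcThresholds()].
#' @param minFraction High-confidence threshold (default 0.05).
#' @param wobbleTol Junction snap tolerance, nt (default 6).
#' @param nmdRuleDistance NMD rule distance, nt (default 50).
#' @param referenceCodingCount Reference coding isoform count (default 28).
#' @param outputDir Optional output directory for [writePipelineOutputs()].
#' @return A `pipeline_config` list.
#' @export
pipelineConfig <- function(seed = 1L, fixture = fixtureConfig(),
                           error = errorModel(),
                           libraries = defaultLibrarySpecs(),
                           qc = qcThresholds(), minFraction = 0.05,
                           wobbleTol = 6L, nmdRuleDistance = 50L,
                           referenceCodingCount = 28L, outputDir = NULL) {
  structure(list(seed = as.integer(seed), fixture = fixture, error = error,
                 libraries = libraries, qc = qc,
                 minFraction = minFraction,
                 wobbleTol = as.integer(wobbleTol),
                 nmdRuleDistance = as.integer(nmdRuleDistance),
                 referenceCodingCount = as.integer(referenceCodingCount),
                 outputDir = outputDir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML round trip)
#'
#' @param cfg A [pipelineConfig()].
#' @param path YAML file.
#' @return `savePipelineConfig` invisibly returns `path`;
#'   `loadPipelineConfig` returns the reconstructed `pipeline_config`,
#'   identical to the saved one.
#' @export
savePipelineConfig <- function(cfg, path) {
  x <- list(seed = cfg$seed, fixture = unclass(cfg$fixture),
            error = unclass(cfg$error),
            libraries = lapply(cfg$libraries, function(l)
              list(id = l$id, depth = l$depth,
                   fractions = lapply(l$fractions, as.list))),
            qc = unclass(cfg$qc), minFraction = cfg$minFraction,
            wobbleTol = cfg$wobbleTol,
            nmdRuleDistance = cfg$nmdRuleDistance,
            referenceCodingCount = cfg$referenceCodingCount,
            outputDir = cfg$outputDir)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname savePipelineConfig
#' @export
loadPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  libs <- lapply(x$libraries, function(l)
    librarySpec(l$id, l$depth, lapply(l$fractions, unlist)))
  names(libs) <- vapply(libs, `[[`, character(1), "id")
  pipelineConfig(seed = x$seed, fixture = do.call(fixtureConfig, x$fixture),
                 error = do.call(errorModel, x$error), libraries = libs,
                 qc = do.call(qcThresholds, x$qc),
                 minFraction = x$minFraction, wobbleTol = x$wobbleTol,
                 nmdRuleDistance = x$nmdRuleDistance,
                 referenceCodingCount = x$referenceCodingCount,
                 outputDir = x$outputDir)
}

pipelineLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end discovery pipeline
#'
#' simulate -> assign -> call -> QC -> cluster -> filter -> annotate ->
#' catalogue -> report, fully deterministic per seed. Stage errors abort
#' with a stage-tagged condition.
#'
#' @param cfg A [pipelineConfig()].
#' @param quiet Suppress stage logging (default `TRUE`).
#' @return A `pipeline_result` list with elements `locus`, `isoforms`,
#'   `reads`, `assigned`, `calls`, `clusters`, `quant`, `annotations`
#'   (data frame), `peptides` (list of [CodingAnnotation-class]),
#'   `catalogue`, `report` and `config`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), quiet = TRUE) {
  log_ <- if (quiet) function(...) invisible() else pipelineLog
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  locus <- stage("fixture", buildFixtureLocus(cfg$fixture))
  isoforms <- stage("fixture", buildFixtureIsoforms(locus))
  amplicons <- stage("fixture", fixtureAmplicons(locus))
  log_("fixture", "%d exons, %d isoform models", length(locus@exons),
       length(isoforms))

  reads <- stage("simulate", {
    parts <- lapply(seq_along(cfg$libraries), function(i)
      simulateReads(locus, isoforms, cfg$libraries[[i]], amplicons,
                    cfg$error, seed = cfg$seed + 101L * i))
    parts <- Filter(Negate(is.null), parts)
    if (!length(parts)) NULL
    else do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  log_("simulate", "%d reads", if (is.null(reads)) 0L else nrow(reads))

  if (is.null(reads) || !nrow(reads)) {
    cat28 <- isoformCatalogue(cfg$referenceCodingCount)
    report <- list(reads_in = 0L, assigned = 0L, qc_passed = 0L,
                   candidates = 0L, high_confidence = 0L, coding = 0L,
                   nmd_candidates = 0L,
                   catalogue_total = catalogueTotal(cat28),
                   seed = cfg$seed,
                   version = as.character(packageVersion("ampliso")))
    return(structure(list(locus = locus, isoforms = isoforms,
                          reads = reads, assigned = NULL, calls = NULL,
                          clusters = NULL,
                          quant = list(fractions = NULL, candidates = NULL),
                          annotations = NULL, peptides = list(),
                          catalogue = cat28, report = report,
                          config = cfg), class = "pipeline_result"))
  }

  assigned <- stage("assign", assignAmplicons(reads, amplicons))
  ok <- assigned[assigned$assign_reason == "pass", , drop = FALSE]
  log_("assign", "%d/%d assigned", nrow(ok), nrow(assigned))

  calls <- stage("call", callExonChains(ok, locus, amplicons))
  calls <- stage("qc", qcFilter(calls, cfg$qc))
  log_("qc", "%d/%d pass", sum(calls$qc_pass), nrow(calls))

  clusters <- stage("cluster",
                    clusterAndCollapse(calls, locus, cfg$wobbleTol))
  quant <- stage("filter",
                 quantifyAndFilter(clusters, locus, cfg$minFraction))
  hc <- quant$candidates[quant$candidates$status == "high_confidence", ,
                         drop = FALSE]
  log_("filter", "%d candidates, %d high-confidence",
       nrow(quant$candidates), nrow(hc))

  annTab <- NULL
  peptides <- list()
  if (nrow(hc)) {
    annTab <- stage("annotate", {
      rows <- lapply(seq_len(nrow(hc)), function(i) {
        ids <- strsplit(hc$chain[i], "+", fixed = TRUE)[[1]]
        t <- transcriptModel(ifelse(is.na(hc$name[i]), hc$chain[i],
                                    hc$name[i]), ids,
                             name = hc$name[i])
        ann <- translateChain(locus, t)
        ann <- classifyNmd(locus, t, ann, cfg$nmdRuleDistance)
        dom <- if (nzchar(ann@peptide)) annotateDomains(locus, t, ann)
               else NULL
        peptides[[t@id]] <<- ann
        data.frame(chain = hc$chain[i], name = hc$name[i],
                   coding_class = ann@codingClass,
                   atg = ann@atgPosition, stop = ann@stopPosition,
                   peptide_length = nchar(ann@peptide),
                   frame_shift_exons = paste(ann@frameShiftExons,
                                             collapse = ","),
                   tm_present = isTRUE(attr(dom, "tm_present")),
                   secreted = isTRUE(attr(dom, "secreted")),
                   domains = if (is.null(dom)) "" else
                     paste(sprintf("%s:%d-%d", dom$role, dom$aa_start,
                                   dom$aa_end), collapse = ";"),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  codingNames <- annTab$name[!is.na(annTab$name) &
                               annTab$coding_class == "coding"]
  catalogue <- stage("catalogue",
    updateCatalogue(isoformCatalogue(cfg$referenceCodingCount),
                    codingNames, rep("coding", length(codingNames))))
  report <- list(
    reads_in = nrow(reads), assigned = nrow(ok),
    qc_passed = sum(calls$qc_pass),
    candidates = nrow(quant$candidates), high_confidence = nrow(hc),
    coding = sum(annTab$coding_class == "coding"),
    nmd_candidates = sum(annTab$coding_class == "NMD_candidate"),
    catalogue_total = catalogueTotal(catalogue), seed = cfg$seed,
    version = as.character(packageVersion("ampliso")))
  structure(list(locus = locus, isoforms = isoforms, reads = reads,
                 assigned = assigned, calls = calls, clusters = clusters,
                 quant = quant, annotations = annTab, peptides = peptides,
                 catalogue = catalogue, report = report, config = cfg),
            class = "pipeline_result")
}

#' Write all pipeline outputs to a directory
#'
#' FASTQ (simulated reads), FASTA (spliced fixture transcripts), protein
#' FASTA (annotated peptides), GTF (high-confidence isoform models), TSV
#' (candidate fractions, annotations), JSON (run report) and YAML
#' (resolved configuration).
#'
#' @param result A `pipeline_result` from [runPipeline()].
#' @param dir Output directory (created if needed; defaults to the
#'   config's `outputDir`).
#' @return Invisibly the directory path.
#' @export
writePipelineOutputs <- function(result, dir = NULL) {
  if (is.null(dir)) dir <- result$config$outputDir
  if (is.null(dir)) stop("no output directory given", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  if (!is.null(result$reads) && nrow(result$reads))
    writeReadsFastq(result$reads, p("reads.fastq"))
  planted <- Filter(function(t) t@tag != "decoy", result$isoforms)
  writeTranscriptsFasta(result$locus, planted, p("fixture_transcripts.fa"))
  if (length(result$peptides))
    writePeptidesFasta(result$peptides, p("peptides.faa"))
  if (!is.null(result$annotations) && nrow(result$annotations)) {
    hcModels <- lapply(seq_len(nrow(result$annotations)), function(i) {
      ids <- strsplit(result$annotations$chain[i], "+", fixed = TRUE)[[1]]
      nm <- result$annotations$name[i]
      transcriptModel(ifelse(is.na(nm), result$annotations$chain[i], nm),
                      ids, name = nm)
    })
    cc <- setNames(result$annotations$coding_class,
                   vapply(hcModels, function(t) t@id, character(1)))
    writeLocusGtf(result$locus, hcModels, p("high_confidence.gtf"),
                  codingClass = cc)
    write.table(result$annotations, p("annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$quant$fractions))
    write.table(result$quant$fractions, p("candidate_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$quant$candidates))
    write.table(result$quant$candidates, p("candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$report, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  savePipelineConfig(result$config, p("config.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("ampliso pipeline result (seed", r$seed, ")\n")
  cat(sprintf("  reads %d -> assigned %d -> QC %d -> candidates %d -> high-confidence %d\n",
              r$reads_in, r$assigned, r$qc_passed, r$candidates,
              r$high_confidence))
  cat(sprintf("  coding %d, NMD candidates %d, catalogue total %d\n",
              r$coding, r$nmd_candidates, r$catalogue_total))
  invisible(x)
}
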