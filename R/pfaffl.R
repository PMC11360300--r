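#' qPCR dilution-series simulation configuration
#'
#' @param efficiency True per-cycle amplification factor E in (1, 2]
#'   (2.0 = 100% efficiency).
#' @param dilutionLog10 Log10 template concentrations (>= 3 points).
#' @param ctNoiseSd Gaussian CT noise, cycles.
#' @param baselineCt CT at log10 concentration 0.
#' @param seed Integer seed.
#' @param primerPair Primer-pair label.
#' @return A `qpcr_sim_config` list.
#' @export
qpcrSimConfig <- function(efficiency = 1.96, dilutionLog10 = 0:-4,
                          ctNoiseSd = 0, baselineCt = 18, seed = 1L,
                          primerPair = "GOI") {
  if (efficiency <= 1 || efficiency > 2)
    stop("invalid-efficiency error: E must lie in (1, 2]", call. = FALSE)
  if (length(dilutionLog10) < 3L)
    stop("a dilution series needs at least 3 points", call. = FALSE)
  structure(list(efficiency = efficiency,
                 dilutionLog10 = as.numeric(dilutionLog10),
                 ctNoiseSd = ctNoiseSd, baselineCt = baselineCt,
                 seed = as.integer(seed), primerPair = primerPair),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR dilution series
#'
#' CT decreases by `1/log10(E)` cycles per 10-fold concentration increase
#' (3.32 cycles for E = 2), plus optional Gaussian noise; deterministic per
#' seed.
#'
#' @param cfg A [qpcrSimConfig()].
#' @return A `dilution_series` data frame with columns `primer_pair`,
#'   `log10_concentration`, `ct`.
#' @export
simulateDilutionSeries <- function(cfg = qpcrSimConfig()) {
  withr::with_seed(cfg$seed, {
    slope <- -1 / log10(cfg$efficiency)
    ct <- cfg$baselineCt + slope * cfg$dilutionLog10 +
      rnorm(length(cfg$dilutionLog10), 0, cfg$ctNoiseSd)
    structure(data.frame(primer_pair = cfg$primerPair,
                         log10_concentration = cfg$dilutionLog10,
                         ct = ct, stringsAsFactors = FALSE),
              class = c("dilution_series", "data.frame"))
  })
}

#' Fit primer efficiency from a dilution series
#'
#' Least-squares fit of CT against log10 concentration;
#' `E = 10^(-1/slope)`, percent efficiency `(E - 1) * 100`.
#'
#' @param series Data frame with columns `log10_concentration` and `ct`
#'   (e.g. from [simulateDilutionSeries()]).
#' @return An `efficiency_estimate` list with elements `E`, `percent`,
#'   `slope`, `r_squared`, `primer_pair`.
#' @export
fitPrimerEfficiency <- function(series) {
  if (nrow(series) < 3L)
    stop("a dilution series needs at least 3 points", call. = FALSE)
  if (any(!is.finite(series$ct)))
    stop("CT values must be finite", call. = FALSE)
  fit <- lm(ct ~ log10_concentration, data = series)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("implausible-series error: CT must decrease with concentration",
         call. = FALSE)
  E <- 10^(-1 / slope)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series fit
  structure(list(E = E, percent = (E - 1) * 100, slope = slope,
                 r_squared = r2,
                 primer_pair = if (is.null(series$primer_pair)) NA_character_
                               else series$primer_pair[1]),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("Primer efficiency %s: E = %.4f (%.1f%%), slope %.3f, r2 %.4f\n",
              x$primer_pair, x$E, x$percent, x$slope, x$r_squared))
  invisible(x)
}

#' Expression measurement for one gene of interest in one sample
#'
#' Technical replicates (n = 3 in the study) are summarised by their mean
#' CT. Undetected targets are represented as missing CTs, never as CT 40
#' or ratio 0.
#'
#' @param goi Gene-of-interest label (e.g. an isoform class).
#' @param hkg Housekeeping-gene label (B2M in the study).
#' @param eGoi,eHkg Amplification factors in (1, 2].
#' @param ctGoi,ctHkg Numeric CT replicate vectors (`NA` = undetected).
#' @param sample Sample label.
#' @return An `expression_measurement` list; `undetected` is `TRUE` when
#'   all GOI CTs are missing.
#' @export
expressionMeasurement <- function(goi, hkg, eGoi, eHkg, ctGoi, ctHkg,
                                  sample = NA_character_) {
  for (E in c(eGoi, eHkg))
    if (!is.finite(E) || E <= 1 || E > 2)
      stop("invalid-efficiency error: E must lie in (1, 2]", call. = FALSE)
  structure(list(goi = goi, hkg = hkg, eGoi = eGoi, eHkg = eHkg,
                 ctGoi = mean(ctGoi, na.rm = TRUE),
                 ctHkg = mean(ctHkg, na.rm = TRUE),
                 undetected = all(is.na(ctGoi)), sample = sample),
            class = "expression_measurement")
}

#' Efficiency-corrected relative expression (single sample)
#'
#' The ratio `E_hkg^CT_hkg / E_goi^CT_goi`: expression of the gene of
#' interest relative to the housekeeping gene, corrected for both primer
#' efficiencies, strictly decreasing in the GOI CT and increasing in the
#' HKG CT.
#'
#' @param m An [expressionMeasurement()].
#' @return Numeric ratio, or `NA` with attribute `undetected = TRUE` when
#'   the target was not detected.
#' @export
relativeExpression <- function(m) {
  stopifnot(inherits(m, "expression_measurement"))
  if (m$undetected || is.na(m$ctHkg))
    return(structure(NA_real_, undetected = TRUE))
  m$eHkg^m$ctHkg / m$eGoi^m$ctGoi
}

#' Efficiency-corrected comparative expression between two samples
#'
#' With `dCT = CT(sample1) - CT(sample2)` for each primer pair, the ratio
#' is `E_goi^(-dCT_goi) / E_hkg^(-dCT_hkg)`; under equal efficiencies this
#' reduces to the classic `2^-ddCT` form.
#'
#' @param m1,m2 [expressionMeasurement()] objects for the same primer
#'   pairs in two samples.
#' @return Numeric ratio of sample 1 relative to sample 2, or `NA` with
#'   attribute `undetected` when either GOI was not detected.
#' @export
comparativeExpression <- function(m1, m2) {
  stopifnot(inherits(m1, "expression_measurement"),
            inherits(m2, "expression_measurement"))
  if (!identical(m1$goi, m2$goi) || !identical(m1$hkg, m2$hkg) ||
      !isTRUE(all.equal(m1$eGoi, m2$eGoi)) ||
      !isTRUE(all.equal(m1$eHkg, m2$eHkg)))
    stop("comparison error: measurements use different primer pairs",
         call. = FALSE)
  if (m1$undetected || m2$undetected)
    return(structure(NA_real_, undetected = TRUE))
  dGoi <- m1$ctGoi - m2$ctGoi
  dHkg <- m1$ctHkg - m2$ctHkg
  m1$eGoi^(-dGoi) / m1$eHkg^(-dHkg)
}

#' Read a CT table
#'
#' @param path TSV with columns `sample`, `primer_pair`, `replicate`,
#'   `ct` (empty or NA = undetected).
#' @return Data frame.
#' @export
readCtTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "primer_pair", "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("CT table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  x$ct <- suppressWarnings(as.numeric(x$ct))
  x
}

#' Relative-expression matrix from a CT table
#'
#' Builds the class-by-sample ratio matrix: for every sample and gene of
#' interest, the efficiency-corrected ratio against the housekeeping gene.
#'
#' @param cts CT table ([readCtTable()] layout).
#' @param efficiencies Named numeric vector of amplification factors per
#'   primer pair (must cover every primer pair present).
#' @param hkg Housekeeping primer-pair label (default `"B2M"`).
#' @return Data frame: `sample`, `primer_pair`, `ratio`, `undetected`.
#' @export
relativeExpressionTable <- function(cts, efficiencies, hkg = "B2M") {
  gois <- setdiff(unique(cts$primer_pair), hkg)
  miss <- setdiff(c(gois, hkg), names(efficiencies))
  if (length(miss))
    stop("missing efficiencies for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (s in unique(cts$sample)) {
    ctH <- cts$ct[cts$sample == s & cts$primer_pair == hkg]
    for (g in gois) {
      ctG <- cts$ct[cts$sample == s & cts$primer_pair == g]
      m <- expressionMeasurement(g, hkg, efficiencies[[g]],
                                 efficiencies[[hkg]], ctG, ctH, sample = s)
      r <- relativeExpression(m)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, primer_pair = g, ratio = as.numeric(r),
        undetected = isTRUE(attr(r, "undetected")),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
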