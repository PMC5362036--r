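#' @include AllClasses.R measure.R simulate.R
NULL

.isFlagged <- function(measurements) {
  nzchar(measurements$flags) | is.na(measurements$ratio)
}

#' Summarize a measured cohort at a threshold
#'
#' Counts membrane-associated and cytosolic cells among the unflagged
#' measurements and forms the membrane-associated fraction (the pie-chart
#' statistic). Flagged cells (too thin, border-touching, saturated,
#' undefined ratio) are counted as excluded and do not enter the
#' fraction's denominator.
#'
#' @param measurements data.frame from [measureCells()].
#' @param threshold classification threshold (cells are re-classified at
#'   this threshold, so a cohort can be summarized at several thresholds).
#' @return A [PopulationSummary-class].
#' @export
summarizePopulation <- function(measurements, threshold = 0.7) {
  excl <- .isFlagged(measurements)
  valid <- measurements[!excl, , drop = FALSE]
  if (nrow(valid) == 0L)
    .mlErr("no_valid_cells", "every cell is flagged or unmeasurable")
  cls <- classifyRatio(valid$ratio, threshold)
  nm <- sum(cls == "membrane")
  ncy <- sum(cls == "cytosolic")
  new("PopulationSummary", nTotal = nrow(measurements),
      nMembrane = as.integer(nm), nCytosolic = as.integer(ncy),
      nExcluded = as.integer(sum(excl)),
      fractionMembrane = nm / (nm + ncy), threshold = threshold)
}

#' Calibrate the classification threshold on control populations
#'
#' Evaluates misclassification of a cytosolic-control cohort (soluble
#' fluorophore; should classify cytosolic) and a membrane-control cohort
#' (membrane dye; should classify membrane-associated) at the given
#' threshold, and searches the observed ratio values for the candidate
#' threshold minimizing the total misclassification count (ties resolved
#' to the smallest candidate).
#'
#' @param cytosolicControl numeric ratios of the cytosolic-control cells.
#' @param membraneControl numeric ratios of the membrane-control cells.
#' @param threshold threshold to evaluate (default 0.7).
#' @return A [CalibrationResult-class].
#' @examples
#' calibrateThreshold(c(0.4, 0.5), c(1.0, 1.2))
#' @export
calibrateThreshold <- function(cytosolicControl, membraneControl,
                               threshold = 0.7) {
  cytosolicControl <- cytosolicControl[!is.na(cytosolicControl)]
  membraneControl <- membraneControl[!is.na(membraneControl)]
  if (!length(cytosolicControl) || !length(membraneControl))
    .mlErr("empty_control", "both control populations must be non-empty")
  missAt <- function(thr)
    c(cyto = mean(cytosolicControl > thr),
      mem = mean(membraneControl <= thr))
  at <- missAt(threshold)
  cand <- sort(unique(c(cytosolicControl, membraneControl)))
  total <- vapply(cand, function(thr)
    sum(cytosolicControl > thr) + sum(membraneControl <= thr), numeric(1))
  opt <- cand[which(total == min(total))[1L]]
  new("CalibrationResult", threshold = threshold,
      misclassCytosolic = unname(at["cyto"]),
      misclassMembrane = unname(at["mem"]), optimalThreshold = opt)
}

#' Ratio-versus-cell-length table
#'
#' One row per unflagged cell, sorted by length: the plotting-ready form
#' of the localization-versus-cell-length relationship.
#'
#' @param measurements data.frame from [measureCells()].
#' @return data.frame with columns length_um, ratio, class, cell_id,
#'   sorted ascending by length.
#' @export
ratioVsLength <- function(measurements) {
  valid <- measurements[!.isFlagged(measurements), , drop = FALSE]
  out <- valid[order(valid$length_um),
               c("length_um", "ratio", "class", "cell_id")]
  rownames(out) <- NULL
  out
}

#' Background-subtracted holdfast stain intensity
#'
#' Mean gray value of a stained holdfast minus the measured background
#' fluorescence of a holdfast-negative control. Negative results are
#' returned as-is and flagged.
#'
#' @param sampleMeanGray mean gray value of the sample (>= 0).
#' @param backgroundControlMean mean gray value of the stain-negative
#'   control strain (>= 0).
#' @return list(value =, flags = character()); flags contains
#'   \code{"below_background"} when the value is negative.
#' @export
holdfastIntensity <- function(sampleMeanGray, backgroundControlMean) {
  stopifnot(sampleMeanGray >= 0, backgroundControlMean >= 0)
  v <- sampleMeanGray - backgroundControlMean
  list(value = v,
       flags = if (v < 0) "below_background" else character())
}

#' Normalize values to a per-condition reference
#'
#' Divides every value by the value at \code{referenceIndex}; the
#' reference maps to exactly 1.
#'
#' @param values numeric vector.
#' @param referenceIndex index of the reference value (must be positive).
#' @return Numeric vector of the same length.
#' @export
normalizePerCondition <- function(values, referenceIndex) {
  ref <- values[referenceIndex]
  if (!is.finite(ref) || ref <= 0)
    .mlErr("invalid_reference",
           sprintf("reference value %s must be > 0", format(ref)))
  values / ref
}

#' End-to-end parameter recovery on synthetic data
#'
#' Simulates a cohort, quantifies it with ground-truth outlines, and
#' compares the realized ground-truth membrane fraction with the
#' pipeline's estimated membrane-associated fraction. The discrepancy
#' measures per-cell classification error of the whole
#' simulate-quantify-summarize chain.
#'
#' @param config a [SimulationConfig-class].
#' @param params a [CompartmentParams-class]; for simulated images use
#'   constant background subtraction at the simulated background level.
#' @return list(trueFraction, estimatedFraction, summary, measurements).
#' @export
recoveryExperiment <- function(config,
                               params = compartmentParams(
                                 backgroundMode = "constant",
                                 backgroundValue = config@background)) {
  cohort <- simulateCohort(config)
  meas <- measureCells(cohort$image, cohort$outlines, params)
  summ <- summarizePopulation(meas, params@threshold)
  truthValid <- cohort$truth[!.isFlagged(meas), , drop = FALSE]
  trueFrac <- mean(truthValid$mode == "membrane")
  list(trueFraction = trueFrac,
       estimatedFraction = fractionMembrane(summ),
       summary = summ, measurements = meas)
}

#' Serialize a PopulationSummary to JSON
#'
#' @param summary a [PopulationSummary-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSummaryJson <- function(summary, path) {
  jsonlite::write_json(
    list(n_total = summary@nTotal, n_membrane = summary@nMembrane,
         n_cytosolic = summary@nCytosolic, n_excluded = summary@nExcluded,
         fraction_membrane = summary@fractionMembrane,
         threshold = summary@threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
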