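#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 classes; slot access from
#' user code should go through these.
#'
#' @param object an object of the documented classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("outlines", function(object) standardGeneric("outlines"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("cellLengthPx", function(object) standardGeneric("cellLengthPx"))
#' @rdname accessors
#' @export
setGeneric("localizationMode",
           function(object) standardGeneric("localizationMode"))
#' @rdname accessors
#' @export
setGeneric("membraneFraction",
           function(object) standardGeneric("membraneFraction"))
#' @rdname accessors
#' @export
setGeneric("classThreshold",
           function(object) standardGeneric("classThreshold"))
#' @rdname accessors
#' @export
setGeneric("fractionMembrane",
           function(object) standardGeneric("fractionMembrane"))
#' @rdname accessors
#' @export
setGeneric("optimalThreshold",
           function(object) standardGeneric("optimalThreshold"))

#' @rdname accessors
setMethod("cellId", "CellGeometry", function(object) object@id)
#' @rdname accessors
setMethod("cellId", "CellOutline", function(object) object@id)
#' @rdname accessors
setMethod("vertices", "CellOutline", function(object) object@vertices)
#' @rdname accessors
setMethod("outlines", "OutlineSet", function(object) object@cells)
#' @rdname accessors
setMethod("pixelSize", "OutlineSet", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "SimulationConfig",
          function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("nCells", "OutlineSet", function(object) length(object@cells))
#' @rdname accessors
setMethod("nCells", "SimulationConfig", function(object) object@nCells)
#' @rdname accessors
setMethod("cellLengthPx", "CellGeometry", function(object) object@lengthPx)
#' @rdname accessors
setMethod("localizationMode", "CellGeometry", function(object) object@mode)
#' @rdname accessors
setMethod("membraneFraction", "CellGeometry",
          function(object) object@membraneFraction)
#' @rdname accessors
setMethod("classThreshold", "CompartmentParams",
          function(object) object@threshold)
#' @rdname accessors
setMethod("classThreshold", "PopulationSummary",
          function(object) object@threshold)
#' @rdname accessors
setMethod("classThreshold", "CalibrationResult",
          function(object) object@threshold)
#' @rdname accessors
setMethod("fractionMembrane", "PopulationSummary",
          function(object) object@fractionMembrane)
#' @rdname accessors
setMethod("optimalThreshold", "CalibrationResult",
          function(object) object@optimalThreshold)

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry '%s': L=%.1f px, W=%.1f px, theta=%.2f rad, %s (f=%.2f)\n",
    object@id, object@lengthPx, object@widthPx, object@orientationRad,
    object@mode, object@membraneFraction))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  canvas  : %d x %d px, %.3f um/px\n",
              object@canvasShape[1], object@canvasShape[2],
              object@pixelSizeUm))
  cat(sprintf("  cells   : n=%d, width %.1f px, lengths %s\n",
              object@nCells, object@widthPx,
              paste(deparse(object@lengthDist), collapse = "")))
  cat(sprintf("  signal  : amplitude %.0f, shell %.2f px, P(membrane)=%.2f\n",
              object@amplitude, object@shellThicknessPx,
              object@populationMembraneProb))
  cat(sprintf("  optics  : PSF sigma %.2f px, background %.0f, poisson=%s, read sd %.1f\n",
              object@psfSigmaPx, object@background,
              object@noise$poisson, object@noise$readSd))
  cat(sprintf("  seed    : %d\n", object@seed))
})

setMethod("show", "CellOutline", function(object) {
  cat(sprintf("CellOutline '%s': %d vertices, area %.1f px^2\n",
              object@id, nrow(object@vertices),
              abs(.polygonArea(object@vertices))))
})

setMethod("show", "OutlineSet", function(object) {
  fr <- if (is.na(object@frame)) "" else sprintf(", frame %d", object@frame)
  cat(sprintf("OutlineSet: %d cells, %.3f um/px%s\n",
              length(object@cells), object@pixelSizeUm, fr))
})

setMethod("show", "CompartmentParams", function(object) {
  bg <- if (object@backgroundMode == "constant")
    sprintf("constant %.1f", object@backgroundValue) else "none"
  cat(sprintf(
    "CompartmentParams: ring %d px, background %s, threshold %.2f\n",
    object@ringWidthPx, bg, object@threshold))
})

setMethod("show", "PopulationSummary", function(object) {
  cat("PopulationSummary\n")
  cat(sprintf("  n=%d (membrane %d, cytosolic %d, excluded %d)\n",
              object@nTotal, object@nMembrane, object@nCytosolic,
              object@nExcluded))
  cat(sprintf("  fraction membrane-associated: %.3f at threshold %.2f\n",
              object@fractionMembrane, object@threshold))
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult\n")
  cat(sprintf("  threshold %.3f: misclassified cytosolic %.3f, membrane %.3f\n",
              object@threshold, object@misclassCytosolic,
              object@misclassMembrane))
  cat(sprintf("  optimal threshold (observed-ratio candidates): %.3f\n",
              object@optimalThreshold))
})
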