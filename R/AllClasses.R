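#' @import methods
NULL

# Error helper: conditions carry a machine-readable class (first element)
# so callers and tests can dispatch on the failure mode.
.mlErr <- function(code, msg) {
  stop(structure(
    class = c(code, "memloc_error", "error", "condition"),
    list(message = sprintf("%s: %s", code, msg), call = sys.call(-1))
  ))
}

#' CellGeometry: parametric spherocylinder model of one rod-shaped cell
#'
#' A cell is modelled as a cylinder of diameter \code{widthPx} capped by two
#' hemispheres, with total pole-to-pole length \code{lengthPx} (caps
#' included), centred at \code{center} (continuous pixel coordinates,
#' x = column, y = row, 0-based) and rotated by \code{orientationRad}.
#' \code{mode} records where the fluorescent label resides:
#' \code{"cytosolic"} (uniform in the cell volume), \code{"membrane"}
#' (confined to a thin shell under the surface), or \code{"mixed"} with
#' \code{membraneFraction} of the total label in the shell.
#'
#' @slot id character cell identifier.
#' @slot center numeric length-2, (x, y) pixel coordinates of the centroid.
#' @slot lengthPx numeric, total length including the hemispherical caps.
#' @slot widthPx numeric, cell diameter (2r).
#' @slot orientationRad numeric, angle of the long axis, radians.
#' @slot mode character, one of \code{"cytosolic"}, \code{"membrane"},
#'   \code{"mixed"}.
#' @slot membraneFraction numeric in [0, 1]; 0 for cytosolic mode, 1 for
#'   membrane mode.
#'
#' @seealso [cellGeometry()] for the user constructor.
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(
    id = "character",
    center = "numeric",
    lengthPx = "numeric",
    widthPx = "numeric",
    orientationRad = "numeric",
    mode = "character",
    membraneFraction = "numeric"
  )
)

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (length(object@center) != 2L)
    msg <- c(msg, "center must be length-2 (x, y)")
  if (!(object@widthPx > 0))
    msg <- c(msg, "widthPx must be > 0")
  if (!(object@lengthPx >= object@widthPx))
    msg <- c(msg, "lengthPx must be >= widthPx")
  if (!object@mode %in% c("cytosolic", "membrane", "mixed"))
    msg <- c(msg, "mode must be cytosolic, membrane or mixed")
  f <- object@membraneFraction
  if (f < 0 || f > 1)
    msg <- c(msg, "membraneFraction must lie in [0, 1]")
  if (object@mode == "cytosolic" && f != 0)
    msg <- c(msg, "cytosolic mode requires membraneFraction 0")
  if (object@mode == "membrane" && f != 1)
    msg <- c(msg, "membrane mode requires membraneFraction 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CellGeometry
#'
#' @param id cell identifier.
#' @param center numeric (x, y) centre in pixel coordinates.
#' @param lengthPx total pole-to-pole length in pixels (caps included).
#' @param widthPx cell diameter in pixels.
#' @param orientationRad long-axis angle in radians.
#' @param mode label localization: "cytosolic", "membrane" or "mixed".
#' @param membraneFraction fraction of label in the membrane shell; forced
#'   to 0/1 for the pure modes.
#' @return A [CellGeometry-class] object.
#' @examples
#' g <- cellGeometry("c1", c(40, 40), lengthPx = 45, widthPx = 15)
#' cellLengthPx(g)
#' @export
cellGeometry <- function(id, center, lengthPx, widthPx,
                         orientationRad = 0, mode = "cytosolic",
                         membraneFraction = NULL) {
  if (is.null(membraneFraction))
    membraneFraction <- switch(mode, cytosolic = 0, membrane = 1,
                               mixed = 0.5)
  new("CellGeometry", id = as.character(id), center = as.numeric(center),
      lengthPx = as.numeric(lengthPx), widthPx = as.numeric(widthPx),
      orientationRad = as.numeric(orientationRad), mode = mode,
      membraneFraction = as.numeric(membraneFraction))
}

#' SimulationConfig: parameters of the synthetic microscopy generator
#'
#' Defaults emulate the study conditions of the localization screen:
#' 250 cells per cohort, 15 px cell width, lengths uniform on 30--60 px,
#' 1.5 px membrane shell, 2 px Gaussian PSF, constant background 100,
#' peak amplitude 1000, Poisson shot noise plus Gaussian read noise
#' (sd 20), 0.066 um pixels.
#'
#' @slot canvasShape integer (rows, cols) of the image.
#' @slot nCells integer number of cells to place.
#' @slot lengthDist list; \code{list(name = "uniform", min =, max =)} or
#'   \code{list(name = "normal", mean =, sd =)} (truncated below at
#'   \code{widthPx}), pixels.
#' @slot widthPx numeric cell diameter, pixels; must exceed 8 so that the
#'   default 4-px ring leaves a non-empty interior.
#' @slot pixelSizeUm numeric micrometres per pixel.
#' @slot shellThicknessPx numeric membrane shell thickness t, pixels.
#' @slot amplitude numeric peak on-axis signal of a cytosolic cell.
#' @slot background numeric constant background offset.
#' @slot psfSigmaPx numeric Gaussian PSF sigma, pixels.
#' @slot noise list(poisson = logical, readSd = numeric).
#' @slot populationMembraneProb numeric, Bernoulli probability that a cell
#'   is membrane-mode.
#' @slot seed integer; fully determines the generator output.
#' @slot maxAttempts integer rejection-sampling cap per cell.
#' @slot marginPx numeric minimum separation between cell footprints.
#'
#' @seealso [simConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    canvasShape = "integer",
    nCells = "integer",
    lengthDist = "list",
    widthPx = "numeric",
    pixelSizeUm = "numeric",
    shellThicknessPx = "numeric",
    amplitude = "numeric",
    background = "numeric",
    psfSigmaPx = "numeric",
    noise = "list",
    populationMembraneProb = "numeric",
    seed = "integer",
    maxAttempts = "integer",
    marginPx = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@canvasShape) != 2L || any(object@canvasShape < 1L))
    msg <- c(msg, "canvasShape must be two positive integers (rows, cols)")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (!(object@widthPx > 8))
    msg <- c(msg, "widthPx must exceed 8 (ring must leave an interior)")
  if (!(object@shellThicknessPx > 0 &&
        object@shellThicknessPx < object@widthPx / 2))
    msg <- c(msg, "shellThicknessPx must lie in (0, widthPx/2)")
  if (object@psfSigmaPx < 0) msg <- c(msg, "psfSigmaPx must be >= 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  p <- object@populationMembraneProb
  if (p < 0 || p > 1)
    msg <- c(msg, "populationMembraneProb must lie in [0, 1]")
  if (!all(c("poisson", "readSd") %in% names(object@noise)))
    msg <- c(msg, "noise must have elements poisson and readSd")
  if (!identical(object@lengthDist$name, "uniform") &&
      !identical(object@lengthDist$name, "normal"))
    msg <- c(msg, "lengthDist$name must be uniform or normal")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param canvasShape integer (rows, cols).
#' @param nCells number of cells.
#' @param lengthDist length distribution, \code{list(name, ...)}; see
#'   [SimulationConfig-class].
#' @param widthPx cell diameter in pixels.
#' @param pixelSizeUm micrometres per pixel.
#' @param shellThicknessPx membrane shell thickness in pixels.
#' @param amplitude peak on-axis cytosolic signal.
#' @param background constant background level.
#' @param psfSigmaPx Gaussian PSF sigma in pixels.
#' @param noise list with elements \code{poisson} (logical) and
#'   \code{readSd} (numeric).
#' @param populationMembraneProb probability a cell is membrane-mode.
#' @param seed integer RNG seed.
#' @param maxAttempts placement attempts per cell before failing.
#' @param marginPx minimum footprint separation in pixels.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nCells = 20, seed = 1)
#' nCells(cfg)
#' @export
simConfig <- function(canvasShape = c(1024L, 1024L),
                      nCells = 250L,
                      lengthDist = list(name = "uniform", min = 30, max = 60),
                      widthPx = 15,
                      pixelSizeUm = 0.066,
                      shellThicknessPx = 1.5,
                      amplitude = 1000,
                      background = 100,
                      psfSigmaPx = 2,
                      noise = list(poisson = TRUE, readSd = 20),
                      populationMembraneProb = 0.5,
                      seed = 1L,
                      maxAttempts = 1000L,
                      marginPx = 2) {
  new("SimulationConfig",
      canvasShape = as.integer(canvasShape), nCells = as.integer(nCells),
      lengthDist = lengthDist, widthPx = as.numeric(widthPx),
      pixelSizeUm = as.numeric(pixelSizeUm),
      shellThicknessPx = as.numeric(shellThicknessPx),
      amplitude = as.numeric(amplitude), background = as.numeric(background),
      psfSigmaPx = as.numeric(psfSigmaPx), noise = noise,
      populationMembraneProb = as.numeric(populationMembraneProb),
      seed = as.integer(seed), maxAttempts = as.integer(maxAttempts),
      marginPx = as.numeric(marginPx))
}

#' CellOutline: closed polygon delimiting one cell
#'
#' Vertices are continuous pixel coordinates (x = column, y = row,
#' 0-based, pixel centers at integer coordinates); the polygon is
#' implicitly closed (last vertex connects to first) and must be simple.
#'
#' @slot id character cell identifier.
#' @slot vertices numeric matrix, n x 2, columns (x, y).
#' @seealso [cellOutline()], [rasterizeOutline()], [cellLength()]
#' @exportClass CellOutline
setClass("CellOutline",
  representation(id = "character", vertices = "matrix")
)

setValidity("CellOutline", function(object) {
  v <- object@vertices
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "vertices must be a numeric n x 2 matrix")
  else {
    if (nrow(v) < 3L) msg <- c(msg, "outline needs at least 3 vertices")
    else {
      if (abs(.polygonArea(v)) <= 0)
        msg <- c(msg, "outline must enclose positive area")
      if (.selfIntersects(v))
        msg <- c(msg, "outline must not self-intersect")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellOutline
#'
#' @param id cell identifier.
#' @param vertices numeric n x 2 matrix of (x, y) vertices, or a list of
#'   length-2 vectors.
#' @return A [CellOutline-class] object.
#' @export
cellOutline <- function(id, vertices) {
  if (is.list(vertices))
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- matrix(as.numeric(vertices), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  new("CellOutline", id = as.character(id), vertices = vertices)
}

#' OutlineSet: the cell outlines of one image frame
#'
#' Bundles the outlines of a single frame with the pixel size used to
#' convert lengths to micrometres and an optional frame index (for
#' time-lapse series).
#'
#' @slot cells list of [CellOutline-class] objects with unique ids.
#' @slot pixelSizeUm numeric micrometres per pixel.
#' @slot frame integer frame index (NA for snapshots).
#' @seealso [outlineSet()], [readOutlines()], [writeOutlines()]
#' @exportClass OutlineSet
setClass("OutlineSet",
  representation(cells = "list", pixelSizeUm = "numeric", frame = "integer")
)

setValidity("OutlineSet", function(object) {
  msg <- character()
  if (!all(vapply(object@cells, is, logical(1), "CellOutline")))
    msg <- c(msg, "cells must all be CellOutline objects")
  else {
    ids <- vapply(object@cells, function(o) o@id, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate cell id: %s",
                            ids[duplicated(ids)][1L]))
  }
  if (!(object@pixelSizeUm > 0))
    msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OutlineSet
#'
#' @param cells list of [CellOutline-class] objects.
#' @param pixelSizeUm micrometres per pixel.
#' @param frame optional integer frame index.
#' @return An [OutlineSet-class] object.
#' @export
outlineSet <- function(cells, pixelSizeUm, frame = NA_integer_) {
  new("OutlineSet", cells = cells, pixelSizeUm = as.numeric(pixelSizeUm),
      frame = as.integer(frame))
}

#' CompartmentParams: parameters of the compartment quantification
#'
#' @slot ringWidthPx integer width of the membrane ring in pixels; the
#'   default 4 takes the first four intracellular pixels flanking the
#'   outline as the membrane compartment.
#' @slot backgroundMode character, "none" or "constant".
#' @slot backgroundValue numeric, subtracted from every intensity when
#'   backgroundMode is "constant".
#' @slot threshold numeric ratio threshold; ratio > threshold is classified
#'   membrane-associated, ratio <= threshold cytosolic. Default 0.7.
#' @slot saturationLevel numeric; cells containing pixels at or above this
#'   level are flagged "saturated" (default Inf, never flagged).
#' @seealso [compartmentParams()], [measureCell()]
#' @exportClass CompartmentParams
setClass("CompartmentParams",
  representation(
    ringWidthPx = "integer",
    backgroundMode = "character",
    backgroundValue = "numeric",
    threshold = "numeric",
    saturationLevel = "numeric"
  )
)

setValidity("CompartmentParams", function(object) {
  msg <- character()
  if (object@ringWidthPx < 1L) msg <- c(msg, "ringWidthPx must be >= 1")
  if (!object@backgroundMode %in% c("none", "constant"))
    msg <- c(msg, "backgroundMode must be none or constant")
  if (!(object@threshold > 0)) msg <- c(msg, "threshold must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct CompartmentParams
#'
#' @param ringWidthPx membrane ring width in pixels (default 4).
#' @param backgroundMode "none" or "constant".
#' @param backgroundValue constant background to subtract.
#' @param threshold classification threshold on the membrane/cytosol ratio.
#' @param saturationLevel intensity at which pixels count as saturated.
#' @return A [CompartmentParams-class] object.
#' @examples
#' compartmentParams(backgroundMode = "constant", backgroundValue = 100)
#' @export
compartmentParams <- function(ringWidthPx = 4L, backgroundMode = "none",
                              backgroundValue = 0, threshold = 0.7,
                              saturationLevel = Inf) {
  new("CompartmentParams", ringWidthPx = as.integer(ringWidthPx),
      backgroundMode = backgroundMode,
      backgroundValue = as.numeric(backgroundValue),
      threshold = as.numeric(threshold),
      saturationLevel = as.numeric(saturationLevel))
}

#' PopulationSummary: cohort-level classification counts
#'
#' @slot nTotal integer, cells supplied.
#' @slot nMembrane integer, unflagged cells classified membrane-associated.
#' @slot nCytosolic integer, unflagged cells classified cytosolic.
#' @slot nExcluded integer, flagged cells excluded from the fraction.
#' @slot fractionMembrane numeric, nMembrane / (nMembrane + nCytosolic).
#' @slot threshold numeric, threshold used.
#' @seealso [summarizePopulation()]
#' @exportClass PopulationSummary
setClass("PopulationSummary",
  representation(nTotal = "integer", nMembrane = "integer",
                 nCytosolic = "integer", nExcluded = "integer",
                 fractionMembrane = "numeric", threshold = "numeric")
)

setValidity("PopulationSummary", function(object) {
  if (object@nMembrane + object@nCytosolic + object@nExcluded !=
      object@nTotal)
    return("counts must sum to nTotal")
  TRUE
})

#' CalibrationResult: control-population misclassification at a threshold
#'
#' @slot threshold numeric, threshold evaluated.
#' @slot misclassCytosolic numeric fraction of cytosolic-control cells
#'   classified membrane-associated.
#' @slot misclassMembrane numeric fraction of membrane-control cells
#'   classified cytosolic.
#' @slot optimalThreshold numeric, observed-ratio candidate minimizing
#'   total misclassifications (ties to the smallest candidate).
#' @seealso [calibrateThreshold()]
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(threshold = "numeric", misclassCytosolic = "numeric",
                 misclassMembrane = "numeric", optimalThreshold = "numeric")
)
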