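#' @include AllClasses.R compartments.R outlines.R
NULL

#' Mean intensity over a pixel mask
#'
#' Arithmetic mean of the image values under the mask after background
#' handling: with \code{backgroundMode = "constant"} the configured
#' constant is subtracted from every pixel first; with \code{"none"}
#' values are used as-is.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same dimension.
#' @param params a [CompartmentParams-class].
#' @return Mean intensity (numeric scalar).
#' @export
meanIntensity <- function(image, mask, params = compartmentParams()) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask)) .mlErr("empty_compartment", "mask is empty")
  m <- mean(image[mask])
  if (params@backgroundMode == "constant") m - params@backgroundValue else m
}

#' Classify a membrane/cytosol intensity ratio
#'
#' Ratios strictly above the threshold are membrane-associated; ratios at
#' or below it (including the boundary value) are cytosolic.
#'
#' @param ratio membrane/cytosol mean-intensity ratio(s).
#' @param threshold classification threshold (default 0.7).
#' @return Character vector, \code{"membrane"} or \code{"cytosolic"}
#'   (\code{NA} for undefined ratios).
#' @examples
#' classifyRatio(c(0.70, 0.71))  # "cytosolic" "membrane"
#' @export
classifyRatio <- function(ratio, threshold = 0.7) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio > threshold, "membrane", "cytosolic"))
}

.emptyMeasurement <- function(id, lengthUm, flags,
                              meanMembrane = NA_real_,
                              meanCytosol = NA_real_) {
  data.frame(cell_id = id, frame = NA_integer_, length_um = lengthUm,
             mean_membrane = meanMembrane, mean_cytosol = meanCytosol,
             ratio = NA_real_, class = NA_character_,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quantify membrane-versus-cytosol localization of one cell
#'
#' The core per-cell measurement: rasterize the outline, split the mask
#' into the boundary ring and the interior, take mean intensities (after
#' background handling), form the ratio membrane/cytosol, and classify it
#' against the threshold. Cells whose ring swallows the whole mask are
#' returned flagged \code{too_thin} with an undefined ratio; cells whose
#' mask touches the image border are flagged \code{border} (their ring
#' would be truncated); pixels at or above the saturation level flag
#' \code{saturated}. A zero or negative cytosol mean after background
#' subtraction leaves the ratio undefined (flag \code{undefined_ratio}),
#' never infinite.
#'
#' @param image numeric matrix of fluorescence intensities.
#' @param outline a [CellOutline-class].
#' @param params a [CompartmentParams-class].
#' @param pixelSizeUm micrometres per pixel for the length column.
#' @return One-row data.frame with columns cell_id, frame, length_um,
#'   mean_membrane, mean_cytosol, ratio, class, flags.
#' @export
measureCell <- function(image, outline, params = compartmentParams(),
                        pixelSizeUm = 1) {
  lengthUm <- cellLength(outline, pixelSizeUm)
  mask <- rasterizeOutline(outline, dim(image))
  flags <- character()
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx[, 1] == 1L) || any(idx[, 1] == nrow(image)) ||
      any(idx[, 2] == 1L) || any(idx[, 2] == ncol(image)))
    flags <- c(flags, "border")
  if (any(image[mask] >= params@saturationLevel))
    flags <- c(flags, "saturated")
  # the ring/interior split only depends on the mask's bounding box
  # (everything outside it is exterior), so work on the crop
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  image <- image[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  mask <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  ring <- membraneRing(mask, params@ringWidthPx)
  interior <- tryCatch(cytosolInterior(mask, ring),
                       cell_too_thin = function(e) NULL)
  if (is.null(interior))
    return(.emptyMeasurement(outline@id, lengthUm,
                             c(flags, "too_thin"),
                             meanMembrane = meanIntensity(image, ring,
                                                          params)))
  mMem <- meanIntensity(image, ring, params)
  mCyt <- meanIntensity(image, interior, params)
  if (!(mCyt > 0))
    return(.emptyMeasurement(outline@id, lengthUm,
                             c(flags, "undefined_ratio"), mMem, mCyt))
  ratio <- mMem / mCyt
  data.frame(cell_id = outline@id, frame = NA_integer_,
             length_um = lengthUm, mean_membrane = mMem,
             mean_cytosol = mCyt, ratio = ratio,
             class = classifyRatio(ratio, params@threshold),
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quantify every cell of a frame
#'
#' @param image numeric matrix.
#' @param outlineSet an [OutlineSet-class]; its pixel size converts
#'   lengths to micrometres.
#' @param params a [CompartmentParams-class].
#' @return data.frame, one row per cell (see [measureCell()]); the frame
#'   column carries the set's frame index when present.
#' @examples
#' cohort <- simulateCohort(simConfig(nCells = 2, canvasShape = c(256L, 256L),
#'                                    seed = 3))
#' pp <- compartmentParams(backgroundMode = "constant", backgroundValue = 100)
#' measureCells(cohort$image, cohort$outlines, pp)
#' @export
measureCells <- function(image, outlineSet, params = compartmentParams()) {
  rows <- lapply(outlines(outlineSet), function(o)
    measureCell(image, o, params, pixelSize(outlineSet)))
  df <- do.call(rbind, rows)
  if (is.null(df)) return(.emptyMeasurement("x", 0, character())[0, ])
  if (!is.na(outlineSet@frame)) df$frame <- outlineSet@frame
  df
}
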