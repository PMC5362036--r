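#' @include AllClasses.R
NULL

# One binary erosion with the 3x3 (8-connected) structuring element.
# Out-of-image counts as background, so masks touching the border erode
# from the border too; this matches a Chebyshev distance transform that
# treats everything outside the image as exterior.
.erode8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- padded[2:(nr + 1L), 2:(nc + 1L)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out & padded[(2L + di):(nr + 1L + di), (2L + dj):(nc + 1L + dj)]
  }
  out
}

#' Membrane ring of a cell mask
#'
#' The membrane compartment: the first \code{ringWidthPx} intracellular
#' pixels flanking the cell outline. Formally, the mask pixels whose
#' Chebyshev distance to the nearest exterior pixel is at most
#' \code{ringWidthPx}; computed as the mask minus \code{ringWidthPx}
#' successive 8-connected erosions (the two definitions coincide). With
#' the default width 4 this is the four-pixel boundary band used to score
#' membrane association.
#'
#' @param mask logical matrix, the rasterized cell.
#' @param ringWidthPx ring width in pixels (0 gives an empty ring).
#' @return Logical matrix; for thin cells the ring may be the whole mask.
#' @seealso [cytosolInterior()], [compartmentMasks()]
#' @export
membraneRing <- function(mask, ringWidthPx = 4L) {
  if (!any(mask)) .mlErr("empty_compartment", "mask is empty")
  if (ringWidthPx < 1L) return(mask & FALSE)
  eroded <- mask
  for (k in seq_len(ringWidthPx)) eroded <- .erode8(eroded)
  mask & !eroded
}

#' Cytosolic interior of a cell mask
#'
#' The cytoplasmic compartment: the remaining intracellular pixels once
#' the membrane ring is removed.
#'
#' @param mask logical matrix, the rasterized cell.
#' @param ring logical matrix, the membrane ring (subset of mask).
#' @return Logical matrix. Errors with condition class
#'   \code{cell_too_thin} when nothing remains (the ring swallowed the
#'   cell); callers flag such cells rather than dropping them silently.
#' @export
cytosolInterior <- function(mask, ring) {
  stopifnot(identical(dim(mask), dim(ring)))
  if (any(ring & !mask))
    stop("ring must be a subset of the mask")
  interior <- mask & !ring
  if (!any(interior))
    .mlErr("cell_too_thin",
           "membrane ring covers the whole cell; no cytosolic pixels left")
  interior
}

#' Membrane/cytosol partition of a cell mask
#'
#' Convenience wrapper returning both compartments; they exactly
#' partition the mask.
#'
#' @param mask logical matrix, the rasterized cell.
#' @param ringWidthPx ring width in pixels.
#' @return list(membrane =, cytosol =) of logical matrices.
#' @export
compartmentMasks <- function(mask, ringWidthPx = 4L) {
  ring <- membraneRing(mask, ringWidthPx)
  list(membrane = ring, cytosol = cytosolInterior(mask, ring))
}
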