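#' @include outlines.R
NULL

# Outer boundary polygon of a labelled component, traced as the 0.5-level
# contour of its binary mask (computed on the component's bounding box).
# Returns an n x 2 (x, y) matrix in image coordinates, or NULL.
.traceBoundary <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(labels), max(idx[, 1]) + 2L)
  c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(labels), max(idx[, 2]) + 2L)
  sub <- (labels[r0:r1, c0:c1] == id) * 1
  cl <- grDevices::contourLines(x = (r0:r1) - 1, y = (c0:c1) - 1, z = sub,
                                levels = 0.5)
  if (!length(cl)) return(NULL)
  # keep the contour with the largest enclosed area (the outer boundary)
  areas <- vapply(cl, function(ct)
    abs(.polygonArea(cbind(ct$y, ct$x))), numeric(1))
  ct <- cl[[which.max(areas)]]
  # contourLines x follows matrix rows (image y), y follows cols (image x)
  v <- cbind(x = ct$y, y = ct$x)
  # drop a duplicated closing vertex if present
  if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-9))
    v <- v[-nrow(v), , drop = FALSE]
  v
}

#' Minimal intensity-based segmenter for synthetic images
#'
#' A deliberately simple stand-in for a dedicated cell-outlining tool
#' (such as Oufti operating on phase-contrast images): Gaussian smoothing,
#' global Otsu threshold, 8-connected component labelling, removal of
#' components below \code{minArea}, and boundary tracing of each
#' remaining component. Intended for the synthetic generator's
#' fluorescence images; it is not tuned for real micrographs.
#'
#' @param image numeric intensity matrix.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param minArea minimum component area in pixels.
#' @param pixelSizeUm pixel size recorded in the returned set.
#' @return An [OutlineSet-class] (possibly empty) with ids
#'   \code{"seg_001"}, \code{"seg_002"}, ... ordered by component
#'   labelling.
#' @export
segmentStandIn <- function(image, sigma = 2, minArea = 50,
                           pixelSizeUm = 1) {
  rng <- range(image)
  if (diff(rng) <= 0)
    return(outlineSet(list(), pixelSizeUm))
  norm <- (image - rng[1]) / diff(rng)
  sm <- if (sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(norm), sigma = sigma))
  else norm
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bw <- sm > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= minArea)
  cells <- list()
  for (k in seq_along(keep)) {
    v <- .traceBoundary(labels, keep[k])
    if (is.null(v) || nrow(v) < 3L) next
    o <- tryCatch(cellOutline(sprintf("seg_%03d", length(cells) + 1L), v),
                  error = function(e) NULL)
    if (!is.null(o)) cells <- c(cells, o)
  }
  outlineSet(cells, pixelSizeUm)
}
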