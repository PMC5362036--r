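#' @include AllClasses.R
NULL

# Perpendicular distance from each pixel center in a window to the
# geometry's axis segment. The silhouette of a spherocylinder is the set
# of points within r of the segment joining the two cap centers; beyond a
# segment end the distance is measured from the cap center, which makes
# the spherical-cap chord formula fall out of the same expression.
# Returns list(d = matrix, xr, yr) over the window (0-based coords).
.axisDistance <- function(geometry, xr, yr) {
  cx <- geometry@center[1]; cy <- geometry@center[2]
  th <- geometry@orientationRad
  r <- geometry@widthPx / 2
  h <- geometry@lengthPx / 2 - r  # half-length of the cylindrical body
  ux <- cos(th); uy <- sin(th)
  px <- matrix(rep(xr, each = length(yr)), length(yr), length(xr))
  py <- matrix(rep(yr, times = length(xr)), length(yr), length(xr))
  tt <- pmin(pmax((px - cx) * ux + (py - cy) * uy, -h), h)
  dx <- px - (cx + tt * ux)
  dy <- py - (cy + tt * uy)
  sqrt(dx * dx + dy * dy)
}

# Pixel window (0-based x and y ranges) covering the cell footprint,
# clipped to the canvas; pad allows a guard band.
.footprintWindow <- function(geometry, shape, pad = 1) {
  r <- geometry@widthPx / 2
  reach <- geometry@lengthPx / 2 + pad
  cx <- geometry@center[1]; cy <- geometry@center[2]
  xr <- max(0L, floor(cx - reach)):min(shape[2] - 1L, ceiling(cx + reach))
  yr <- max(0L, floor(cy - reach)):min(shape[1] - 1L, ceiling(cy + reach))
  list(xr = xr, yr = yr)
}

.checkInCanvas <- function(geometry, shape) {
  r <- geometry@lengthPx / 2
  cx <- geometry@center[1]; cy <- geometry@center[2]
  if (cx - r < -0.5 || cx + r > shape[2] - 0.5 ||
      cy - r < -0.5 || cy + r > shape[1] - 0.5)
    .mlErr("cell_out_of_bounds",
           sprintf("cell '%s' footprint exceeds the %d x %d canvas",
                   geometry@id, shape[1], shape[2]))
}

# Chord depth through a uniformly labelled solid spherocylinder,
# normalized so the on-axis mid-cell value equals `amplitude`.
.cytosolicProfile <- function(d, r, amplitude) {
  amplitude * sqrt(pmax(r * r - d * d, 0)) / r
}

# Unscaled path length through a shell of thickness t under the surface:
# 2*(sqrt(r^2-d^2) - sqrt(max(0, (r-t)^2-d^2))). Edge-peaked, maximum at
# d = r - t.
.membraneProfile <- function(d, r, t) {
  2 * (sqrt(pmax(r * r - d * d, 0)) -
       sqrt(pmax((r - t) * (r - t) - d * d, 0)))
}

#' Render a uniformly cytosolic cell into a canvas
#'
#' Adds the 2D projection of a uniformly labelled solid spherocylinder:
#' each pixel receives the chord depth \eqn{2\sqrt{r^2-d^2}} for
#' perpendicular distance d from the long axis (the spherical-cap
#' equivalent near the poles), normalized so the on-axis value at mid-cell
#' equals \code{amplitude}. Zero outside the silhouette. This is the
#' forward model of a soluble-fluorophore (eGFP) control cell.
#'
#' @param geometry a [CellGeometry-class]; must lie inside the canvas.
#' @param amplitude peak on-axis intensity.
#' @param canvas numeric matrix to add the cell to.
#' @return The canvas with the cell added.
#' @export
renderCytosolic <- function(geometry, amplitude, canvas) {
  shape <- dim(canvas)
  .checkInCanvas(geometry, shape)
  w <- .footprintWindow(geometry, shape)
  d <- .axisDistance(geometry, w$xr, w$yr)
  canvas[w$yr + 1L, w$xr + 1L] <- canvas[w$yr + 1L, w$xr + 1L] +
    .cytosolicProfile(d, geometry@widthPx / 2, amplitude)
  canvas
}

#' Render a membrane-confined cell into a canvas
#'
#' Adds the projected path length through a shell of thickness
#' \code{shellThicknessPx} just under the cell surface (the forward model
#' of an FM4-64-stained membrane). The profile is edge-peaked with its
#' maximum at distance r - t from the axis. The rendered cell is scaled so
#' its total integrated signal equals that of [renderCytosolic()] with the
#' same \code{amplitude}, so amplitude means total per-cell label
#' irrespective of where it resides.
#'
#' @param geometry a [CellGeometry-class]; must lie inside the canvas.
#' @param amplitude per-cell signal scale (matched to the cytosolic
#'   render).
#' @param shellThicknessPx shell thickness t, pixels; must satisfy
#'   0 < t < r.
#' @param canvas numeric matrix to add the cell to.
#' @return The canvas with the cell added.
#' @export
renderMembrane <- function(geometry, amplitude, shellThicknessPx, canvas) {
  r <- geometry@widthPx / 2
  if (!(shellThicknessPx > 0) || shellThicknessPx >= r)
    .mlErr("shell_too_thick",
           sprintf("shell thickness %.2f must lie in (0, r=%.2f)",
                   shellThicknessPx, r))
  shape <- dim(canvas)
  .checkInCanvas(geometry, shape)
  w <- .footprintWindow(geometry, shape)
  d <- .axisDistance(geometry, w$xr, w$yr)
  raw <- .membraneProfile(d, r, shellThicknessPx)
  cyto <- .cytosolicProfile(d, r, amplitude)
  sraw <- sum(raw)
  if (sraw > 0) raw <- raw * (sum(cyto) / sraw)
  canvas[w$yr + 1L, w$xr + 1L] <- canvas[w$yr + 1L, w$xr + 1L] + raw
  canvas
}

#' Render a cell according to its localization mode
#'
#' Dispatches on \code{localizationMode(geometry)}: pure cytosolic, pure
#' membrane, or a mixture rendering
#' \code{f * membrane + (1 - f) * cytosolic} with both components
#' normalized to the same total per-cell signal, so
#' \code{membraneFraction} f is the fraction of label in the membrane.
#'
#' @inheritParams renderMembrane
#' @return The canvas with the cell added.
#' @export
renderCell <- function(geometry, amplitude, shellThicknessPx, canvas) {
  f <- geometry@membraneFraction
  if (f <= 0) return(renderCytosolic(geometry, amplitude, canvas))
  if (f >= 1)
    return(renderMembrane(geometry, amplitude, shellThicknessPx, canvas))
  zero <- matrix(0, nrow(canvas), ncol(canvas))
  canvas +
    f * renderMembrane(geometry, amplitude, shellThicknessPx, zero) +
    (1 - f) * renderCytosolic(geometry, amplitude, zero)
}

#' Apply microscope optics and detection noise
#'
#' In order: Gaussian PSF blur, constant background offset, Poisson
#' resampling of pixel counts (shot noise), additive Gaussian read noise,
#' and clamping of negative values to zero. The order mimics photon
#' emission followed by detector read-out.
#'
#' @param image numeric matrix of noiseless intensities.
#' @param psfSigmaPx Gaussian PSF sigma in pixels (0 = no blur).
#' @param background constant offset added after blurring.
#' @param noise list(poisson = logical, readSd = numeric).
#' @param seed integer seed making the noise reproducible.
#' @return Numeric matrix of the same dimension, all values >= 0.
#' @examples
#' img <- matrix(0, 64, 64); img[32, 32] <- 100
#' out <- applyOptics(img, psfSigmaPx = 2, background = 10,
#'                    noise = list(poisson = FALSE, readSd = 0), seed = 1)
#' abs(sum(out) - (100 + 10 * 64 * 64)) < 1e-6
#' @export
applyOptics <- function(image, psfSigmaPx, background,
                        noise = list(poisson = TRUE, readSd = 20),
                        seed = 1L) {
  if (psfSigmaPx < 0 || background < 0)
    .mlErr("invalid_optics_param",
           "psfSigmaPx and background must be >= 0")
  out <- image
  if (psfSigmaPx > 0)
    out <- EBImage::imageData(EBImage::gblur(EBImage::Image(out),
                                             sigma = psfSigmaPx))
  out <- out + background
  readSd <- if (is.null(noise$readSd)) 0 else noise$readSd
  poisson <- isTRUE(noise$poisson)
  if (poisson || readSd > 0) {
    set.seed(as.integer(seed))
    if (poisson) {
      dm <- dim(out)
      out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)),
                    dm[1], dm[2])
    }
    if (readSd > 0)
      out <- out + matrix(stats::rnorm(length(out), sd = readSd),
                          nrow(out), ncol(out))
  }
  pmax(out, 0)
}

#' Ground-truth outline of a cell geometry
#'
#' Traces the spherocylinder silhouette boundary as a closed polygon:
#' two straight flanks along the cylindrical body joined by two
#' semicircular pole arcs, with vertices distributed over the arcs.
#'
#' @param geometry a [CellGeometry-class].
#' @param nVertices number of polygon vertices (>= 8).
#' @return A [CellOutline-class] with \code{nVertices} vertices.
#' @examples
#' o <- outlineOf(cellGeometry("c", c(50, 50), 40, 15))
#' max(dist(vertices(o)))  # ~40: Feret diameter = total length
#' @export
outlineOf <- function(geometry, nVertices = 64L) {
  stopifnot(nVertices >= 8L)
  r <- geometry@widthPx / 2
  h <- geometry@lengthPx / 2 - r
  th <- geometry@orientationRad
  # split vertices between the two pole arcs and the two straight flanks
  nArc <- max(3L, round(nVertices * r * pi / (2 * r * pi + 4 * h)))
  nArc <- min(nArc, floor((nVertices - 2L) / 2L))
  nFlank <- nVertices - 2L * nArc  # vertices placed along both flanks
  nf1 <- ceiling(nFlank / 2); nf2 <- nFlank - nf1
  # boundary in body coordinates (axis along +x): right cap from -pi/2 to
  # +pi/2 around (+h, 0), top flank, left cap, bottom flank
  angR <- seq(-pi / 2, pi / 2, length.out = nArc)
  capR <- cbind(h + r * cos(angR), r * sin(angR))
  flankT <- if (nf1 > 0)
    cbind(seq(h, -h, length.out = nf1 + 2)[2:(nf1 + 1)], r) else NULL
  angL <- seq(pi / 2, 3 * pi / 2, length.out = nArc)
  capL <- cbind(-h + r * cos(angL), r * sin(angL))
  flankB <- if (nf2 > 0)
    cbind(seq(-h, h, length.out = nf2 + 2)[2:(nf2 + 1)], -r) else NULL
  b <- rbind(capR, flankT, capL, flankB)
  # rotate and translate into image coordinates
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v <- t(R %*% t(b))
  v[, 1] <- v[, 1] + geometry@center[1]
  v[, 2] <- v[, 2] + geometry@center[2]
  cellOutline(geometry@id, v)
}
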