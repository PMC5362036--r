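#' @include AllClasses.R
NULL

# Signed area (shoelace); vertices n x 2, implicitly closed.
.polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Proper-crossing self-intersection test between non-adjacent edges.
# O(n^2); outlines are small (tens to a few hundred vertices).
.selfIntersects <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1), , drop = FALSE]
  orient <- function(a, b, c)
    sign((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges adjacent to edge i
    if (!length(js)) next
    a <- matrix(p1[i, ], length(js), 2, byrow = TRUE)
    b <- matrix(p2[i, ], length(js), 2, byrow = TRUE)
    c_ <- p1[js, , drop = FALSE]
    d <- p2[js, , drop = FALSE]
    hit <- orient(a, b, c_) * orient(a, b, d) < 0 &
           orient(c_, d, a) * orient(c_, d, b) < 0
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# Boundary-inclusive even-odd point-in-polygon, vectorized over points.
# px, py: point coordinates; v: n x 2 polygon (implicitly closed).
.pointsInPolygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  for (i in seq_len(n)) {
    # on-segment test
    dx <- x2[i] - x1[i]; dy <- y2[i] - y1[i]
    len2 <- dx * dx + dy * dy
    cross <- (px - x1[i]) * dy - (py - y1[i]) * dx
    tpar <- ((px - x1[i]) * dx + (py - y1[i]) * dy)
    onEdge <- onEdge |
      (abs(cross) <= eps * max(1, sqrt(len2)) & tpar >= -eps &
       tpar <= len2 + eps)
    # even-odd ray crossing (ray towards +x)
    crosses <- (y1[i] > py) != (y2[i] > py)
    if (any(crosses)) {
      xin <- x1[i] + (py - y1[i]) / (y2[i] - y1[i]) * dx
      inside <- xor(inside, crosses & px < xin)
    }
  }
  inside | onEdge
}

#' Rasterize a cell outline to a pixel mask
#'
#' A pixel belongs to the mask iff its center (integer coordinates,
#' x = column, y = row, 0-based) lies inside the polygon or exactly on its
#' boundary (even-odd rule, boundary-inclusive).
#'
#' @param outline a [CellOutline-class].
#' @param shape integer (rows, cols) of the target image.
#' @return Logical matrix of dimension \code{shape}; \code{TRUE} inside
#'   the cell.
#' @examples
#' sq <- cellOutline("sq", rbind(c(-0.5, -0.5), c(11.5, -0.5),
#'                               c(11.5, 11.5), c(-0.5, 11.5)))
#' sum(rasterizeOutline(sq, c(20, 20)))  # 144 = the 12 x 12 block
#' @export
rasterizeOutline <- function(outline, shape) {
  stopifnot(is(outline, "CellOutline"))
  v <- outline@vertices
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  if (min(v[, 1]) < -0.5 || max(v[, 1]) > cols - 0.5 ||
      min(v[, 2]) < -0.5 || max(v[, 2]) > rows - 0.5)
    .mlErr("outline_out_of_bounds",
           sprintf("outline '%s' exceeds the %d x %d image", outline@id,
                   rows, cols))
  mask <- matrix(FALSE, rows, cols)
  # bounding box of candidate pixel centers
  xr <- max(0L, floor(min(v[, 1]))):min(cols - 1L, ceiling(max(v[, 1])))
  yr <- max(0L, floor(min(v[, 2]))):min(rows - 1L, ceiling(max(v[, 2])))
  px <- rep(xr, each = length(yr))
  py <- rep(yr, times = length(xr))
  hit <- .pointsInPolygon(px, py, v)
  mask[cbind(py[hit] + 1L, px[hit] + 1L)] <- TRUE
  mask
}

#' Cell length from an outline
#'
#' Length is the maximum pairwise vertex distance (Feret diameter) scaled
#' by the pixel size. For a spherocylindrical rod this equals the total
#' pole-to-pole length; for bent cells it underestimates the medial-axis
#' length by the curvature correction.
#'
#' @param outline a [CellOutline-class].
#' @param pixelSizeUm micrometres per pixel (use 1 for pixel units).
#' @return Length in micrometres.
#' @examples
#' g <- cellGeometry("c", c(40, 40), 40, 15)
#' cellLength(outlineOf(g), pixelSizeUm = 0.066)  # ~2.64
#' @export
cellLength <- function(outline, pixelSizeUm = 1) {
  v <- outline@vertices
  max(stats::dist(v)) * pixelSizeUm
}

.outlineToList <- function(o) {
  list(id = o@id,
       vertices = lapply(seq_len(nrow(o@vertices)),
                         function(i) as.numeric(o@vertices[i, ])))
}

.outlineSetToList <- function(os) {
  doc <- list(pixel_size_um = os@pixelSizeUm)
  if (!is.na(os@frame)) doc$frame <- os@frame
  doc$cells <- lapply(os@cells, .outlineToList)
  doc
}

.outlineSetFromList <- function(doc, path = "") {
  if (is.null(doc$pixel_size_um) || is.null(doc$cells))
    .mlErr("invalid_outline_file",
           sprintf("%s: missing pixel_size_um or cells", path))
  ids <- vapply(doc$cells, function(cl) as.character(cl$id), character(1))
  if (anyDuplicated(ids))
    .mlErr("invalid_outline_file",
           sprintf("%s: duplicate cell id '%s'", path,
                   ids[duplicated(ids)][1L]))
  cells <- lapply(doc$cells, function(cl) {
    vv <- cl$vertices
    if (is.list(vv)) vv <- do.call(rbind, lapply(vv, as.numeric))
    vv <- matrix(as.numeric(vv), ncol = 2L)
    tryCatch(cellOutline(as.character(cl$id), vv), error = function(e)
      .mlErr("invalid_outline_file",
             sprintf("%s: cell '%s' invalid (%s)", path, cl$id,
                     conditionMessage(e))))
  })
  outlineSet(cells, doc$pixel_size_um,
             if (is.null(doc$frame)) NA_integer_ else doc$frame)
}

#' Read cell outlines from JSON
#'
#' The document is either a single object
#' \code{\{"pixel_size_um": .., "frame": .., "cells": [\{"id", "vertices"\}]\}}
#' (a snapshot) or an array of such objects (a time-lapse, one per frame).
#'
#' @param path path to the JSON file.
#' @return An [OutlineSet-class], or a list of them for multi-frame files.
#' @seealso [writeOutlines()]
#' @export
readOutlines <- function(path) {
  if (!file.exists(path))
    .mlErr("invalid_outline_file", sprintf("no such file: %s", path))
  doc <- tryCatch(jsonlite::read_json(path), error = function(e)
    .mlErr("invalid_outline_file",
           sprintf("%s: malformed JSON (%s)", path, conditionMessage(e))))
  if (!is.null(doc$cells)) return(.outlineSetFromList(doc, path))
  if (is.list(doc) && length(doc) && !is.null(doc[[1]]$cells))
    return(lapply(doc, .outlineSetFromList, path = path))
  .mlErr("invalid_outline_file", sprintf("%s: unrecognized schema", path))
}

#' Write cell outlines to JSON
#'
#' @param x an [OutlineSet-class] or a list of them (multi-frame).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @seealso [readOutlines()]
#' @export
writeOutlines <- function(x, path) {
  doc <- if (is(x, "OutlineSet")) .outlineSetToList(x)
         else lapply(x, .outlineSetToList)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
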