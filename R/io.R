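#' @include AllClasses.R
NULL

# Intensities are stored in TIFF as 32-bit float scaled to [0, 1] by a
# 16-bit camera full scale (65535 counts); readImageTiff undoes the
# scaling. Round trip is exact to float32 precision.
.TIFF_FULL_SCALE <- 65535

#' Read / write grayscale intensity TIFFs
#'
#' Images are numeric matrices of detector counts (row-major,
#' \code{img[row, col]}). Files are 32-bit float TIFFs with counts scaled
#' by 1/65535; multi-frame (time-lapse) stacks are multi-page TIFFs and
#' map to lists of matrices.
#'
#' @param path file path.
#' @return \code{readImageTiff}: a matrix, or a list of matrices for a
#'   multi-page file.
#' @seealso [tiff::readTIFF()]
#' @export
readImageTiff <- function(path) {
  if (!file.exists(path))
    .mlErr("io_error", sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate gray-stored-as-RGB
    p * .TIFF_FULL_SCALE
  })
  if (length(pages) == 1L) pages[[1]] else pages
}

#' @rdname readImageTiff
#' @param image numeric matrix, or list of matrices for a multi-frame
#'   stack; values are counts in [0, 65535].
#' @export
writeImageTiff <- function(image, path) {
  frames <- if (is.list(image)) image else list(image)
  frames <- lapply(frames, function(fr) fr / .TIFF_FULL_SCALE)
  ok <- tryCatch({
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .mlErr("io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Read / write per-cell measurement tables
#'
#' The cells CSV has columns cell_id, frame, length_um, mean_membrane,
#' mean_cytosol, ratio, class, flags (flags semicolon-separated, empty
#' when clean).
#'
#' @param measurements data.frame as returned by [measureCells()].
#' @param path file path.
#' @return \code{readCellsCsv}: the data.frame; \code{writeCellsCsv}:
#'   invisibly, \code{path}.
#' @export
writeCellsCsv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname writeCellsCsv
#' @export
readCellsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character"))
  df$flags[is.na(df$flags)] <- ""
  df$class[is.na(df$class)] <- NA_character_
  df
}
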