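#' @include AllClasses.R render.R
NULL

.drawLength <- function(dist, n, widthPx) {
  if (dist$name == "uniform")
    stats::runif(n, dist$min, dist$max)
  else
    pmax(stats::rnorm(n, dist$mean, dist$sd), widthPx)
}

#' Deterministic per-stage seed fan-out
#'
#' Derives a stage-specific RNG seed from a single run seed by hashing
#' the stage name, so one number reproduces a whole multi-stage run.
#' Results stay below 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return Integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Sample a non-overlapping cell population
#'
#' Draws \code{nCells} spherocylinder geometries with lengths from the
#' configured distribution, uniform orientations, and localization modes
#' Bernoulli(\code{populationMembraneProb}) between membrane and
#' cytosolic. Cells are placed by rejection sampling so that rasterized
#' footprints (dilated by \code{marginPx}) are pairwise disjoint and every
#' footprint stays at least 8 px clear of the canvas border (so boundary
#' rings are never truncated).
#'
#' @param config a [SimulationConfig-class].
#' @return List of [CellGeometry-class] objects (length \code{nCells}).
#' @export
samplePopulation <- function(config) {
  validObject(config)
  n <- config@nCells
  if (n == 0L) return(list())
  set.seed(stageSeed(config@seed, "sample_population"))
  shape <- config@canvasShape
  lengths <- .drawLength(config@lengthDist, n, config@widthPx)
  modes <- ifelse(stats::runif(n) < config@populationMembraneProb,
                  "membrane", "cytosolic")
  pad <- config@marginPx
  borderClear <- 8
  occupied <- matrix(FALSE, shape[1], shape[2])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lengths[i]
    reach <- L / 2 + borderClear
    if (2 * reach >= min(shape))
      .mlErr("canvas_too_crowded",
             sprintf("cell of length %.1f px cannot fit the canvas", L))
    placed <- FALSE
    for (attempt in seq_len(config@maxAttempts)) {
      cx <- stats::runif(1, reach, shape[2] - 1 - reach)
      cy <- stats::runif(1, reach, shape[1] - 1 - reach)
      th <- stats::runif(1, 0, pi)
      g <- cellGeometry(sprintf("cell_%03d", i), c(cx, cy), L,
                        config@widthPx, th, modes[i])
      w <- .footprintWindow(g, shape, pad = pad + 1)
      d <- .axisDistance(g, w$xr, w$yr)
      foot <- d <= config@widthPx / 2 + pad
      sub <- occupied[w$yr + 1L, w$xr + 1L]
      if (!any(sub & foot)) {
        occupied[w$yr + 1L, w$xr + 1L] <- sub | foot
        out[[i]] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .mlErr("canvas_too_crowded",
             sprintf("failed to place cell %d after %d attempts", i,
                     config@maxAttempts))
  }
  out
}

#' Render a whole cohort noiselessly
#'
#' @param geometries list of [CellGeometry-class].
#' @param config a [SimulationConfig-class] supplying canvas shape,
#'   amplitude and shell thickness.
#' @return Numeric matrix: sum of all per-cell renders, no background or
#'   noise.
#' @export
renderPopulation <- function(geometries, config) {
  canvas <- matrix(0, config@canvasShape[1], config@canvasShape[2])
  for (g in geometries)
    canvas <- renderCell(g, config@amplitude, config@shellThicknessPx,
                         canvas)
  canvas
}

#' Simulate one cohort ("strain") of cells
#'
#' Runs sample -> render -> optics and assembles the ground truth. When
#' \code{outDir} is given, writes the artifact set of one cohort: the
#' fluorescence image (\code{image.tif}), ground-truth outlines
#' (\code{outlines.json}), per-cell label table (\code{truth.csv} with
#' columns cell_id, mode, membrane_fraction, length_px) and the resolved
#' configuration (\code{sim_config.yaml}).
#'
#' @param config a [SimulationConfig-class].
#' @param outDir optional output directory.
#' @return Invisibly, a list with elements \code{image} (matrix),
#'   \code{outlines} ([OutlineSet-class]), \code{truth} (data.frame) and
#'   \code{geometries}.
#' @examples
#' cohort <- simulateCohort(simConfig(nCells = 3, canvasShape = c(256L, 256L),
#'                                    seed = 11))
#' cohort$truth
#' @export
simulateCohort <- function(config, outDir = NULL) {
  geoms <- samplePopulation(config)
  img <- renderPopulation(geoms, config)
  img <- applyOptics(img, config@psfSigmaPx, config@background,
                     config@noise, seed = stageSeed(config@seed, "optics"))
  cells <- lapply(geoms, outlineOf)
  os <- outlineSet(cells, config@pixelSizeUm)
  truth <- data.frame(
    cell_id = vapply(geoms, cellId, character(1)),
    mode = vapply(geoms, localizationMode, character(1)),
    membrane_fraction = vapply(geoms, membraneFraction, numeric(1)),
    length_px = vapply(geoms, cellLengthPx, numeric(1)),
    stringsAsFactors = FALSE)
  res <- list(image = img, outlines = os, truth = truth,
              geometries = geoms)
  if (!is.null(outDir)) {
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                           showWarnings = FALSE)
    if (!ok) .mlErr("io_error", sprintf("cannot create '%s'", outDir))
    writeImageTiff(img, file.path(outDir, "image.tif"))
    writeOutlines(os, file.path(outDir, "outlines.json"))
    utils::write.csv(truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    yaml::write_yaml(configToList(config),
                     file.path(outDir, "sim_config.yaml"))
  }
  invisible(res)
}

#' Simulate a time-lapse series with scheduled relocalization
#'
#' Uses one fixed cell population across frames and re-renders each frame
#' with per-frame membrane fractions, emulating membrane-to-cytosol
#' dispersal and return during the cell cycle. No growth or division is
#' modelled; the schedule supplies the localization dynamics.
#'
#' @param config a [SimulationConfig-class].
#' @param schedule numeric matrix, cells x frames, membrane fraction of
#'   each cell in each frame; or a vector applied to every cell.
#' @param frameIntervalMin minutes between frames (metadata only here).
#' @param outDir optional directory; writes a multi-page
#'   \code{image.tif}, per-frame \code{outlines.json} and
#'   \code{truth.csv} with a frame column.
#' @return Invisibly, list(frames = list of matrices,
#'   outlines = list of [OutlineSet-class], truth = data.frame,
#'   frameIntervalMin).
#' @export
simulateTimelapse <- function(config, schedule, frameIntervalMin = 3,
                              outDir = NULL) {
  geoms <- samplePopulation(config)
  n <- length(geoms)
  if (is.vector(schedule))
    schedule <- matrix(rep(schedule, each = n), nrow = n)
  stopifnot(nrow(schedule) == n)
  nFrames <- ncol(schedule)
  frames <- vector("list", nFrames)
  outl <- vector("list", nFrames)
  truth <- NULL
  for (k in seq_len(nFrames)) {
    gk <- lapply(seq_len(n), function(i) {
      f <- schedule[i, k]
      mode <- if (f <= 0) "cytosolic" else if (f >= 1) "membrane"
              else "mixed"
      cellGeometry(geoms[[i]]@id, geoms[[i]]@center, geoms[[i]]@lengthPx,
                   geoms[[i]]@widthPx, geoms[[i]]@orientationRad, mode, f)
    })
    img <- renderPopulation(gk, config)
    frames[[k]] <- applyOptics(img, config@psfSigmaPx, config@background,
                               config@noise,
                               seed = stageSeed(config@seed,
                                                paste0("optics_f", k)))
    outl[[k]] <- outlineSet(lapply(gk, outlineOf), config@pixelSizeUm,
                            frame = k - 1L)
    truth <- rbind(truth, data.frame(
      cell_id = vapply(gk, cellId, character(1)),
      frame = k - 1L,
      mode = vapply(gk, localizationMode, character(1)),
      membrane_fraction = schedule[, k],
      length_px = vapply(gk, cellLengthPx, numeric(1)),
      stringsAsFactors = FALSE))
  }
  res <- list(frames = frames, outlines = outl, truth = truth,
              frameIntervalMin = frameIntervalMin)
  if (!is.null(outDir)) {
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                           showWarnings = FALSE)
    if (!ok) .mlErr("io_error", sprintf("cannot create '%s'", outDir))
    writeImageTiff(frames, file.path(outDir, "image.tif"))
    writeOutlines(outl, file.path(outDir, "outlines.json"))
    utils::write.csv(truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(res)
}

#' Serialize / restore a SimulationConfig
#'
#' Plain-list forms used for YAML round-tripping in run directories.
#'
#' @param config a [SimulationConfig-class].
#' @return \code{configToList}: a named list; \code{configFromList}: a
#'   [SimulationConfig-class].
#' @export
configToList <- function(config) {
  list(canvas_shape = as.integer(config@canvasShape),
       n_cells = config@nCells,
       length_dist = config@lengthDist,
       width_px = config@widthPx,
       pixel_size_um = config@pixelSizeUm,
       shell_thickness_px = config@shellThicknessPx,
       amplitude = config@amplitude,
       background = config@background,
       psf_sigma_px = config@psfSigmaPx,
       noise = config@noise,
       population_membrane_prob = config@populationMembraneProb,
       seed = config@seed,
       max_attempts = config@maxAttempts,
       margin_px = config@marginPx)
}

#' @rdname configToList
#' @param x a named list as produced by \code{configToList} (missing
#'   entries fall back to the defaults of [simConfig()]).
#' @export
configFromList <- function(x) {
  args <- list(
    canvasShape = x$canvas_shape, nCells = x$n_cells,
    lengthDist = x$length_dist, widthPx = x$width_px,
    pixelSizeUm = x$pixel_size_um,
    shellThicknessPx = x$shell_thickness_px,
    amplitude = x$amplitude, background = x$background,
    psfSigmaPx = x$psf_sigma_px, noise = x$noise,
    populationMembraneProb = x$population_membrane_prob,
    seed = x$seed, maxAttempts = x$max_attempts, marginPx = x$margin_px)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(simConfig, args)
}
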