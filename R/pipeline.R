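#' @include simulate.R measure.R popstats.R segment.R io.R
NULL

#' Run a reproducible simulate/segment/quantify/report pipeline
#'
#' Executes the requested stages in order into a run directory, writing
#' every intermediate artifact, a structured log (one JSON record per
#' stage) and the resolved configuration that reproduces the run.
#' Re-running with the same resolved configuration reproduces all CSV and
#' JSON outputs byte-identically.
#'
#' The configuration is a named list (or path to a YAML file) with
#' entries: \code{stages} (subset of "simulate", "segment", "quantify",
#' "report" in pipeline order), \code{sim} (a [simConfig()] list form,
#' see [configToList()]), \code{quantify} (ring_width_px,
#' background_mode, background_value, threshold, outlines = "truth" or
#' "segmented"), \code{segment} (sigma, min_area) and \code{seed}
#' (fanned out deterministically to per-stage seeds by [stageSeed()],
#' overriding the sim seed).
#'
#' @param config named list or path to a YAML file.
#' @param outDir run directory (created if needed).
#' @return Invisibly, a list with the stage artifacts (config, image,
#'   outlines, measurements, summary) and the log.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "quantify", "report")
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) .mlErr("io_error", sprintf("cannot create '%s'", outDir))
  log <- list()
  note <- function(stage, ...) {
    rec <- list(stage = stage, ...,
                elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    log[[length(log) + 1L]] <<- rec
    rec
  }
  simCfg <- configFromList(if (is.null(config$sim)) list() else config$sim)
  if (!is.null(config$seed))
    simCfg@seed <- as.integer(config$seed)
  resolved <- list(stages = stages, sim = configToList(simCfg),
                   quantify = config$quantify, segment = config$segment,
                   seed = simCfg@seed)
  yaml::write_yaml(resolved, file.path(outDir, "config.yaml"))

  qc <- config$quantify
  params <- compartmentParams(
    ringWidthPx = if (is.null(qc$ring_width_px)) 4L else qc$ring_width_px,
    backgroundMode = if (is.null(qc$background_mode)) "none"
                     else qc$background_mode,
    backgroundValue = if (is.null(qc$background_value)) 0
                      else qc$background_value,
    threshold = if (is.null(qc$threshold)) 0.7 else qc$threshold)

  image <- NULL; os <- NULL; meas <- NULL; summ <- NULL
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "simulate") {
      cohort <- simulateCohort(simCfg, outDir = outDir)
      image <- cohort$image
      if (is.null(qc$outlines) || qc$outlines == "truth")
        os <- cohort$outlines
      note("simulate", n_cells = nCells(simCfg), seed = simCfg@seed)
    } else if (stage == "segment") {
      if (is.null(image)) {
        p <- file.path(outDir, "image.tif")
        if (!file.exists(p))
          .mlErr("missing_input",
                 "segment: no image; run simulate first or provide image.tif")
        image <- readImageTiff(p)
        if (is.list(image)) image <- image[[1L]]
      }
      sg <- config$segment
      os <- segmentStandIn(image,
        sigma = if (is.null(sg$sigma)) 2 else sg$sigma,
        minArea = if (is.null(sg$min_area)) 50 else sg$min_area,
        pixelSizeUm = pixelSize(simCfg))
      writeOutlines(os, file.path(outDir, "outlines_segmented.json"))
      note("segment", n_outlines = nCells(os))
    } else if (stage == "quantify") {
      if (is.null(image) || is.null(os))
        .mlErr("missing_input",
               "quantify: needs an image and an outlines source")
      meas <- measureCells(image, os, params)
      writeCellsCsv(meas, file.path(outDir, "cells.csv"))
      note("quantify", n_cells = nrow(meas),
           n_flagged = sum(nzchar(meas$flags)))
    } else if (stage == "report") {
      if (is.null(meas)) .mlErr("missing_input", "report: needs cells")
      summ <- summarizePopulation(meas, params@threshold)
      writeSummaryJson(summ, file.path(outDir, "summary.json"))
      rl <- ratioVsLength(meas)
      utils::write.csv(rl, file.path(outDir, "ratio_length.csv"),
                       row.names = FALSE, quote = FALSE)
      note("report", n_membrane = summ@nMembrane,
           n_cytosolic = summ@nCytosolic,
           fraction_membrane = fractionMembrane(summ))
    } else {
      .mlErr("missing_input", sprintf("unknown stage '%s'", stage))
    }
  }
  jsonlite::write_json(log, file.path(outDir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = resolved, image = image, outlines = os,
                 measurements = meas, summary = summ, log = log))
}

#' Emit the canonical small validation fixtures
#'
#' Writes six named fixtures, each with an expected-output sidecar
#' computed by a method independent of the main code path: the 12x12
#' square-mask compartment case (sidecar: brute-force Chebyshev
#' distance-transform ring/interior sizes), the uniform-image case
#' (sidecar ratio 1 by the equal-means identity), one noiseless membrane
#' and one noiseless cytosolic cell (sidecar: ratios recomputed directly
#' from profile formulas and a distance-transform ring), a 20-cell mixed
#' cohort (sidecar: ground-truth labels), and a 7-frame ratio trace
#' (sidecar: episode from the run-length definition).
#'
#' @param outDir writable output directory.
#' @return Invisibly, character vector of the six fixture directories.
#' @export
makeFixtures <- function(outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) .mlErr("io_error", sprintf("cannot create '%s'", outDir))
  fdir <- function(name) {
    d <- file.path(outDir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  sidecar <- function(d, x)
    jsonlite::write_json(x, file.path(d, "expected.json"),
                         auto_unbox = TRUE, digits = NA)

  # brute-force Chebyshev distance to the exterior (independent of the
  # erosion implementation)
  chebRing <- function(mask, w) {
    nr <- nrow(mask); nc <- ncol(mask)
    out <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      i0 <- i - w; i1 <- i + w; j0 <- j - w; j1 <- j + w
      nearBorder <- i0 < 1 || i1 > nr || j0 < 1 || j1 > nc
      sub <- mask[max(1, i0):min(nr, i1), max(1, j0):min(nc, j1)]
      out[i, j] <- nearBorder || any(!sub)
    }
    out
  }

  # 1: 12x12 solid square in a 20x20 grid
  d <- fdir("square_mask")
  sq <- cellOutline("sq", rbind(c(3.5, 3.5), c(15.5, 3.5),
                                c(15.5, 15.5), c(3.5, 15.5)))
  writeOutlines(outlineSet(list(sq), 1), file.path(d, "outlines.json"))
  mask <- matrix(FALSE, 20, 20); mask[5:16, 5:16] <- TRUE
  ring <- chebRing(mask, 4)
  sidecar(d, list(mask_px = sum(mask), ring_px = sum(ring),
                  interior_px = sum(mask & !ring)))

  # 2: uniform image
  d <- fdir("uniform_image")
  img <- matrix(5, 64, 64)
  writeImageTiff(img, file.path(d, "image.tif"))
  g <- cellGeometry("u1", c(31, 31), 40, 15)
  writeOutlines(outlineSet(list(outlineOf(g)), 1),
                file.path(d, "outlines.json"))
  sidecar(d, list(ratio = 1.0, class = "membrane"))

  # 3 & 4: one noiseless membrane / cytosolic cell; sidecar ratio from
  # the closed-form profiles + distance-transform ring (no blur)
  oneCell <- function(name, mode) {
    d <- fdir(name)
    g <- cellGeometry(name, c(40, 40), 45, 15, 0.4, mode)
    cfg <- simConfig(canvasShape = c(81L, 81L), nCells = 0L,
                     noise = list(poisson = FALSE, readSd = 0),
                     background = 0, psfSigmaPx = 0)
    img <- renderCell(g, cfg@amplitude, cfg@shellThicknessPx,
                      matrix(0, 81, 81))
    writeImageTiff(img, file.path(d, "image.tif"))
    o <- outlineOf(g)
    writeOutlines(outlineSet(list(o), 1), file.path(d, "outlines.json"))
    m <- rasterizeOutline(o, c(81L, 81L))
    rg <- chebRing(m, 4)
    ratio <- mean(img[rg]) / mean(img[m & !rg])
    sidecar(d, list(mode = mode, ratio = ratio,
                    class = classifyRatio(ratio)))
    d
  }
  oneCell("membrane_cell", "membrane")
  oneCell("cytosolic_cell", "cytosolic")

  # 5: 20-cell mixed cohort with ground truth
  d <- fdir("mixed_cohort")
  cfg <- simConfig(canvasShape = c(512L, 512L), nCells = 20L,
                   populationMembraneProb = 0.5, seed = 20L)
  cohort <- simulateCohort(cfg, outDir = d)
  sidecar(d, list(n_cells = 20L,
                  n_membrane_true = sum(cohort$truth$mode == "membrane")))

  # 6: 7-frame worked ratio trace
  d <- fdir("timelapse_trace")
  trace <- c(0.9, 0.9, 0.6, 0.65, 0.6, 0.9, 0.95)
  utils::write.csv(data.frame(frame = 0:6, ratio = trace),
                   file.path(d, "trace.csv"), row.names = FALSE)
  # expected episode from the run-length definition, worked by hand:
  # frames 2..4 are <= 0.7 (a 3-frame run), 3-min spacing
  sidecar(d, list(n_episodes = 1L, onset_min = 6, duration_min = 9))

  invisible(file.path(outDir,
    c("square_mask", "uniform_image", "membrane_cell", "cytosolic_cell",
      "mixed_cohort", "timelapse_trace")))
}
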