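test_that("population sampling respects counts, modes and determinism", {
  cfg0 <- simConfig(nCells = 0L, seed = 3)
  expect_identical(samplePopulation(cfg0), list())

  cfg <- simConfig(nCells = 25L, canvasShape = c(512L, 512L), seed = 5,
                   populationMembraneProb = 0.5)
  pop1 <- samplePopulation(cfg)
  pop2 <- samplePopulation(cfg)
  expect_length(pop1, 25L)
  expect_identical(pop1, pop2)

  # lengths within the configured distribution's support
  lens <- vapply(pop1, cellLengthPx, numeric(1))
  expect_true(all(lens >= 30 & lens <= 60))

  # footprints pairwise disjoint: total rendered support equals the sum
  # of per-cell supports
  masks <- lapply(pop1, function(g)
    rasterizeOutline(outlineOf(g), c(512L, 512L)))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_lte(max(total), 1L)
})

test_that("membrane-mode draws follow Bernoulli(p) at n = 250", {
  cfg <- simConfig(nCells = 250L, canvasShape = c(1024L, 1024L),
                   populationMembraneProb = 0.7, seed = 7)
  pop <- samplePopulation(cfg)
  nMem <- sum(vapply(pop, localizationMode, character(1)) == "membrane")
  # 99.9% binomial band for n=250, p=0.7 (qbinom: 151..199)
  expect_gte(nMem, 150)
  expect_lte(nMem, 200)
})

test_that("a crowded canvas fails with canvas_too_crowded", {
  cfg <- simConfig(nCells = 40L, canvasShape = c(160L, 160L), seed = 1,
                   maxAttempts = 25L)
  expect_error(samplePopulation(cfg), class = "canvas_too_crowded")
})

test_that("cytosolic render is the normalized chord-depth projection", {
  # width 16 so that r/2 and r land on pixel centers along the y axis
  g <- cellGeometry("c", c(40, 40), 48, 16, 0, "cytosolic")
  img <- renderCytosolic(g, 1000, matrix(0, 81, 81))
  at <- function(x, y) img[y + 1, x + 1]
  expect_equal(at(40, 40), 1000)                      # on-axis mid-cell
  expect_equal(at(40, 44), 1000 * sqrt(3) / 2)        # d = r/2
  expect_equal(at(40, 48), 0)                         # d = r
  expect_equal(at(40, 60), 0)                         # far outside
  # silhouette support: zero wherever the axis distance is >= r
  d <- memloc:::.axisDistance(g, 0:80, 0:80)
  expect_true(all(img[d >= 8] == 0))
  expect_true(all(img[d < 8] > 0))
})

test_that("membrane render is edge-peaked with shell path-length profile", {
  g <- cellGeometry("m", c(40, 40), 48, 16, 0, "membrane")
  t <- 2; r <- 8
  img <- renderMembrane(g, 1000, t, matrix(0, 81, 81))
  at <- function(x, y) img[y + 1, x + 1]
  # scaling cancels in ratios: centre/path-peak = 2t / 2 sqrt(2rt - t^2)
  expect_equal(at(40, 40) / at(40, 46), 2 * t / (2 * sqrt(2 * r * t - t^2)),
               tolerance = 1e-12)
  expect_equal(at(40, 48), 0)  # d = r, outside
  # total signal matches the cytosolic render (per-cell normalization)
  cyt <- renderCytosolic(g, 1000, matrix(0, 81, 81))
  expect_equal(sum(img), sum(cyt), tolerance = 1e-9)
  # edge-peaked: maximum farther from the axis than the cytosolic max
  d <- memloc:::.axisDistance(g, 0:80, 0:80)
  expect_gt(d[which.max(img)], d[which.max(cyt)])
  expect_error(renderMembrane(g, 1000, 9, matrix(0, 81, 81)),
               class = "shell_too_thick")
})

test_that("membrane profile peaks nearer the edge for random geometries", {
  set.seed(11)
  for (k in 1:8) {
    W <- runif(1, 10, 18)
    g <- cellGeometry("g", c(50, 50), runif(1, W, 70), W,
                      runif(1, 0, pi), "membrane")
    t <- runif(1, 0.3, W / 8)  # t <= r/4
    mem <- renderMembrane(g, 1000, t, matrix(0, 101, 101))
    cyt <- renderCytosolic(g, 1000, matrix(0, 101, 101))
    d <- memloc:::.axisDistance(g, 0:100, 0:100)
    expect_gt(d[which.max(mem)], d[which.max(cyt)])
  }
})

test_that("optics applies blur, background and reproducible noise", {
  img <- matrix(0, 64, 64); img[30:34, 30:34] <- 50
  # identity blur: every pixel raised by exactly the background
  out <- applyOptics(img, 0, 7, list(poisson = FALSE, readSd = 0), 1)
  expect_equal(out, img + 7)
  # blur conserves mass for interior sources (0.1%)
  out <- applyOptics(img, 2, 0, list(poisson = FALSE, readSd = 0), 1)
  expect_equal(sum(out), sum(img), tolerance = 1e-3)
  # determinism of the noisy path
  n1 <- applyOptics(img, 2, 100, list(poisson = TRUE, readSd = 20), 42)
  n2 <- applyOptics(img, 2, 100, list(poisson = TRUE, readSd = 20), 42)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
  expect_error(applyOptics(img, -1, 0, list(poisson = FALSE, readSd = 0), 1),
               class = "invalid_optics_param")
})

test_that("ground-truth outlines trace the spherocylinder silhouette", {
  g <- cellGeometry("c", c(50, 50), 40, 15, 0.7, "cytosolic")
  o <- outlineOf(g, 64L)
  expect_equal(nrow(vertices(o)), 64L)
  # Feret diameter of a spherocylinder equals its total length
  expect_equal(max(dist(vertices(o))), 40, tolerance = 1)
  # degenerate sphere: polygon approximates a circle of diameter width
  gs <- cellGeometry("s", c(50, 50), 15, 15, 0, "cytosolic")
  vs <- vertices(outlineOf(gs, 64L))
  rad <- sqrt((vs[, 1] - 50)^2 + (vs[, 2] - 50)^2)
  expect_true(all(abs(rad - 7.5) < 0.6))
})

test_that("simulateCohort writes a consistent, reproducible artifact set", {
  cfg <- simConfig(nCells = 5L, canvasShape = c(320L, 320L), seed = 9,
                   populationMembraneProb = 0)
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  simulateCohort(cfg, d1)
  simulateCohort(cfg, d2)
  os <- readOutlines(file.path(d1, "outlines.json"))
  expect_equal(nCells(os), 5L)
  truth <- read.csv(file.path(d1, "truth.csv"))
  expect_equal(nrow(truth), 5L)
  expect_true(all(truth$mode == "cytosolic"))  # p = 0 passes through
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  img <- readImageTiff(file.path(d1, "image.tif"))
  expect_equal(dim(img), c(320L, 320L))
})
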