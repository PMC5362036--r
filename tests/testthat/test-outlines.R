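test_that("outline JSON round trip preserves ids, order and vertices", {
  o1 <- cellOutline("c1", rbind(c(1.123456, 2.5), c(8.2, 2.5), c(4, 9.75)))
  o2 <- outlineOf(cellGeometry("c2", c(30, 30), 40, 15, 0.3))
  path <- tempfile(fileext = ".json")
  writeOutlines(outlineSet(list(o1, o2), 0.066), path)
  back <- readOutlines(path)
  expect_equal(pixelSize(back), 0.066)
  ids <- vapply(outlines(back), cellId, character(1))
  expect_identical(ids, c("c1", "c2"))
  expect_equal(vertices(outlines(back)[[1]]), vertices(o1),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vertices(outlines(back)[[2]]), vertices(o2),
               tolerance = 1e-6, ignore_attr = TRUE)

  # empty set round-trips
  writeOutlines(outlineSet(list(), 1), path)
  expect_length(outlines(readOutlines(path)), 0L)
})

test_that("malformed outline files are rejected naming the offender", {
  path <- tempfile(fileext = ".json")
  doc <- list(pixel_size_um = 1, cells = list(
    list(id = "c1", vertices = list(c(0, 0), c(4, 0), c(0, 4))),
    list(id = "c1", vertices = list(c(9, 9), c(12, 9), c(9, 12)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  err <- tryCatch(readOutlines(path), error = function(e) e)
  expect_s3_class(err, "invalid_outline_file")
  expect_match(conditionMessage(err), "c1")

  writeLines("{not json", path)
  expect_error(readOutlines(path), class = "invalid_outline_file")

  # self-intersecting polygon (bow-tie)
  doc <- list(pixel_size_um = 1, cells = list(
    list(id = "bow", vertices = list(c(0, 0), c(4, 4), c(4, 0), c(0, 4)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(readOutlines(path), class = "invalid_outline_file")
})

test_that("rasterization follows the pixel-center boundary-inclusive rule", {
  sq <- cellOutline("sq", rbind(c(-0.5, -0.5), c(11.5, -0.5),
                                c(11.5, 11.5), c(-0.5, 11.5)))
  mask <- rasterizeOutline(sq, c(20L, 20L))
  expect_equal(sum(mask), 144L)  # the 12x12 block of centers 0..11
  expect_true(all(mask[1:12, 1:12]))

  # sub-pixel triangle containing only the center of pixel (x=5, y=5)
  tri <- cellOutline("tri", rbind(c(4.8, 4.8), c(5.3, 4.9), c(5.0, 5.3)))
  m <- rasterizeOutline(tri, c(12L, 12L))
  expect_equal(which(m, arr.ind = TRUE), cbind(row = 6L, col = 6L),
               ignore_attr = TRUE)

  # boundary-inclusive: a pixel center exactly on an edge belongs
  edge <- cellOutline("e", rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6)))
  m <- rasterizeOutline(edge, c(10L, 10L))
  expect_true(m[3, 3])  # vertex (2,2) itself
  expect_true(m[3, 5])  # on the y = 2 edge

  expect_error(
    rasterizeOutline(cellOutline("o", rbind(c(-2, 0), c(5, 0), c(0, 5))),
                     c(10L, 10L)),
    class = "outline_out_of_bounds")
})

test_that("rasterized simulated cells match the analytic silhouette area", {
  for (seed in 1:3) {
    set.seed(seed)
    L <- runif(1, 30, 60); W <- 15
    g <- cellGeometry("g", c(50, 50), L, W, runif(1, 0, pi), "cytosolic")
    mask <- rasterizeOutline(outlineOf(g), c(101L, 101L))
    expect_equal(sum(mask), spherocylinderArea(L, W), tolerance = 0.05)
  }
})

test_that("rasterization is monotone under polygon containment", {
  outer <- cellOutline("o", rbind(c(2, 2), c(14, 3), c(13, 13), c(3, 12)))
  inner <- cellOutline("i", rbind(c(5, 5), c(11, 5.5), c(10, 10), c(5, 9)))
  mo <- rasterizeOutline(outer, c(20L, 20L))
  mi <- rasterizeOutline(inner, c(20L, 20L))
  expect_true(all(mo[mi]))
})

test_that("masks of valid geometries are non-empty and 8-connected", {
  set.seed(4)
  for (k in 1:6) {
    W <- runif(1, 3, 16)
    g <- cellGeometry("g", c(40, 40), runif(1, W, 60), W,
                      runif(1, 0, pi), "cytosolic")
    mask <- rasterizeOutline(outlineOf(g), c(81L, 81L))
    expect_gt(sum(mask), 0)
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    expect_equal(max(lab), 1)
  }
})

test_that("cell length is the Feret diameter scaled by pixel size", {
  g <- cellGeometry("g", c(40, 40), 40, 15, 0.25, "cytosolic")
  o <- outlineOf(g)
  expect_equal(cellLength(o, 0.066), 2.64, tolerance = 0.066)
  expect_equal(cellLength(o, 1), cellLength(o, 0.5) * 2)

  # circle of diameter 15 px
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cellOutline("c", cbind(20 + 7.5 * cos(ang), 20 + 7.5 * sin(ang)))
  expect_equal(cellLength(circ, 0.066), 0.99, tolerance = 0.03)

  # rotation/translation invariance to 1 px discretization
  lens <- vapply(c(0, 0.5, 1.1, 2.3), function(th)
    cellLength(outlineOf(cellGeometry("g", c(40 + th, 38 - th), 40, 15,
                                      th, "cytosolic"))), numeric(1))
  expect_lt(diff(range(lens)), 1)
})

test_that("the stand-in segmenter recovers simulated cells", {
  blank <- matrix(3, 64, 64)
  expect_equal(nCells(segmentStandIn(blank)), 0L)

  one <- renderOneCell("membrane")
  seg <- segmentStandIn(one$image, sigma = 2, minArea = 50)
  expect_equal(nCells(seg), 1L)

  cfg <- simConfig(nCells = 10L, canvasShape = c(512L, 512L), seed = 2,
                   populationMembraneProb = 0.5,
                   noise = list(poisson = FALSE, readSd = 0))
  cohort <- simulateCohort(cfg)
  seg <- segmentStandIn(cohort$image, sigma = 2, minArea = 100,
                        pixelSizeUm = pixelSize(cohort$outlines))
  expect_equal(nCells(seg), 10L)
  shape <- dim(cohort$image)
  segMasks <- lapply(outlines(seg), rasterizeOutline, shape = shape)
  for (o in outlines(cohort$outlines)) {
    gt <- rasterizeOutline(o, shape)
    iou <- max(vapply(segMasks, function(m)
      sum(m & gt) / sum(m | gt), numeric(1)))
    expect_gte(iou, 0.8)
  }
})
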