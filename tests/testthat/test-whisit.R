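test_that("membrane ring equals the brute-force Chebyshev definition", {
  # frozen worked case: 12x12 solid square, ring width 4
  mask <- matrix(FALSE, 20, 20); mask[5:16, 5:16] <- TRUE
  ring <- membraneRing(mask, 4L)
  expect_equal(sum(ring), 128L)
  interior <- cytosolInterior(mask, ring)
  expect_equal(sum(interior), 16L)
  expect_identical(ring, bruteForceRing(mask, 4L))

  # width 0: empty ring, interior is the whole mask
  r0 <- membraneRing(mask, 0L)
  expect_false(any(r0))
  expect_identical(cytosolInterior(mask, r0), mask)

  # 5x5 square, width 4: the ring is the whole mask, no interior left
  m5 <- matrix(FALSE, 9, 9); m5[3:7, 3:7] <- TRUE
  r5 <- membraneRing(m5, 4L)
  expect_identical(r5, m5)
  expect_error(cytosolInterior(m5, r5), class = "cell_too_thin")
})

test_that("erosion ring matches the distance-transform oracle on random masks", {
  set.seed(99)
  for (k in 1:200) {
    mask <- randomBlobMask()
    w <- sample(1:4, 1)
    expect_identical(membraneRing(mask, w), bruteForceRing(mask, w))
  }
})

test_that("compartments exactly partition the cell mask", {
  set.seed(7)
  for (k in 1:25) {
    mask <- randomBlobMask(24, 24)
    ring <- membraneRing(mask, 4L)
    interior <- tryCatch(cytosolInterior(mask, ring),
                         cell_too_thin = function(e) mask & FALSE)
    expect_false(any(ring & interior))
    expect_identical(ring | interior, mask)
    expect_true(all(mask[ring]))
  }
})

test_that("mean intensity handles background modes", {
  img <- matrix(5, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  expect_equal(meanIntensity(img, mask), 5)
  img2 <- matrix(0, 8, 8); img2[3:5, 3] <- c(2, 4, 6)
  m3 <- matrix(FALSE, 8, 8); m3[3:5, 3] <- TRUE
  expect_equal(meanIntensity(img2, m3), 4)
  pc <- compartmentParams(backgroundMode = "constant", backgroundValue = 3)
  expect_equal(meanIntensity(img, mask, pc), 2)
  expect_error(meanIntensity(img, img > 99), class = "empty_compartment")
})

test_that("classification splits strictly above the threshold", {
  expect_identical(classifyRatio(0.70), "cytosolic")
  expect_identical(classifyRatio(0.71), "membrane")
  expect_identical(classifyRatio(0), "cytosolic")
  expect_identical(classifyRatio(c(1.2, NA, 0.3)),
                   c("membrane", NA, "cytosolic"))
  expect_identical(classifyRatio(0.9, threshold = 1), "cytosolic")
})

test_that("a uniform image gives ratio exactly 1", {
  img <- matrix(5, 81, 81)
  o <- outlineOf(cellGeometry("u", c(40, 40), 45, 15, 0.2))
  m <- measureCell(img, o, compartmentParams(), 1)
  expect_equal(m$ratio, 1)
  expect_identical(m$class, "membrane")  # 1.0 > 0.7
  expect_identical(m$flags, "")
})

test_that("noiseless control cells fall on the right side of 0.7", {
  pp <- compartmentParams()
  mem <- renderOneCell("membrane")
  rMem <- measureCell(mem$image, mem$outline, pp, 1)$ratio
  expect_gt(rMem, 1)
  cyt <- renderOneCell("cytosolic")
  rCyt <- measureCell(cyt$image, cyt$outline, pp, 1)$ratio
  expect_lt(rCyt, 0.7)
})

test_that("the ratio is invariant to intensity scaling", {
  pp <- compartmentParams()
  one <- renderOneCell("mixed", membraneFraction = 0.4)
  r1 <- measureCell(one$image, one$outline, pp, 1)$ratio
  for (c_ in c(0.01, 3, 1e4)) {
    rc <- measureCell(one$image * c_, one$outline, pp, 1)$ratio
    expect_equal(rc, r1, tolerance = 1e-9)
  }
})

test_that("the ratio increases strictly with the membrane fraction", {
  pp <- compartmentParams()
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  ratios <- vapply(fs, function(f) {
    one <- renderOneCell("mixed", membraneFraction = f)
    measureCell(one$image, one$outline, pp, 1)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("degenerate cells are flagged, not dropped or made infinite", {
  # thin cell: ring swallows everything
  img <- matrix(10, 30, 30)
  thin <- cellOutline("t", rbind(c(5, 12), c(24, 12), c(24, 17), c(5, 17)))
  m <- measureCell(img, thin, compartmentParams(), 1)
  expect_match(m$flags, "too_thin")
  expect_true(is.na(m$ratio))
  # border-touching cell (mask includes the x = 0 image column)
  touch <- cellOutline("b", rbind(c(-0.4, 8), c(15, 8), c(15, 16),
                                  c(-0.4, 16)))
  mb <- measureCell(matrix(10, 25, 40), touch, compartmentParams(), 1)
  expect_match(mb$flags, "border")
  # zero cytosol mean after subtraction: undefined, never infinite
  pc <- compartmentParams(backgroundMode = "constant", backgroundValue = 10)
  big <- outlineOf(cellGeometry("z", c(14, 14), 22, 12, 0.3))
  mz <- measureCell(matrix(10, 29, 29), big, pc, 1)
  expect_match(mz$flags, "undefined_ratio")
  expect_true(is.na(mz$ratio))
})

test_that("measureCells measures every outline of a frame", {
  cfg <- simConfig(nCells = 4L, canvasShape = c(320L, 320L), seed = 12,
                   populationMembraneProb = 1)
  cohort <- simulateCohort(cfg)
  pp <- compartmentParams(backgroundMode = "constant",
                          backgroundValue = 100)
  meas <- measureCells(cohort$image, cohort$outlines, pp)
  expect_equal(nrow(meas), 4L)
  expect_identical(meas$cell_id, cohort$truth$cell_id)
  expect_true(all(meas$class == "membrane"))
  expect_equal(meas$length_um, cohort$truth$length_px * 0.066,
               tolerance = 0.07)
})

test_that("dispersal episodes follow the two-frame debounce rule", {
  ep <- dispersalEpisodes(c(0.9, 0.9, 0.6, 0.65, 0.6, 0.9, 0.95),
                          frameIntervalMin = 3)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$onset_min, 6)
  expect_equal(ep$duration_min, 9)
  expect_equal(ep$first_frame, 2L)
  expect_equal(ep$last_frame, 4L)

  expect_equal(nrow(dispersalEpisodes(rep(0.9, 6))), 0L)
  # a single isolated cytosolic frame is debounced away
  expect_equal(nrow(dispersalEpisodes(c(0.9, 0.9, 0.5, 0.9, 0.9))), 0L)
  # NA gaps break runs
  expect_equal(nrow(dispersalEpisodes(c(0.6, NA, 0.6, 0.9))), 0L)
  # two separate episodes stay separate and time-ordered
  ep2 <- dispersalEpisodes(c(0.5, 0.5, 0.9, 0.9, 0.6, 0.6, 0.6),
                           frameIntervalMin = 3)
  expect_equal(ep2$onset_min, c(0, 12))
  expect_equal(ep2$duration_min, c(6, 9))
})

test_that("image-based time series yields per-cell episodes and gap flags", {
  cfg <- simConfig(nCells = 3L, canvasShape = c(300L, 300L), seed = 21,
                   populationMembraneProb = 1)
  # all cells: membrane for 2 frames, cytosolic for 3, membrane for 2
  sched <- c(1, 1, 0, 0, 0, 1, 1)
  tl <- simulateTimelapse(cfg, sched, frameIntervalMin = 3)
  pp <- compartmentParams(backgroundMode = "constant",
                          backgroundValue = 100)
  res <- measureTimeseries(tl$frames, tl$outlines, pp,
                           frameIntervalMin = 3)
  expect_equal(nrow(res$measurements), 21L)
  expect_equal(nrow(res$episodes), 3L)
  expect_true(all(res$episodes$onset_min == 6))
  expect_true(all(res$episodes$duration_min == 9))

  # removing one cell from one frame breaks its run and flags the gap
  os <- tl$outlines
  keep <- outlines(os[[4]])[-1]
  os[[4]] <- outlineSet(keep, pixelSize(os[[4]]), frame = 3L)
  res2 <- measureTimeseries(tl$frames, os, pp, frameIntervalMin = 3)
  gone <- outlines(tl$outlines[[4]])[[1]]
  expect_true(all(grepl("gap",
    res2$measurements$flags[res2$measurements$cell_id == cellId(gone)])))
  expect_equal(nrow(res2$episodes[res2$episodes$cell_id == cellId(gone), ]),
               0L)
})
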