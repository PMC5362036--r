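# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (erosion, rendering) so that agreement is a
# two-route check, not a tautology.

# Brute-force Chebyshev distance-transform ring: a mask pixel is in the
# ring iff some pixel within the (2w+1)^2 Chebyshev neighbourhood is
# exterior (out-of-image counts as exterior).
bruteForceRing <- function(mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nearBorder <- i - w < 1 || i + w > nr || j - w < 1 || j + w > nc
    sub <- mask[max(1, i - w):min(nr, i + w),
                max(1, j - w):min(nc, j + w)]
    out[i, j] <- nearBorder || any(!sub)
  }
  out
}

# Random small blob masks (unions of discs on a small grid), non-empty.
randomBlobMask <- function(nr = 16, nc = 16) {
  repeat {
    mask <- matrix(FALSE, nr, nc)
    for (k in seq_len(sample(1:3, 1))) {
      ci <- runif(1, 2, nr - 1); cj <- runif(1, 2, nc - 1)
      r <- runif(1, 1, 5)
      ii <- matrix(rep(seq_len(nr), nc), nr, nc)
      jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      mask <- mask | ((ii - ci)^2 + (jj - cj)^2 <= r^2)
    }
    if (any(mask)) return(mask)
  }
}

# Noiseless single-cell scene at the generator's default physics.
renderOneCell <- function(mode, membraneFraction = NULL, shape = c(81, 81),
                          lengthPx = 45, widthPx = 15, theta = 0.4,
                          psfSigmaPx = 2, background = 0) {
  g <- cellGeometry("one", c((shape[2] - 1) / 2, (shape[1] - 1) / 2),
                    lengthPx, widthPx, theta, mode, membraneFraction)
  img <- renderCell(g, 1000, 1.5, matrix(0, shape[1], shape[2]))
  img <- applyOptics(img, psfSigmaPx, background,
                     noise = list(poisson = FALSE, readSd = 0), seed = 1)
  list(geometry = g, image = img, outline = outlineOf(g))
}

# Analytic silhouette area of a spherocylinder: body rectangle plus the
# two cap half-discs.
spherocylinderArea <- function(lengthPx, widthPx)
  (lengthPx - widthPx) * widthPx + pi * (widthPx / 2)^2
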