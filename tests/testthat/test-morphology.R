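test_that("region statistics match hand arithmetic on tiny regions", {
  ## constant 4x4 region of 2.0
  r <- matrix(2, 4, 4)
  s <- region_statistics(r)
  expect_equal(unname(s["StdValue"]), 0)
  expect_equal(unname(s["IQRValue"]), 0)
  expect_equal(unname(s["EntropyValue"]), log(16))
  expect_equal(unname(s["EnergyValue"]), 64)
  expect_equal(unname(s["CentroidX"]), 1.5)
  expect_equal(unname(s["CentroidY"]), 1.5)

  ## 2x2 region [[1,2],[3,4]] (rows of the matrix)
  r2 <- rbind(c(1, 2), c(3, 4))
  s2 <- region_statistics(r2)
  expect_equal(unname(s2["MeanValue"]), 2.5)
  expect_equal(unname(s2["MedianValue"]), 2.5)
  expect_equal(unname(s2["EnergyValue"]), 30)
  expect_equal(unname(s2["PeakValue"]), 4)
  ## intensity-weighted X centroid: (1*0 + 2*1 + 3*0 + 4*1) / 10
  expect_equal(unname(s2["CentroidX"]), 0.6)
  expect_equal(unname(s2["CentroidY"]), (3 + 4) / 10)

  ## single nonzero cell: zero entropy, centroid at that cell
  r3 <- matrix(0, 3, 3); r3[2, 3] <- 7
  s3 <- region_statistics(r3)
  expect_equal(unname(s3["EntropyValue"]), 0)
  expect_equal(unname(s3["CentroidX"]), 2)
  expect_equal(unname(s3["CentroidY"]), 1)

  ## all-zero region flags entropy/centroids
  s0 <- region_statistics(matrix(0, 3, 3))
  expect_true(is.na(s0["EntropyValue"]))
  expect_true(is.na(s0["CentroidX"]))

  ## frequency calibration
  sf <- region_statistics(rbind(c(1, 1), c(3, 3)), freq_axis = c(100, 300))
  expect_equal(unname(sf["FrequencyCentroid"]), (100 * 2 + 300 * 6) / 8)
})

test_that("Otsu binarization isolates the bright mode", {
  r <- matrix(0.1, 10, 10)
  r[3:6, 4:8] <- 0.9
  bm <- binarize_region(r)
  expect_false(bm$flagged)
  expect_identical(dim(bm$mask), dim(r))
  expect_true(all(bm$mask[3:6, 4:8]))
  expect_equal(sum(bm$mask), 4 * 5)

  bc <- binarize_region(matrix(5, 4, 4))
  expect_true(bc$flagged)
  expect_false(any(bc$mask))

  ## threshold is relative: scaling values leaves the mask unchanged
  bs <- binarize_region(r * 1000)
  expect_identical(bs$mask, bm$mask)
})

test_that("morphology closed forms hold for squares and holed squares", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, 3:12] <- TRUE
  d <- region_morphology(m)
  expect_equal(unname(d["Area"]), 100)
  expect_equal(unname(d["ConnectedComponents"]), 1)
  expect_equal(unname(d["Holes"]), 0)
  expect_equal(unname(d["EulerNumber"]), 1)
  expect_equal(unname(d["Perimeter"]), 40)
  expect_equal(unname(d["BoundingBoxDiagonal"]), sqrt(162))
  expect_equal(unname(d["AspectRatio"]), 1)
  expect_equal(unname(d["Compactness"]), 4 * pi * 100 / 1600)

  m2 <- m
  m2[6:7, 6:7] <- FALSE                        # 2x2 interior hole
  d2 <- region_morphology(m2)
  expect_equal(unname(d2["Holes"]), 1)
  expect_equal(unname(d2["EulerNumber"]), 0)

  d0 <- region_morphology(matrix(FALSE, 4, 4))
  expect_equal(unname(d0["Area"]), 0)
  expect_true(is.na(d0["AspectRatio"]))
})

test_that("box-counting dimension reaches its known limits", {
  full <- matrix(TRUE, 64, 64)
  expect_lt(abs(region_morphology(full)["FractalDimension"] - 2), 0.1)
  line <- matrix(FALSE, 64, 64)
  line[32, ] <- TRUE
  expect_lt(abs(region_morphology(line)["FractalDimension"] - 1), 0.1)
})

test_that("Euler identity holds on random masks against the flood-fill oracle", {
  withr::with_seed(21, {
    for (r in 1:50) {
      m <- matrix(runif(18 * 16) < runif(1, 0.3, 0.7), 18, 16)
      d <- region_morphology(m)
      comp <- max(flood_label(m, 8))
      bg <- flood_label(!m, 4)
      border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      holes <- length(setdiff(unique(as.integer(bg)), c(0L, border)))
      expect_equal(unname(d["ConnectedComponents"]), comp)
      expect_equal(unname(d["Holes"]), holes)
      expect_equal(unname(d["EulerNumber"]), comp - holes)
    }
  })
})

test_that("GLCM texture matches exhaustive pair enumeration", {
  ## constant region: degenerate single-level case
  g0 <- glcm_texture(matrix(1, 3, 3))
  expect_equal(unname(g0["TextureEnergy"]), 1)
  expect_equal(unname(g0["TextureContrast"]), 0)
  expect_equal(unname(g0["TextureHomogeneity"]), 1)
  expect_true(is.na(g0["TextureCorrelation"]))

  ## 2-level checkerboard: all neighbour pairs cross the two extreme levels
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g1 <- glcm_texture(cb, levels = 8)
  expect_equal(unname(g1["TextureEnergy"]), 0.5)
  expect_equal(unname(g1["TextureContrast"]), 49)

  ## hand 3x3 region against a brute-force co-occurrence count
  r <- rbind(c(0.0, 0.5, 1.0),
             c(0.5, 0.5, 0.0),
             c(1.0, 0.0, 0.5))
  levels <- 4
  g <- glcm_texture(r, levels = levels)
  cuts <- seq(min(r), max(r), length.out = levels + 1)
  q <- matrix(pmin(levels, findInterval(r, cuts, rightmost.closed = TRUE)), 3)
  P <- matrix(0, levels, levels)
  for (i in 1:3) for (j in 1:3) {
    if (j < 3) { a <- q[i, j]; b <- q[i, j + 1]
      P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1 }
    if (i < 3) { a <- q[i, j]; b <- q[i + 1, j]
      P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1 }
  }
  P <- P / sum(P)
  expect_equal(attr(g, "glcm"), P)
  ii <- matrix(seq_len(levels), levels, levels); jj <- t(ii)
  expect_equal(unname(g["TextureContrast"]), sum(P * (ii - jj)^2))
  expect_equal(unname(g["TextureEnergy"]), sum(P^2))
  expect_equal(unname(g["TextureHomogeneity"]), sum(P / (1 + (ii - jj)^2)))
})

test_that("GLCM is a probability distribution and scale-invariant", {
  withr::with_seed(22, {
    for (r in 1:10) {
      m <- matrix(runif(64), 8, 8)
      g <- glcm_texture(m)
      P <- attr(g, "glcm")
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_true(g["TextureEnergy"] > 0 && g["TextureEnergy"] <= 1)
      expect_true(g["TextureHomogeneity"] > 0 && g["TextureHomogeneity"] <= 1)
      g2 <- glcm_texture(m * 123.4)
      expect_equal(g, g2, tolerance = 1e-12)
    }
  })
})
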