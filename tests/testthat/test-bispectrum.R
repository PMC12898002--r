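make_ci <- function(lower, upper, label = "x") {
  structure(list(lower = lower, upper = upper,
                 mean = (lower + upper) / 2, class_label = label),
            class = "class_band_ci")
}

test_that("quadratic phase coupling produces a dominant bispectral peak", {
  fs <- 2048
  t <- seq(0, 8, by = 1 / fs)
  fa <- 180; fb <- 260
  withr::with_seed(3, {
    x <- cos(2 * pi * fa * t + 1.1) + cos(2 * pi * fb * t + 0.4) +
      0.8 * cos(2 * pi * fa * t + 1.1) * cos(2 * pi * fb * t + 0.4) +
      0.3 * rnorm(length(t))
    bs <- estimate_bispectrum(x, fs, nperseg = 256)
    ia <- which.min(abs(bs$f1 - fb)); ib <- which.min(abs(bs$f2 - fa))
    peak <- bs$magnitude[max(ia, ib), min(ia, ib)]
    expect_gt(peak / median(bs$magnitude, na.rm = TRUE), 10)

    ## Gaussian noise: no comparable structure (vanishing third-order cumulant)
    ns <- estimate_bispectrum(rnorm(length(t)), fs, nperseg = 256)
    expect_lt(max(ns$magnitude, na.rm = TRUE) /
                median(ns$magnitude, na.rm = TRUE),
              peak / median(bs$magnitude, na.rm = TRUE) / 10)
  })
})

test_that("bispectrum magnitude is exactly symmetric and errors when short", {
  withr::with_seed(4, x <- rnorm(4096))
  bs <- estimate_bispectrum(x, 2048, nperseg = 256)
  m <- bs$magnitude
  expect_true(all(m == t(m), na.rm = TRUE))
  expect_error(estimate_bispectrum(rnorm(300), 2048, nperseg = 256), "short")
})

test_that("bootstrap CI collapses for identical subjects and is seeded", {
  sp <- rep(list(c(1, 2, 3, 4)), 5)
  ci <- bootstrap_class_ci(sp, n_boot = 50, seed = 1)
  expect_equal(ci$lower, c(1, 2, 3, 4))
  expect_equal(ci$upper, c(1, 2, 3, 4))
  withr::with_seed(9, sp2 <- lapply(1:6, function(i) rnorm(8)))
  a <- bootstrap_class_ci(sp2, n_boot = 200, seed = 5)
  b <- bootstrap_class_ci(sp2, n_boot = 200, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$lower <= a$mean & a$mean <= a$upper))
  expect_error(bootstrap_class_ci(list(1:3, 1:4, 1:3)), "grid")
  expect_error(bootstrap_class_ci(sp2[1:2]))
})

test_that("bootstrap CI coverage is near the nominal 95%", {
  n <- 30; nbins <- 6; reps <- 200
  cover <- 0
  for (r in seq_len(reps)) {
    withr::with_seed(1000 + r, sp <- lapply(seq_len(n), function(i)
      rnorm(nbins, 5, 2)))
    ci <- bootstrap_class_ci(sp, n_boot = 300, seed = r)
    cover <- cover + mean(ci$lower <= 5 & ci$upper >= 5)
  }
  expect_gt(cover / reps, 0.90)
  expect_lt(cover / reps, 0.98)
})

test_that("doubling the class size shrinks CI width about sqrt(2)-fold", {
  widths <- function(n, off) mean(vapply(1:30, function(r) {
    withr::with_seed(off + r, sp <- lapply(seq_len(n), function(i) rnorm(6)))
    ci <- bootstrap_class_ci(sp, n_boot = 300, seed = r)
    mean(ci$upper - ci$lower)
  }, numeric(1)))
  ratio <- widths(20, 0) / widths(40, 500)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.65)
})

test_that("1D gap bands match a brute-force bin scan", {
  ## identical classes: no gaps
  ci <- make_ci(rep(0, 30), rep(1, 30))
  expect_equal(nrow(detect_gap_bands_1d(ci, ci)), 0)

  ## clean offset on bins 10-20 only
  lo_b <- rep(0, 30); hi_b <- rep(1, 30)
  lo_b[10:20] <- 5; hi_b[10:20] <- 6
  band <- detect_gap_bands_1d(make_ci(rep(0, 30), rep(1, 30), "a"),
                              make_ci(lo_b, hi_b, "b"))
  expect_equal(nrow(band), 1)
  expect_equal(band$bin_lo, 10)
  expect_equal(band$bin_hi, 20)
  expect_equal(band$direction, "b")

  ## two separated regions bridged by one non-gap bin stay two bands
  lo2 <- rep(0, 30); hi2 <- rep(1, 30)
  lo2[c(5:8, 10:13)] <- 5; hi2[c(5:8, 10:13)] <- 6
  two <- detect_gap_bands_1d(make_ci(rep(0, 30), rep(1, 30)),
                             make_ci(lo2, hi2), min_bins = 2)
  expect_equal(nrow(two), 2)

  ## random CIs: flagged bins equal the brute-force scan, runs >= min_bins
  withr::with_seed(11, {
    for (r in 1:20) {
      la <- runif(40); ua <- la + runif(40)
      lb <- runif(40); ub <- lb + runif(40)
      bands <- detect_gap_bands_1d(make_ci(la, ua), make_ci(lb, ub),
                                   min_bins = 2)
      gap <- pmax(la, lb) > pmin(ua, ub)
      in_band <- rep(FALSE, 40)
      if (nrow(bands)) for (i in seq_len(nrow(bands)))
        in_band[bands$bin_lo[i]:bands$bin_hi[i]] <- TRUE
      expect_true(all(gap[in_band]))
      runs <- rle(gap)
      expect_equal(sum(in_band),
                   sum(runs$lengths[runs$values & runs$lengths >= 2]))
    }
  })
})

test_that("gap detection is symmetric in class order with flipped direction", {
  lo_b <- rep(0, 20); hi_b <- rep(1, 20)
  lo_b[4:9] <- 3; hi_b[4:9] <- 4
  a <- make_ci(rep(0, 20), rep(1, 20), "A")
  b <- make_ci(lo_b, hi_b, "B")
  g1 <- detect_gap_bands_1d(a, b)
  g2 <- detect_gap_bands_1d(b, a)
  expect_equal(g1[, c("bin_lo", "bin_hi")], g2[, c("bin_lo", "bin_hi")])
  expect_equal(g1$direction, g2$direction)      # labels travel with the CIs
})

test_that("widening the intervals never creates new gap bins", {
  withr::with_seed(12, {
    la <- runif(50); ua <- la + runif(50, 0.1, 0.5)
    lb <- runif(50); ub <- lb + runif(50, 0.1, 0.5)
    gap_n <- function(extra) {
      g <- detect_gap_bands_1d(make_ci(la - extra, ua + extra),
                               make_ci(lb - extra, ub + extra), min_bins = 1)
      if (nrow(g)) sum(g$bin_hi - g$bin_lo + 1) else 0
    }
    widths <- vapply(c(0, 0.05, 0.1, 0.2), gap_n, numeric(1))
    expect_true(all(diff(widths) <= 0))
  })
})

test_that("2D gap boxes bound the disjoint components found by flood fill", {
  z <- matrix(0, 20, 20)
  ci_a <- make_ci(z, z + 1)
  expect_equal(nrow(detect_gap_boxes_2d(ci_a, ci_a)), 0)

  ## one injected 5x3 disjoint block
  lo_b <- z; hi_b <- z + 1
  lo_b[6:10, 4:6] <- 5; hi_b[6:10, 4:6] <- 6
  bx <- detect_gap_boxes_2d(ci_a, make_ci(lo_b, hi_b))
  expect_equal(nrow(bx), 1)
  expect_equal(unlist(bx[1, c("row_lo", "row_hi", "col_lo", "col_hi")],
                      use.names = FALSE), c(6, 10, 4, 6))
  expect_equal(bx$n_cells, 15)

  ## diagonal-touching blocks form one 8-connected component
  lo_d <- z; hi_d <- z + 1
  lo_d[2:4, 2:4] <- 5; hi_d[2:4, 2:4] <- 6
  lo_d[5:7, 5:7] <- 5; hi_d[5:7, 5:7] <- 6
  bd <- detect_gap_boxes_2d(ci_a, make_ci(lo_d, hi_d))
  expect_equal(nrow(bd), 1)
  expect_equal(bd$n_cells, 18)

  ## random masks: every disjoint bin lies in some box unless its component
  ## was below min_area (flood-fill oracle)
  withr::with_seed(13, {
    for (r in 1:10) {
      la <- matrix(runif(15 * 15), 15); ua <- la + runif(15 * 15)
      lb <- matrix(runif(15 * 15), 15); ub <- lb + runif(15 * 15)
      boxes <- detect_gap_boxes_2d(make_ci(la, ua), make_ci(lb, ub),
                                   min_area = 3)
      gap <- pmax(la, lb) > pmin(ua, ub)
      lab <- flood_label(gap, 8)
      sizes <- table(lab[lab > 0])
      for (cell in which(gap)) {
        id <- lab[cell]
        rr <- (cell - 1) %% 15 + 1; cc <- (cell - 1) %/% 15 + 1
        inside <- nrow(boxes) > 0 &&
          any(boxes$row_lo <= rr & rr <= boxes$row_hi &
              boxes$col_lo <= cc & cc <= boxes$col_hi)
        if (sizes[as.character(id)] >= 3) expect_true(inside)
      }
      expect_equal(nrow(boxes), sum(sizes >= 3))
    }
  })
})

test_that("boxes are ordered by component size with deterministic ties", {
  z <- matrix(0, 12, 12)
  lo <- z; hi <- z + 1
  lo[1:2, 1:2] <- 5; hi[1:2, 1:2] <- 6        # 4 cells
  lo[8:10, 8:10] <- 5; hi[8:10, 8:10] <- 6    # 9 cells
  bx <- detect_gap_boxes_2d(make_ci(z, z + 1), make_ci(lo, hi))
  expect_equal(bx$n_cells, c(9, 4))
  expect_equal(bx$component_id, c(1, 2))
})
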