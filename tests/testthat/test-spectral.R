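test_that("Welch PSD integrates to the signal variance and localizes tones", {
  fs <- 10240
  withr::with_seed(1, x <- rnorm(fs * 8))
  psd <- welch_psd(x, fs)
  expect_s3_class(psd, "psd_estimate")
  expect_true(all(diff(psd$freqs) > 0))
  expect_true(all(psd$power >= 0))
  integral <- sum(psd$power) * diff(psd$freqs)[1]
  expect_lt(abs(integral - var(x)) / var(x), 0.05)

  tone <- sin(2 * pi * 500 * seq(0, 2, by = 1 / fs))
  pt <- welch_psd(tone, fs)
  expect_lt(abs(pt$freqs[which.max(pt$power)] - 500), fs / 1024)

  expect_error(welch_psd(rnorm(100), fs, nperseg = 1024), "nperseg")
})

test_that("averaging PSDs of two records matches the PSD of their union", {
  fs <- 8000
  withr::with_seed(2, { a <- rnorm(fs); b <- rnorm(fs) })
  pa <- welch_psd(a, fs, nperseg = 512)$power
  pb <- welch_psd(b, fs, nperseg = 512)$power
  pc <- welch_psd(c(a, b), fs, nperseg = 512)$power
  ## segment-boundary overlap makes this approximate
  expect_lt(mean(abs((pa + pb) / 2 - pc)) / mean(pc), 0.15)
})

test_that("spectral descriptors match brute-force weighted moments", {
  ## hand-built 4-bin spectrum
  p <- c(0.1, 0.2, 0.3, 0.4)
  f <- c(100, 200, 300, 400)
  psd <- structure(list(freqs = f, power = p), class = "psd_estimate")
  d <- spectral_descriptors(psd, band = c(50, 450),
                            ratio_bands = list(c(50, 250), c(250, 450)))
  w <- p / sum(p)
  cen <- sum(w * f)
  bw <- sqrt(sum(w * (f - cen)^2))
  expect_equal(unname(d["FreqCentroid"]), cen, tolerance = 1e-12)
  expect_equal(unname(d["Bandwidth"]), bw, tolerance = 1e-12)
  expect_equal(unname(d["FreqSkewness"]),
               sum(w * (f - cen)^3) / bw^3, tolerance = 1e-12)
  expect_equal(unname(d["FreqKurtosis"]),
               sum(w * (f - cen)^4) / bw^4 - 3, tolerance = 1e-12)
  expect_equal(unname(d["Crest"]), max(p) / mean(p), tolerance = 1e-12)
  expect_equal(unname(d["FrequencyRatio"]), (0.1 + 0.2) / (0.3 + 0.4),
               tolerance = 1e-12)

  ## single-bin spectrum: entropy 0, bandwidth 0, crest = bin count
  p1 <- c(0, 0, 1, 0)
  d1 <- spectral_descriptors(structure(list(freqs = f, power = p1),
                                       class = "psd_estimate"),
                             band = c(50, 450))
  expect_equal(unname(d1["Entropy"]), 0)
  expect_equal(unname(d1["Bandwidth"]), 0)
  expect_equal(unname(d1["Crest"]), 4)

  ## flat spectrum: centroid at band centre, normalized entropy 1
  pf <- rep(1, 64)
  ff <- seq(0, 630, by = 10)
  df <- spectral_descriptors(structure(list(freqs = ff, power = pf),
                                       class = "psd_estimate"),
                             band = c(0, 630))
  expect_equal(unname(df["FreqCentroid"]), mean(ff))
  expect_equal(unname(df["Entropy"]), 1)

  expect_error(spectral_descriptors(psd, band = c(5000, 6000)), "band")
  expect_error(spectral_descriptors(
    structure(list(freqs = f, power = rep(0, 4)), class = "psd_estimate"),
    band = c(50, 450)), "zero total power")
})

test_that("descriptors are invariant to sign flip and gain", {
  fs <- 10240
  withr::with_seed(3, x <- rnorm(fs * 2))
  p1 <- spectral_descriptors(welch_psd(x, fs))
  p2 <- spectral_descriptors(welch_psd(-x, fs))
  expect_equal(p1, p2, tolerance = 1e-12)
  p3 <- spectral_descriptors(welch_psd(3.7 * x, fs))
  for (k in c("FreqCentroid", "Bandwidth", "Entropy", "FreqSkewness",
              "FreqKurtosis", "Crest", "FrequencyRatio"))
    expect_equal(unname(p1[k]), unname(p3[k]), tolerance = 1e-9)
})

test_that("spectral flux vanishes for stationary tones and is gain-invariant", {
  fs <- 8192
  tone <- sin(2 * pi * 400 * seq(0, 1, by = 1 / fs))
  expect_lt(spectral_flux(tone, fs), 0.02)

  ## alternating 300 / 1200 Hz frames produce near-maximal flux
  nper <- 256
  t_fr <- seq_len(nper) / fs
  frames <- lapply(seq_len(40), function(i)
    sin(2 * pi * (if (i %% 2) 300 else 1200) * t_fr))
  alt <- unlist(frames)
  fl_alt <- spectral_flux(alt, fs, nperseg = nper, overlap = 0)
  expect_gt(fl_alt, 10 * spectral_flux(tone, fs))

  withr::with_seed(4, x <- rnorm(fs))
  expect_equal(spectral_flux(x, fs), spectral_flux(100 * x, fs),
               tolerance = 1e-12)
  expect_error(spectral_flux(rnorm(100), fs, nperseg = 256))
})

test_that("time-domain descriptors match closed forms on a pure tone", {
  fs <- 10000
  x <- sin(2 * pi * 100 * seq(1 / fs, 1, by = 1 / fs))
  d <- time_domain_descriptors(x, fs)
  expect_equal(unname(d["ZCR"]), 200, tolerance = 0.01)
  expect_equal(unname(d["RMS"]), sqrt(0.5), tolerance = 1e-3)
  expect_equal(unname(d["Jitter"]), 0, tolerance = 1e-4)
  expect_equal(unname(d["Shimmer"]), 0, tolerance = 1e-3)
  expect_lt(unname(d["NHR"]), 1e-3)
})

test_that("shimmer tracks alternating peak amplitudes and NHR tracks noise", {
  fs <- 10000
  t <- seq(1 / fs, 1, by = 1 / fs)
  base <- sin(2 * pi * 100 * t)
  ## +-10% alternating cycle amplitudes: mean relative peak difference 0.2/1.0
  gain <- 1 + 0.1 * rep(rep(c(1, -1), each = fs / 100), length.out = length(t))
  d <- time_domain_descriptors(base * gain, fs)
  expect_equal(unname(d["Shimmer"]), 0.2, tolerance = 0.03)

  withr::with_seed(5, noise <- rnorm(length(t), 0, sqrt(0.05)))
  dn <- time_domain_descriptors(base + noise, fs)
  ## noise power / harmonic power = 0.05 / 0.5
  expect_equal(unname(dn["NHR"]), 0.1, tolerance = 0.03)
})

test_that("aperiodic input flags voice metrics as undefined", {
  withr::with_seed(6, x <- rnorm(5000))
  d <- time_domain_descriptors(x, 10000)
  expect_true(is.na(d["Jitter"]))
  expect_true(is.na(d["Shimmer"]))
  expect_true(is.na(d["NHR"]))
  expect_false(is.na(d["ZCR"]))
})
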