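test_that("band-pass filter preserves mid-band tones and rejects DC and rumble", {
  fs <- 10240
  t <- seq(0, 2, by = 1 / fs)
  mid <- sin(2 * pi * 1500 * t)
  y <- bandpass_filter(mid, fs)
  expect_length(y, length(mid))
  expect_lt(abs(sqrt(mean(y^2)) / sqrt(mean(mid^2)) - 1), 0.01)

  ## DC rejection, judged away from the filter's edge transients
  dc <- rep(1, 3 * fs)
  ydc <- bandpass_filter(dc, fs)
  expect_lt(max(abs(ydc[fs:(2 * fs)])), 1e-3)

  rumble <- sin(2 * pi * 20 * t)
  yr <- bandpass_filter(rumble, fs)
  atten_db <- 10 * log10(mean(rumble^2) / mean(yr^2))
  expect_gt(atten_db, 20)

  expect_error(bandpass_filter(mid, 4000), "too low")
  expect_error(bandpass_filter(c(1, NA, 3), fs))
})

test_that("filtering a signal band-limited inside the passband changes little", {
  fs <- 10240
  withr::with_seed(8, x <- rnorm(4 * fs))
  ## content well inside 75-3000 Hz, where the band edges have no bite
  xb <- bandpass_filter(x, fs, band = c(300, 1500))
  once <- bandpass_filter(xb, fs)
  twice <- bandpass_filter(once, fs)
  i <- seq(fs, 3 * fs)
  expect_lt(sqrt(mean((once[i] - xb[i])^2)) / sqrt(mean(xb[i]^2)), 0.02)
  expect_lt(sqrt(mean((twice[i] - once[i])^2)) / sqrt(mean(once[i]^2)), 0.02)
})

test_that("segmentation finds alternating phases and merges short dropouts", {
  coh <- generate_cohort(c(Mild = 1), seed = 13)
  rec <- coh$recordings[[1]]$nose
  filt <- bandpass_filter(rec$samples, rec$fs)
  segs <- segment_breath_phases(filt, rec$fs)
  expect_length(segs, 10)
  expect_equal(segs[[1]]$phase, "inspiration")
  expect_equal(vapply(segs, `[[`, integer(1), "breath_index"),
               rep(1:5, each = 2))

  ## inject a 50 ms dropout inside one phase: the merge-gap rule keeps 10 segments
  x2 <- filt
  mid <- segs[[3]]$start + (segs[[3]]$end - segs[[3]]$start) %/% 2
  x2[mid:(mid + round(0.05 * rec$fs))] <- 0
  segs2 <- segment_breath_phases(x2, rec$fs)
  expect_length(segs2, 10)

  ## segmentation count is invariant to global gain
  segs3 <- segment_breath_phases(filt * 37, rec$fs)
  expect_length(segs3, 10)
})

test_that("pure noise-floor input yields no segments", {
  withr::with_seed(2, x <- rnorm(10240 * 2) * 1e-4)
  expect_length(segment_breath_phases(x, 10240), 0)
  expect_error(segment_breath_phases(numeric(0), 10240))
})

test_that("SNR follows its closed form and the generator's -40 dB floor", {
  expect_equal(compute_snr(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_equal(compute_snr(rep(10, 8), rep(1, 8)), 20)
  expect_error(compute_snr(1:3, rep(0, 3)), "zero")
  expect_error(compute_snr(numeric(0), 1:3))

  coh <- generate_cohort(c(Non = 1), seed = 17, noise_floor_db = -40)
  rec <- coh$recordings[[1]]$mouth
  filt <- bandpass_filter(rec$samples, rec$fs)
  segs <- segment_breath_phases(filt, rec$fs)
  snrs <- vapply(segs, `[[`, numeric(1), "snr_db")
  ## active-segment SNR is near the constructed 40 dB (envelope correction
  ## lowers the average active power below the peak)
  expect_true(all(snrs > 25 & snrs < 45))
})

test_that("mid-flow extraction is centred and length-exact", {
  seg <- list(samples = sin(2 * pi * 5 * seq(0, 1, length.out = 10000)) *
                exp(-((seq_len(10000) - 5000) / 2000)^2),
              fs = 10000)
  expect_identical(extract_midflow(seg, fraction = 1), seg$samples)
  half <- extract_midflow(seg, fraction = 0.5)
  expect_length(half, 5000)
  ## symmetric envelope: the returned window straddles the envelope peak,
  ## i.e. the peak-amplitude region sits near the window centre
  env <- abs(seg$samples)
  win_env <- abs(half)
  expect_lt(abs(which.max(win_env) - 2500), 300)
  ## and the window is a contiguous slice of the segment
  expect_true(any(vapply(seq_len(5001), function(s0)
    identical(half, seg$samples[s0:(s0 + 4999)]), logical(1))))
  expect_error(extract_midflow(seg, fraction = 0))
  expect_error(extract_midflow(list(samples = rnorm(100), fs = 100),
                               fraction = 0.1))
})

test_that("normalization choice maximizes mutual information with ties ordered", {
  withr::with_seed(5, {
    y <- rep(c("a", "b"), each = 30)
    ## one cleanly separated feature: every method preserves the separation,
    ## so MI ties and the fixed order picks mean-range
    x <- matrix(c(rnorm(30, 0, 0.2), rnorm(30, 5, 0.2)), ncol = 1,
                dimnames = list(NULL, "f1"))
    res <- select_normalization(x, y)
    expect_equal(res$method, "mean-range")
    expect_true(all(abs(res$mi_scores - res$mi_scores[1]) < 1e-9))

    ## label-independent features: mean MI near zero for every method
    xr <- matrix(rnorm(60 * 5), 60, 5,
                 dimnames = list(NULL, paste0("r", 1:5)))
    res_r <- select_normalization(xr, y)
    expect_true(all(res_r$mi_scores < 0.15))

    ## constant column is flagged and passed through, not NaN
    xc <- cbind(x, const = rep(2, 60))
    res_c <- select_normalization(xc, y)
    expect_true("const" %in% res_c$flagged)
    expect_false(anyNA(res_c$normalized))
  })
})

test_that("normalization statistics never consult held-out rows", {
  withr::with_seed(6, {
    y <- rep(c("a", "b"), 20)
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("u", "v", "w")))
    train <- 1:20
    r1 <- select_normalization(X, y, train_rows = train)
    X2 <- X
    X2[21:40, ] <- X2[21:40, ] * 100 + 7    # corrupt only held-out rows
    r2 <- select_normalization(X2, y, train_rows = train)
    expect_identical(r1$method, r2$method)
    expect_identical(r1$mi_scores, r2$mi_scores)
    expect_identical(r1$stats, r2$stats)
    expect_identical(r1$normalized[train, ], r2$normalized[train, ])
  })
})

test_that("normalization requires two represented classes", {
  X <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "f"))
  expect_error(select_normalization(X, rep("a", 10)), "2 label classes")
  expect_error(select_normalization(X, c(rep("a", 9), "b")), "2 subjects")
})
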