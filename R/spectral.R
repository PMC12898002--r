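## Welch power spectral density and spectral/time-domain descriptors.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

## Short-time magnitude spectra: columns = frames, rows = freq bins 0..nperseg/2.
stft_mag <- function(x, fs, nperseg = 256, overlap = 0.5, window = hann_window) {
  hop <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = hop)
  if (length(starts) < 1) stop("input shorter than one frame", call. = FALSE)
  w <- window(nperseg)
  nb <- nperseg %/% 2L + 1L
  mag <- vapply(starts, function(s) {
    X <- fft(x[s:(s + nperseg - 1L)] * w)
    Mod(X[seq_len(nb)])
  }, numeric(nb))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = nb)
  list(mag = mag, freqs = seq(0, nperseg / 2) * fs / nperseg,
       times = (starts - 1L + nperseg / 2) / fs)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with density scaling, so that the
#' integral of the PSD over frequency approximates the signal variance
#' (one-sided spectrum; interior bins doubled).
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length (default 1024).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list of class `psd_estimate`: `freqs` (Hz), `power` (density,
#'   units^2/Hz), `nperseg`, `overlap`, `window`, `n_segments`.
#' @export
welch_psd <- function(x, fs, nperseg = 1024, overlap = 0.5) {
  if (length(x) < nperseg)
    stop("input shorter than nperseg", call. = FALSE)
  hop <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = hop)
  w <- hann_window(nperseg)
  scale <- fs * sum(w^2)
  nb <- nperseg %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- fft(x[s:(s + nperseg - 1L)] * w)
    acc <- acc + (Mod(X[seq_len(nb)])^2) / scale
  }
  p <- acc / length(starts)
  ## one-sided: double all bins except DC and Nyquist
  if (nb > 2) p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
  structure(list(freqs = seq(0, nperseg / 2) * fs / nperseg, power = p,
                 nperseg = nperseg, overlap = overlap, window = "hann",
                 n_segments = length(starts)),
            class = "psd_estimate")
}

#' Spectral descriptors of a PSD within a frequency band
#'
#' Power-weighted moments over frequency (centroid, bandwidth, skewness,
#' kurtosis), normalized spectral entropy, crest factor, mean/peak power, band
#' maximum frequency, and the low/high frequency power ratio.
#'
#' @param psd a [welch_psd()] result (or a list with `freqs` and `power`).
#' @param band analysis band in Hz (default `c(75, 3000)`).
#' @param ratio_bands list of two Hz intervals for the frequency ratio
#'   (default `list(c(150, 450), c(450, 3000))`).
#' @return named numeric vector of descriptors.
#' @export
spectral_descriptors <- function(psd, band = c(75, 3000),
                                 ratio_bands = list(c(150, 450), c(450, 3000))) {
  f <- psd$freqs; p <- psd$power
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("band outside PSD support", call. = FALSE)
  f <- f[sel]; p <- p[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero total power in band", call. = FALSE)
  w <- p / tot
  centroid <- sum(w * f)
  bw <- sqrt(sum(w * (f - centroid)^2))
  skew <- if (bw > 0) sum(w * (f - centroid)^3) / bw^3 else 0
  kurt <- if (bw > 0) sum(w * (f - centroid)^4) / bw^4 - 3 else 0
  nz <- w > 0
  ent_raw <- -sum(w[nz] * log(w[nz]))
  ent <- if (length(f) > 1) ent_raw / log(length(f)) else 0
  r_lo <- sum(p[f >= ratio_bands[[1]][1] & f <= ratio_bands[[1]][2]])
  r_hi <- sum(p[f >= ratio_bands[[2]][1] & f <= ratio_bands[[2]][2]])
  c(FreqCentroid = centroid,
    Bandwidth = bw,
    Entropy = ent,
    FreqSkewness = skew,
    FreqKurtosis = kurt,
    Crest = max(p) / mean(p),
    MeanPower = mean(p),
    PeakPower = max(p),
    Maximum = f[which.max(p)],
    FrequencyRatio = if (r_hi > 0) r_lo / r_hi else NA_real_,
    SpectralEnergy = tot)
}

#' Spectral flux of a waveform
#'
#' Mean Euclidean norm of successive differences of per-frame L1-normalized
#' magnitude spectra; invariant to global amplitude scaling.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param nperseg STFT frame length (default 256).
#' @param overlap fractional overlap (default 0.5).
#' @return scalar flux value.
#' @export
spectral_flux <- function(x, fs, nperseg = 256, overlap = 0.5) {
  st <- stft_mag(x, fs, nperseg, overlap)
  m <- st$mag
  if (ncol(m) < 2) stop("need at least 2 frames", call. = FALSE)
  s <- colSums(m)
  s[s == 0] <- 1
  m <- sweep(m, 2, s, "/")
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  mean(sqrt(colSums(d^2)))
}

## Autocorrelation pitch detector in [f_lo, f_hi]; NA when no clear peak.
detect_pitch <- function(x, fs, f_lo = 60, f_hi = 400) {
  n <- length(x)
  lag_min <- max(2L, as.integer(floor(fs / f_hi)))
  lag_max <- min(n - 2L, as.integer(ceiling(fs / f_lo)))
  if (lag_max <= lag_min) return(NA_real_)
  x0 <- x - mean(x)
  ac <- acf(x0, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[-1]
  seg <- ac[lag_min:lag_max]
  k <- which.max(seg)
  if (seg[k] < 0.3) return(NA_real_)     # no convincing periodicity
  fs / (lag_min + k - 1L)
}

#' Time-domain descriptors (ZCR, RMS, jitter, shimmer, NHR)
#'
#' Zero-crossing rate (crossings/second) and RMS are always returned. Jitter
#' (mean absolute consecutive period difference / mean period), shimmer (same
#' on cycle peak amplitudes), and noise-to-harmonics ratio (noise power over
#' harmonic power from a comb decomposition at the detected fundamental)
#' require detectable periodicity in 60-400 Hz; without it those three keys
#' are returned as `NA` rather than fabricated.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @return named numeric vector `ZCR`, `RMS`, `Jitter`, `Shimmer`, `NHR`.
#' @export
time_domain_descriptors <- function(x, fs) {
  n <- length(x)
  s <- sign(x); s[s == 0] <- 1
  zcr <- sum(diff(s) != 0) / (n / fs)
  rms <- sqrt(mean(x^2))
  out <- c(ZCR = zcr, RMS = rms, Jitter = NA_real_, Shimmer = NA_real_,
           NHR = NA_real_)

  f0 <- detect_pitch(x, fs)
  if (is.na(f0)) return(out)
  period <- fs / f0
  if (n < 3 * period) return(out)

  ## cycle boundaries at upward zero crossings near the nominal period,
  ## linearly interpolated to sub-sample precision
  ux <- which(x[-n] <= 0 & x[-1] > 0)
  if (length(ux) >= 4) {
    tc <- ux + x[ux] / (x[ux] - x[ux + 1L])
    periods <- diff(tc)
    ## keep plausible cycle lengths (0.5..1.5 of nominal)
    ok <- periods > 0.5 * period & periods < 1.5 * period
    periods <- periods[ok]
    if (length(periods) >= 3) {
      out["Jitter"] <- mean(abs(diff(periods))) / mean(periods)
      keep_idx <- which(ok)
      peaks <- vapply(keep_idx, function(i)
        max(abs(x[ux[i]:ux[i + 1]])), numeric(1))
      if (length(peaks) >= 3)
        out["Shimmer"] <- mean(abs(diff(peaks))) / mean(peaks)
    }
  }

  ## comb decomposition: harmonic power from least-squares sin/cos fit at
  ## k*f0; noise = residual
  k_max <- max(1L, floor((fs / 2) / f0) - 1L)
  k_max <- min(k_max, 10L)
  t <- seq_len(n) / fs
  basis <- do.call(cbind, lapply(seq_len(k_max), function(k)
    cbind(sin(2 * pi * k * f0 * t), cos(2 * pi * k * f0 * t))))
  fit <- stats::lm.fit(basis, x)
  harm <- basis %*% fit$coefficients
  noise <- x - harm
  ph <- mean(harm^2)
  if (ph > 0) out["NHR"] <- mean(noise^2) / ph
  out
}
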