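## Wavelet, mel-cepstral, and constant-Q descriptors.

## Daubechies-4 (8-tap, 4 vanishing moments) orthonormal decomposition
## low-pass filter; high-pass follows by quadrature mirror construction.
.db4_lo <- c(-0.010597401784997278, 0.032883011666982945,
             0.030841381835986965, -0.187034811718881140,
             -0.027983769416983850, 0.630880767929590400,
             0.714846570552541500, 0.230377813308855230)

## One level of the periodized orthogonal DWT (input length must be even).
dwt_step <- function(s, lo) {
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  N <- length(s)
  k <- seq(0, N / 2 - 1)
  idx <- outer(2 * k, seq_len(L) - 1, "+") %% N + 1   # (N/2) x L
  sm <- matrix(s[idx], nrow = N / 2)
  list(approx = as.numeric(sm %*% lo), detail = as.numeric(sm %*% hi))
}

#' Discrete wavelet decomposition energy statistics
#'
#' Periodized orthogonal DWT (Daubechies db4 by default) down to `levels`
#' levels; returns each level's relative energy (detail levels fine to
#' coarse, then the final approximation) and the log-energy (Shannon) entropy
#' of the relative energies. Orthogonality means the level energies sum to
#' the signal energy. Input is truncated to the largest multiple of
#' `2^levels`.
#'
#' @param x numeric series (length >= `2^levels`).
#' @param wavelet currently `"db4"`.
#' @param levels decomposition depth (default 5).
#' @return named numeric vector: `WaveletEnergy_D1` ... `WaveletEnergy_D<levels>`,
#'   `WaveletEnergy_A<levels>`, `WaveletEntropy`, plus attribute
#'   `absolute_energies`.
#' @export
wavelet_stats <- function(x, wavelet = "db4", levels = 5) {
  if (!identical(wavelet, "db4")) stop("only db4 is implemented", call. = FALSE)
  if (length(x) < 2^levels) stop("series too short for requested depth", call. = FALSE)
  n_keep <- (length(x) %/% (2^levels)) * (2^levels)
  s <- x[seq_len(n_keep)]
  energies <- numeric(levels + 1)
  names(energies) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  for (l in seq_len(levels)) {
    st <- dwt_step(s, .db4_lo)
    energies[l] <- sum(st$detail^2)
    s <- st$approx
  }
  energies[levels + 1] <- sum(s^2)
  rel <- energies / sum(energies)
  nz <- rel > 0
  ent <- -sum(rel[nz] * log(rel[nz]))
  out <- c(setNames(rel, paste0("WaveletEnergy_", names(energies))),
           WaveletEntropy = ent)
  attr(out, "absolute_energies") <- energies
  out
}

## Hz <-> mel (HTK convention)
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

## Triangular mel filterbank on the band [f_lo, f_hi]: n_mels x n_bins.
mel_filterbank <- function(n_mels, n_fft, fs, f_lo, f_hi) {
  nb <- n_fft %/% 2L + 1L
  freqs <- seq(0, n_fft / 2) * fs / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                       length.out = n_mels + 2))
  fb <- matrix(0, n_mels, nb)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; cen <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (cen - lo)
    down <- (hi - freqs) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

## orthonormal-free DCT-II of a vector
dct2 <- function(v) {
  N <- length(v)
  n <- seq(0, N - 1)
  vapply(seq(0, N - 1), function(k) sum(v * cos(pi * (n + 0.5) * k / N)),
         numeric(1))
}

#' Mel-frequency cepstral coefficient statistics
#'
#' Frame-wise MFCCs (Hann STFT, triangular mel filterbank on 75-3000 Hz, log
#' energies with a small floor, DCT-II); returns the per-coefficient mean and
#' standard deviation across frames. Silent input is defined through the log
#' floor and flagged via the `flagged` attribute.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param n_coeff number of cepstral coefficients (default 13, including the
#'   log-energy coefficient 0).
#' @param n_mels mel filters (default 26).
#' @param nperseg frame length (default 256).
#' @param band mel analysis band in Hz (default `c(75, 3000)`).
#' @return named numeric vector of `2 * n_coeff` values:
#'   `MFCC<k>_Mean`, `MFCC<k>_SD` for k = 0 .. n_coeff-1.
#' @export
mfcc_stats <- function(x, fs, n_coeff = 13, n_mels = 26, nperseg = 256,
                       band = c(75, 3000)) {
  st <- stft_mag(x, fs, nperseg, overlap = 0.5)
  if (ncol(st$mag) < 5) stop("need at least 5 frames", call. = FALSE)
  fb <- mel_filterbank(n_mels, nperseg, fs, band[1], min(band[2], fs / 2))
  pow <- st$mag^2
  melE <- fb %*% pow                       # n_mels x frames
  flagged <- all(melE < 1e-20)
  logE <- log(melE + 1e-20)
  cep <- apply(logE, 2, function(v) dct2(v)[seq_len(n_coeff)])
  mu <- rowMeans(cep)
  sdv <- apply(cep, 1, sd)
  out <- c(setNames(mu, sprintf("MFCC%d_Mean", seq_len(n_coeff) - 1)),
           setNames(sdv, sprintf("MFCC%d_SD", seq_len(n_coeff) - 1)))
  attr(out, "flagged") <- flagged
  out
}

#' Constant-Q transform statistics per octave band
#'
#' Constant-Q magnitudes are computed from `f_min` (75 Hz) upward with
#' `bins_per_octave` log-spaced bins (Hann-windowed complex inner products of
#' length `Q * fs / f_k`); bins are grouped into octave bands and summarized
#' as per-octave mean, SD, and band energy ratio.
#'
#' @param x numeric waveform; must be at least one analysis window of the
#'   lowest bin (`Q * fs / f_min` samples).
#' @param fs sampling rate in Hz.
#' @param bins_per_octave bins per octave (default 24).
#' @param f_min lowest centre frequency in Hz (default 75).
#' @param f_max highest centre frequency (default `min(3000, fs / 2 * 0.95)`).
#' @return named numeric vector of `3 * n_octaves` values:
#'   `CQTOct<i>_Mean`, `CQTOct<i>_SD`, `CQTOct<i>_EnergyRatio`.
#' @export
cqt_stats <- function(x, fs, bins_per_octave = 24, f_min = 75, f_max = NULL) {
  f_max <- f_max %||% min(3000, fs / 2 * 0.95)
  Q <- 1 / (2^(1 / bins_per_octave) - 1)
  n_bins <- floor(bins_per_octave * log2(f_max / f_min)) + 1
  fk <- f_min * 2^((seq_len(n_bins) - 1) / bins_per_octave)
  N0 <- ceiling(Q * fs / f_min)
  if (length(x) < N0)
    stop("record shorter than the lowest-bin support (", N0, " samples)",
         call. = FALSE)
  mags <- vapply(fk, function(f) {
    Nk <- ceiling(Q * fs / f)
    ## centre the analysis window
    s0 <- (length(x) - Nk) %/% 2L
    seg <- x[(s0 + 1):(s0 + Nk)]
    w <- hann_window(Nk)
    t <- seq(0, Nk - 1)
    Mod(sum(seg * w * exp(-2i * pi * f * t / fs))) / sum(w)
  }, numeric(1))
  octave <- floor(log2(fk / f_min))
  tot_e <- sum(mags^2)
  out <- numeric(0)
  for (o in sort(unique(octave))) {
    m <- mags[octave == o]
    out <- c(out, setNames(
      c(mean(m), if (length(m) > 1) sd(m) else 0,
        if (tot_e > 0) sum(m^2) / tot_e else NA_real_),
      sprintf("CQTOct%d_%s", o + 1, c("Mean", "SD", "EnergyRatio"))))
  }
  out
}
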