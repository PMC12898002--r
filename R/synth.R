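## Synthetic breath-sound waveforms with severity-dependent acoustics.

#' Default severity acoustic profiles
#'
#' Parameter ladders encoding the acoustic escalation expected with OSA
#' severity: upward spectral centroid shift, bandwidth growth, more impulsive
#' bursts, larger breath-to-breath amplitude variability, and less regular
#' (lower autoregressive pole radius) airflow noise. These are synthesis
#' fixtures for testing the analysis pipeline, not physiological models.
#'
#' @return named list of profiles, one per severity class; each profile has
#'   `centroid_shift` (Hz), `bandwidth_scale` (>= 1), `burst_rate`
#'   (bursts/breath), `amplitude_cv`, and `ar_regularity` in \[0, 1).
#' @export
default_severity_profiles <- function() {
  list(
    Non      = acoustic_profile(0,   1.0, 0.2, 0.05, 0.90),
    Mild     = acoustic_profile(60,  1.3, 1.0, 0.12, 0.85),
    Moderate = acoustic_profile(130, 1.7, 2.5, 0.22, 0.75),
    Severe   = acoustic_profile(220, 2.3, 5.0, 0.35, 0.60)
  )
}

#' Construct an acoustic severity profile
#'
#' @param centroid_shift centre-frequency shift in Hz (>= 0).
#' @param bandwidth_scale multiplicative bandwidth factor (>= 1).
#' @param burst_rate expected impulsive bursts per breath (>= 0).
#' @param amplitude_cv coefficient of variation of per-breath amplitude.
#' @param ar_regularity autoregressive pole radius in \[0, 1); higher values
#'   give more tonal, regular noise.
#' @export
acoustic_profile <- function(centroid_shift, bandwidth_scale, burst_rate,
                             amplitude_cv, ar_regularity) {
  stopifnot(centroid_shift >= 0, bandwidth_scale >= 1, burst_rate >= 0,
            amplitude_cv >= 0, ar_regularity >= 0, ar_regularity < 1)
  structure(list(centroid_shift = centroid_shift,
                 bandwidth_scale = bandwidth_scale,
                 burst_rate = burst_rate,
                 amplitude_cv = amplitude_cv,
                 ar_regularity = ar_regularity),
            class = "acoustic_profile")
}

## base spectral placement of tracheal noise before severity shifts
.base_center_hz <- 350
.base_bandwidth_hz <- 250

#' Synthesize one breath-phase waveform
#'
#' A raised-cosine amplitude envelope modulates band-shaped coloured noise
#' (white noise band-pass filtered around a severity-shifted centre frequency,
#' then passed through a second-order autoregressive resonator whose pole
#' radius is `profile$ar_regularity`). Poisson-distributed impulsive bursts
#' are superimposed at `profile$burst_rate` per breath. Mouth breathing is
#' synthesized slightly higher in frequency than nose breathing, and
#' expiration slightly lower than inspiration.
#'
#' @param route "nose" or "mouth".
#' @param phase "inspiration" or "expiration".
#' @param profile an [acoustic_profile()].
#' @param fs sampling rate in Hz; must be >= 6000 so the 3000 Hz analysis
#'   band lies below Nyquist.
#' @param duration phase duration in seconds, in \[0.5, 5\].
#' @param seed integer seed; identical seeds give bit-identical waveforms.
#' @return zero-mean numeric waveform of `round(duration * fs)` samples.
#' @export
synth_breath_cycle <- function(route = c("nose", "mouth"),
                               phase = c("inspiration", "expiration"),
                               profile, fs = 10240, duration = 1,
                               seed = NULL) {
  route <- match.arg(route)
  phase <- match.arg(phase)
  stopifnot(inherits(profile, "acoustic_profile"))
  if (fs < 6000)
    stop("fs must be >= 6000 Hz (Nyquist above the 3000 Hz analysis band)",
         call. = FALSE)
  if (duration < 0.5 || duration > 5)
    stop("duration must lie in [0.5, 5] s", call. = FALSE)
  n <- as.integer(round(duration * fs))

  center <- (.base_center_hz + profile$centroid_shift) *
    (if (route == "mouth") 1.15 else 1) *
    (if (phase == "expiration") 0.9 else 1)
  halfwidth <- .base_bandwidth_hz * profile$bandwidth_scale / 2
  lo <- max(80, center - halfwidth)
  hi <- min(fs / 2 - 50, center + halfwidth)

  with_seed(seed, {
    w <- rnorm(n + 2048)                      # pad to flush filter transients
    bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, w)
    ## AR(2) resonator at the centre frequency; pole radius = regularity
    r <- profile$ar_regularity
    theta <- 2 * pi * center / fs
    x <- as.numeric(signal::filter(1, c(1, -2 * r * cos(theta), r^2), x))
    x <- x[1025:(1024 + n)]
    x <- x / (sqrt(mean(x^2)) + 1e-12) * 0.1

    env <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))
    gain <- if (profile$amplitude_cv > 0)
      max(0.1, 1 + profile$amplitude_cv * rnorm(1)) else 1
    y <- x * env * gain

    n_burst <- rpois(1, profile$burst_rate)
    if (n_burst > 0) {
      blen <- as.integer(round(0.005 * fs))
      decay <- exp(-seq_len(blen) / (0.002 * fs))
      amp <- 3 * sqrt(mean(y^2))
      pos <- as.integer(round(runif(n_burst, 0.1, 0.9) * (n - blen)))
      for (p in pos) {
        idx <- p + seq_len(blen)
        y[idx] <- y[idx] + amp * decay * rnorm(blen)
      }
    }
    y - mean(y)
  })
}

#' Generate a synthetic cohort of breath recordings and metadata
#'
#' For each subject, one nose-breathing and one mouth-breathing recording of
#' five breath cycles (alternating inspiration/expiration) separated by
#' silence gaps, with a low-level microphone noise floor added so that SNR
#' computation is exercised. Anthropometric records are drawn with
#' [sample_anthropometrics()].
#'
#' @param class_sizes named vector/list mapping severity class to a
#'   non-negative subject count, e.g. `c(Non = 10, Severe = 10)`.
#' @param fs sampling rate in Hz (default 10240).
#' @param seed integer seed controlling all randomness.
#' @param out_dir optional directory; when given, per-subject WAV files
#'   (`<subject>_nose.wav`, `<subject>_mouth.wav`) and `metadata.csv` are
#'   written there.
#' @param profiles severity acoustic profiles
#'   (default [default_severity_profiles()]).
#' @param n_breaths breath cycles per recording (default 5).
#' @param gap_s silence gap between phases in seconds (default 0.3).
#' @param noise_floor_db microphone noise floor relative to breath RMS in dB
#'   (default -40).
#' @return list with `recordings` (per subject: list of `nose`/`mouth`
#'   waveforms with `fs`) and `metadata` (a data.frame of subject records).
#' @export
generate_cohort <- function(class_sizes, fs = 10240, seed = NULL,
                            out_dir = NULL,
                            profiles = default_severity_profiles(),
                            n_breaths = 5, gap_s = 0.3,
                            noise_floor_db = -40) {
  class_sizes <- unlist(class_sizes)
  if (is.null(names(class_sizes)) || !all(names(class_sizes) %in% severity_levels()))
    stop("class_sizes must be named with severity classes", call. = FALSE)
  if (any(class_sizes < 0)) stop("counts must be >= 0", call. = FALSE)

  meta <- list(); recs <- list(); si <- 0L
  for (sev in names(class_sizes)) {
    n <- as.integer(class_sizes[[sev]])
    if (n == 0) next
    m <- sample_anthropometrics(sev, n, seed = child_seed(seed, match(sev, severity_levels())))
    meta[[sev]] <- m
    prof <- profiles[[sev]]
    for (i in seq_len(n)) {
      si <- si + 1L
      sid <- m$subject_id[i]
      recs[[sid]] <- list(
        nose  = list(samples = synth_recording("nose", prof, fs, n_breaths,
                                               gap_s, noise_floor_db,
                                               child_seed(seed, 100L + 2L * si)),
                     fs = fs),
        mouth = list(samples = synth_recording("mouth", prof, fs, n_breaths,
                                               gap_s, noise_floor_db,
                                               child_seed(seed, 101L + 2L * si)),
                     fs = fs)
      )
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(recs)) {
      write_wav(recs[[sid]]$nose$samples, fs,
                file.path(out_dir, paste0(sid, "_nose.wav")))
      write_wav(recs[[sid]]$mouth$samples, fs,
                file.path(out_dir, paste0(sid, "_mouth.wav")))
    }
    write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  }
  list(recordings = recs, metadata = metadata)
}

## one full recording: alternating inspiration/expiration phases + gaps
synth_recording <- function(route, profile, fs, n_breaths, gap_s,
                            noise_floor_db, seed) {
  with_seed(seed, {
    gap_n <- as.integer(round(gap_s * fs))
    pieces <- list(numeric(gap_n))
    k <- 0L
    for (b in seq_len(n_breaths)) {
      for (ph in c("inspiration", "expiration")) {
        k <- k + 1L
        dur <- max(0.8, min(1.4, rnorm(1, if (ph == "inspiration") 1.1 else 1.0, 0.1)))
        ## draw the phase seed from the active RNG stream so recordings differ
        s <- as.integer(runif(1, 1, 2^30))
        pieces[[length(pieces) + 1L]] <- synth_breath_cycle(route, ph, profile,
                                                            fs, dur, seed = s)
        pieces[[length(pieces) + 1L]] <- numeric(gap_n)
      }
    }
    y <- unlist(pieces)
    active_rms <- sqrt(mean(y[y != 0]^2))
    floor_sd <- active_rms * 10^(noise_floor_db / 20)
    y <- y + rnorm(length(y), 0, floor_sd)
    y <- y - mean(y)
    ## keep within WAV range
    peak <- max(abs(y))
    if (peak > 0.99) y <- y * 0.99 / peak
    y
  })
}
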