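## Preprocessing: band-pass filtering, breath-phase segmentation, SNR gating,
## mid-flow extraction, and mutual-information-guided normalization choice.

#' Band-pass filter a breath recording (75-3000 Hz Butterworth)
#'
#' A 4th-order Butterworth band-pass (edges 75 and 3000 Hz) applied
#' forward-backward (zero phase), so envelope timing is preserved for
#' segmentation. Output length equals input length.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz; must exceed 6000 so the 3000 Hz edge lies
#'   below Nyquist.
#' @param band lower/upper band edges in Hz (default `c(75, 3000)`).
#' @param order Butterworth design order (default 4).
#' @return filtered waveform, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, band = c(75, 3000), order = 4) {
  stop_if_not_finite(x, "waveform")
  if (fs <= 2 * band[2])
    stop("fs too low for the ", band[2], " Hz band edge", call. = FALSE)
  if (length(x) <= 3 * (2 * order))
    stop("input too short for the filter order", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segmentation configuration
#'
#' @param frame_s envelope frame length in seconds (default 0.05).
#' @param overlap fractional frame overlap (default 0.5).
#' @param min_phase_s minimum breath-phase duration in seconds (default 0.2).
#' @param merge_gap_s sub-threshold gaps shorter than this are fused into the
#'   surrounding phase (default 0.1 s).
#' @param low_pct,high_pct envelope percentiles defining the noise floor and
#'   activity level; the adaptive threshold is their midpoint (defaults 5, 95).
#' @param min_snr_db SNR gate in dB; segments below it are flagged
#'   (`retained = FALSE`) but not dropped (default 5).
#' @param start_phase phase label of the first retained segment
#'   (default "inspiration"; the protocol starts each breath with inspiration).
#' @export
segmentation_config <- function(frame_s = 0.05, overlap = 0.5,
                                min_phase_s = 0.2, merge_gap_s = 0.1,
                                low_pct = 5, high_pct = 95,
                                min_snr_db = 5,
                                start_phase = c("inspiration", "expiration")) {
  list(frame_s = frame_s, overlap = overlap, min_phase_s = min_phase_s,
       merge_gap_s = merge_gap_s, low_pct = low_pct, high_pct = high_pct,
       min_snr_db = min_snr_db, start_phase = match.arg(start_phase))
}

#' Segment a recording into inspiratory/expiratory phases
#'
#' The log-variance envelope is computed on sliding frames; the adaptive
#' threshold is the midpoint between its low-percentile noise floor and
#' high-percentile activity level. Supra-threshold runs shorter than the
#' minimum phase duration are discarded, sub-threshold gaps shorter than the
#' merge gap are fused, and retained runs are labelled alternately
#' inspiration/expiration. Per-segment SNR (against the sub-threshold noise
#' floor) is attached; segments under the SNR gate are flagged, not dropped.
#'
#' @param x waveform (ideally already band-pass filtered).
#' @param fs sampling rate in Hz.
#' @param route "nose" or "mouth" (carried into the segment metadata).
#' @param subject_id identifier carried into the segment metadata.
#' @param params a [segmentation_config()].
#' @return list of breath-phase segments; each has `samples`, `fs`, `route`,
#'   `phase`, `breath_index`, `snr_db`, `retained`, `subject_id`, and the
#'   sample index range `start`/`end`. All-silent input gives an empty list.
#' @export
segment_breath_phases <- function(x, fs, route = "nose", subject_id = "subj",
                                  params = segmentation_config()) {
  if (length(x) == 0) stop("empty waveform", call. = FALSE)
  frame_n <- max(8L, as.integer(round(params$frame_s * fs)))
  hop <- max(1L, as.integer(round(frame_n * (1 - params$overlap))))
  starts <- seq(1L, max(1L, length(x) - frame_n + 1L), by = hop)
  env <- vapply(starts, function(s) {
    seg <- x[s:(s + frame_n - 1L)]
    log(var(seg) + 1e-20)
  }, numeric(1))

  lo <- quantile(env, params$low_pct / 100, names = FALSE)
  hi <- quantile(env, params$high_pct / 100, names = FALSE)
  if (hi - lo < 1) return(list())      # no dynamic range: all-silent input
  thr <- (lo + hi) / 2
  active <- env > thr

  runs <- rle(active)
  ## fuse sub-threshold gaps shorter than merge_gap_s (interior only)
  gap_frames <- params$merge_gap_s * fs / hop
  v <- runs$values; l <- runs$lengths
  if (length(v) > 2) {
    for (i in seq(2, length(v) - 1)) {
      if (!v[i] && l[i] < gap_frames && v[i - 1] && v[i + 1]) v[i] <- TRUE
    }
  }
  active <- inverse.rle(list(values = v, lengths = l))
  runs <- rle(active)

  ## map frame runs back to sample indices
  ends_frame <- cumsum(runs$lengths)
  starts_frame <- c(1L, head(ends_frame, -1) + 1L)
  min_frames <- params$min_phase_s * fs / hop
  keep <- which(runs$values & runs$lengths >= min_frames)
  if (length(keep) == 0) return(list())

  noise_idx <- !active[rep(seq_along(starts), each = 1)]
  noise_samples <- unlist(lapply(which(!active), function(f) {
    s <- starts[f]; x[s:min(length(x), s + frame_n - 1L)]
  }))
  if (length(noise_samples) < frame_n) noise_samples <- x * 0 + 1e-10

  phases <- if (params$start_phase == "inspiration")
    c("inspiration", "expiration") else c("expiration", "inspiration")
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    s0 <- starts[starts_frame[i]]
    e0 <- min(length(x), starts[ends_frame[i]] + frame_n - 1L)
    seg <- x[s0:e0]
    snr <- compute_snr(seg, noise_samples)
    out[[j]] <- list(samples = seg, fs = fs, route = route,
                     phase = phases[(j - 1L) %% 2L + 1L],
                     breath_index = (j - 1L) %/% 2L + 1L,
                     snr_db = snr,
                     retained = snr >= params$min_snr_db,
                     subject_id = subject_id,
                     start = s0, end = e0)
  }
  out
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(mean(segment^2) / mean(noise^2))`.
#'
#' @param segment waveform of the active segment.
#' @param noise_floor waveform of background noise.
#' @return SNR in dB.
#' @export
compute_snr <- function(segment, noise_floor) {
  if (length(segment) == 0 || length(noise_floor) == 0)
    stop("empty input", call. = FALSE)
  pn <- mean(noise_floor^2)
  if (pn == 0) stop("zero noise-floor power", call. = FALSE)
  10 * log10(mean(segment^2) / pn)
}

#' Extract the mid-flow portion of a breath-phase segment
#'
#' Returns the central `fraction` of the segment's samples, centred on the
#' peak of a smoothed amplitude envelope (the high-flow part of the phase).
#'
#' @param segment a segment from [segment_breath_phases()], or a bare numeric
#'   waveform (then `fs` must be supplied).
#' @param fraction proportion of samples to keep, in (0, 1].
#' @param fs sampling rate (taken from the segment when available).
#' @param min_samples minimum acceptable output length (default 64).
#' @return numeric waveform of `round(fraction * length)` samples.
#' @export
extract_midflow <- function(segment, fraction = 0.5, fs = NULL,
                            min_samples = 64) {
  x <- if (is.list(segment)) segment$samples else segment
  fs <- if (is.list(segment)) segment$fs else fs
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  n <- length(x)
  keep <- as.integer(round(fraction * n))
  if (keep < min_samples)
    stop("mid-flow window shorter than the minimum analysis length", call. = FALSE)
  if (keep == n) return(x)
  ## envelope peak via moving-average of |x| (cumsum rolling window)
  w <- max(3L, as.integer(round(0.05 * (fs %||% 10000))))
  w <- min(w, n)
  cs <- c(0, cumsum(abs(x)))
  env <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  peak <- which.max(env) + w %/% 2L
  half <- keep %/% 2L
  s0 <- min(max(1L, peak - half), n - keep + 1L)
  x[s0:(s0 + keep - 1L)]
}

## ---- normalization selection ------------------------------------------------

normalization_methods <- function() c("mean-range", "z-score", "min-max", "robust")

## Column-wise normalization statistics learned from (training) data.
norm_stats <- function(x, method) {
  switch(method,
    "mean-range" = list(center = mean(x), scale = diff(range(x))),
    "z-score"    = list(center = mean(x), scale = sd(x)),
    "min-max"    = list(center = min(x), scale = diff(range(x))),
    "robust"     = list(center = median(x), scale = stats::IQR(x)))
}

apply_norm <- function(x, st) {
  if (!is.finite(st$scale) || st$scale == 0) return(list(x = x, flagged = TRUE))
  list(x = (x - st$center) / st$scale, flagged = FALSE)
}

## Mutual information between a numeric feature and a categorical label,
## estimated by equal-frequency binning with ceiling(sqrt(n)) bins. Nats.
mi_feature_label <- function(x, labels, n_bins = NULL) {
  n <- length(x)
  n_bins <- n_bins %||% ceiling(sqrt(n))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(0)
  bx <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(bx, labels)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Select a feature normalization method by mutual information
#'
#' Each candidate method (mean-range, z-score, min-max, robust scaling) is
#' applied column-wise with statistics learned from the training rows only;
#' the mutual information between each normalized column and the class label
#' is estimated by equal-frequency binning, and the method with maximal mean
#' MI is selected (ties broken in the fixed order mean-range, z-score,
#' min-max, robust). Zero-variance columns are passed through unscaled and
#' flagged.
#'
#' @param features numeric matrix or data.frame (rows = subjects).
#' @param labels class label per row (>= 2 classes, >= 2 rows each).
#' @param train_rows indices of rows used to learn the statistics and the MI
#'   scores (default: all rows). Remaining rows are transformed with the
#'   learned statistics and never influence the choice.
#' @return list with `method`, `mi_scores` (named, nats), `normalized`
#'   (full matrix transformed with training statistics), `flagged`
#'   (column names passed through unscaled), and `stats` (per-column learned
#'   statistics of the chosen method).
#' @export
select_normalization <- function(features, labels, train_rows = NULL) {
  X <- as.matrix(features)
  train_rows <- train_rows %||% seq_len(nrow(X))
  ytr <- labels[train_rows]
  if (length(unique(ytr)) < 2) stop("need >= 2 label classes", call. = FALSE)
  if (min(table(ytr)) < 2) stop("need >= 2 subjects per class", call. = FALSE)

  methods <- normalization_methods()
  mi_scores <- setNames(numeric(length(methods)), methods)
  norm_by_method <- list()
  flagged_by_method <- list()
  stats_by_method <- list()
  for (m in methods) {
    st <- lapply(seq_len(ncol(X)), function(j) norm_stats(X[train_rows, j], m))
    res <- lapply(seq_len(ncol(X)), function(j) apply_norm(X[, j], st[[j]]))
    Xn <- vapply(res, `[[`, numeric(nrow(X)), "x")
    if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = nrow(X))
    colnames(Xn) <- colnames(X)
    flagged <- vapply(res, `[[`, logical(1), "flagged")
    mi_scores[m] <- mean(vapply(seq_len(ncol(Xn)), function(j)
      mi_feature_label(Xn[train_rows, j], ytr), numeric(1)))
    norm_by_method[[m]] <- Xn
    flagged_by_method[[m]] <- colnames(X)[flagged]
    stats_by_method[[m]] <- st
  }
  ## maximal MI; ties (within estimator noise) broken by the fixed order
  best <- methods[which(mi_scores >= max(mi_scores) - 1e-12)][1]
  list(method = best, mi_scores = mi_scores,
       normalized = norm_by_method[[best]],
       flagged = flagged_by_method[[best]],
       stats = stats_by_method[[best]])
}
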