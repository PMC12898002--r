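## Fractal, chaos, and recurrence descriptors of breath-sound series.

#' Katz fractal dimension
#'
#' `log10(n) / (log10(n) + log10(d / L))` with `L` the total path length of
#' the curve, `d` the maximum distance from the first point, and `n` the
#' number of segments. Equals 1 for a straight line and grows with waveform
#' irregularity; invariant to amplitude scaling.
#'
#' @param x numeric series (length >= 3).
#' @return scalar fractal dimension.
#' @export
katz_fd <- function(x) {
  n <- length(x) - 1L
  if (n < 2) stop("need at least 3 samples", call. = FALSE)
  L <- sum(abs(diff(x)))
  if (L == 0) stop("zero path length", call. = FALSE)
  d <- max(abs(x - x[1]))
  log10(n) / (log10(n) + log10(d / L))
}

#' Higuchi fractal dimension
#'
#' Average normalized curve lengths `L(k)` are computed for lags
#' `k = 1..kmax`; the dimension is the negative least-squares slope of
#' `log L(k)` versus `log k`. Approaches 1 for smooth curves and 2 for
#' uncorrelated noise.
#'
#' @param x numeric series (length >= 10 * kmax).
#' @param kmax maximum lag (default 10).
#' @return scalar fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  if (n < 10 * kmax) stop("series too short for kmax", call. = FALSE)
  Lk <- vapply(seq_len(kmax), function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm <- (n - 1) / (length(idx) - 1) / k
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm, na.rm = TRUE)
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax))), log(Lk))
  -unname(fit$coefficients[2])
}

## Anis-Lloyd expected R/S of an i.i.d. series at window size n; used to
## de-bias the small-sample rescaled-range statistic.
expected_rs <- function(n) {
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  if (n <= 340)
    ((n - 0.5) / n) * gamma((n - 1) / 2) / (sqrt(pi) * gamma(n / 2)) * s
  else
    ((n - 0.5) / n) * s / sqrt(n * pi / 2)
}

#' Hurst exponent by bias-corrected rescaled-range analysis
#'
#' Classical R/S analysis over six or more log-spaced window sizes, with the
#' Anis-Lloyd small-sample correction: `H` is 0.5 plus the least-squares
#' slope of `log(R/S) - log(E[R/S])` versus `log(window size)`. White noise
#' gives H near 0.5, an integrated (cumsum) process H near 1.
#'
#' @param x numeric series (length >= 256).
#' @param min_window smallest window (default 16).
#' @param n_scales number of log-spaced window sizes (default 8).
#' @return scalar Hurst exponent.
#' @export
hurst_exponent <- function(x, min_window = 16, n_scales = 8) {
  n <- length(x)
  if (n < 256) stop("need at least 256 samples", call. = FALSE)
  if (sd(x) == 0) stop("constant series", call. = FALSE)
  sizes <- unique(round(exp(seq(log(min_window), log(n %/% 2),
                                length.out = max(6, n_scales)))))
  rs <- vapply(sizes, function(w) {
    k <- n %/% w
    vals <- vapply(seq_len(k), function(i) {
      seg <- x[((i - 1) * w + 1):(i * w)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      s <- sd(seg)
      if (s == 0) NA_real_ else r / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  e_rs <- vapply(sizes, expected_rs, numeric(1))
  ok <- is.finite(rs) & rs > 0
  fit <- stats::lm.fit(cbind(1, log(sizes[ok])), log(rs[ok]) - log(e_rs[ok]))
  0.5 + unname(fit$coefficients[2])
}

#' Embedding configuration for phase-space estimators
#'
#' @param m embedding dimension (default 3).
#' @param tau delay in samples; `NULL` selects the first zero crossing of the
#'   autocorrelation at run time.
#' @param radius recurrence radius as a fraction of the phase-space diameter
#'   (default 0.1).
#' @param theiler temporal exclusion window in samples; `NULL` defaults to
#'   the delay.
#' @export
embedding_config <- function(m = 3, tau = NULL, radius = 0.1, theiler = NULL) {
  stopifnot(m >= 1, radius > 0, radius < 1)
  list(m = m, tau = tau, radius = radius, theiler = theiler)
}

## first zero crossing of the autocorrelation (fallback: n/10)
first_acf_zero <- function(x) {
  a <- acf(x, lag.max = min(length(x) - 2, 500), plot = FALSE)$acf[-1]
  k <- which(a <= 0)[1]
  if (is.na(k)) max(1L, length(x) %/% 10L) else as.integer(k)
}

## delay embedding: rows = points, cols = m coordinates
embed_series <- function(x, m, tau) {
  n_pts <- length(x) - (m - 1) * tau
  if (n_pts < 2) stop("m * tau too large for series length", call. = FALSE)
  sapply(0:(m - 1), function(j) x[(1 + j * tau):(n_pts + j * tau)])
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For each embedded point the nearest neighbour outside the Theiler window
#' is found; the mean log divergence of neighbour pairs is tracked over time
#' and the exponent is the slope of its initial linear region, in units of
#' 1/sample (multiply by `fs` for 1/s).
#'
#' @param x numeric series.
#' @param cfg an [embedding_config()].
#' @param t_max divergence horizon in samples (default 30).
#' @param fit_range samples of the initial linear region used for the slope
#'   (default `1:15`).
#' @return scalar exponent (per sample).
#' @export
largest_lyapunov <- function(x, cfg = embedding_config(), t_max = 30,
                             fit_range = 1:15) {
  tau <- cfg$tau %||% first_acf_zero(x)
  theiler <- cfg$theiler %||% tau
  Y <- embed_series(x, cfg$m, tau)
  n <- nrow(Y)
  if (n < 100) stop("need >= 100 embedded points", call. = FALSE)
  D <- as.matrix(dist(Y))
  ## exclude temporal neighbours and self
  for (i in seq_len(n)) {
    lo <- max(1, i - theiler); hi <- min(n, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- apply(D, 1, which.min)
  valid0 <- is.finite(D[cbind(seq_len(n), nn)])
  if (!any(valid0)) stop("no valid neighbour pairs", call. = FALSE)
  mean_logdiv <- vapply(0:t_max, function(k) {
    i <- which(valid0 & seq_len(n) + k <= n & nn + k <= n)
    if (length(i) < 5) return(NA_real_)
    d <- sqrt(rowSums((Y[i + k, , drop = FALSE] - Y[nn[i] + k, , drop = FALSE])^2))
    d <- d[d > 0]
    if (length(d) < 5) return(NA_real_)
    mean(log(d))
  }, numeric(1))
  ks <- 0:t_max
  use <- ks %in% fit_range & is.finite(mean_logdiv)
  if (sum(use) < 2) stop("divergence curve too short to fit", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ks[use]), mean_logdiv[use])
  unname(fit$coefficients[2])
}

#' Recurrence quantification analysis
#'
#' Recurrence matrix at `radius` times the phase-space diameter; returns the
#' recurrence rate, determinism (fraction of recurrent points on diagonal
#' lines of length >= 2, main diagonal excluded), laminarity (vertical
#' lines), the longest diagonal, and the Shannon entropy of the diagonal
#' length distribution.
#'
#' @param x numeric series.
#' @param cfg an [embedding_config()].
#' @param l_min minimum diagonal/vertical line length (default 2).
#' @return named numeric vector: `RecurrenceRate`, `Determinism`,
#'   `Laminarity`, `LongestDiagonal`, `DiagonalEntropy`.
#' @export
rqa_metrics <- function(x, cfg = embedding_config(), l_min = 2) {
  tau <- cfg$tau %||% first_acf_zero(x)
  Y <- embed_series(x, cfg$m, tau)
  n <- nrow(Y)
  if (n < 50) stop("need >= 50 embedded points", call. = FALSE)
  D <- as.matrix(dist(Y))
  eps <- cfg$radius * max(D)
  R <- D <= eps
  diag(R) <- FALSE
  n_rec <- sum(R)
  if (n_rec == 0) stop("empty recurrence set", call. = FALSE)
  rr <- n_rec / (n * (n - 1))

  ## diagonal line lengths (main diagonal excluded; count both triangles)
  dl_list <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    i <- seq_len(n - k)
    d <- R[cbind(i, i + k)]
    r <- rle(d)
    dl_list[[k]] <- r$lengths[r$values]
  }
  up <- unlist(dl_list)
  ## the lower triangle mirrors the upper for a symmetric recurrence matrix
  diag_lengths <- c(up, up)
  det_pts <- sum(diag_lengths[diag_lengths >= l_min])
  determinism <- det_pts / n_rec
  longest <- if (length(diag_lengths)) max(diag_lengths) else 0L
  dl <- diag_lengths[diag_lengths >= l_min]
  d_ent <- if (length(dl)) {
    p <- table(dl) / length(dl)
    -sum(p * log(p))
  } else 0

  ## vertical line lengths for laminarity
  vert_lengths <- integer(0)
  for (j in seq_len(n)) {
    r <- rle(R[, j])
    vert_lengths <- c(vert_lengths, r$lengths[r$values])
  }
  lam_pts <- sum(vert_lengths[vert_lengths >= l_min])
  laminarity <- lam_pts / n_rec

  c(RecurrenceRate = rr, Determinism = determinism, Laminarity = laminarity,
    LongestDiagonal = as.numeric(longest), DiagonalEntropy = d_ent)
}
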