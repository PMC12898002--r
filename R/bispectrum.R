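## Bispectrum estimation, bootstrap class confidence intervals, and detection
## of 1D gap bands / 2D gap bounding boxes where class CIs do not overlap.

#' Direct (FFT) bispectrum estimate on the principal bifrequency domain
#'
#' Per Hann-windowed segment the triple product
#' `X(f1) * X(f2) * Conj(X(f1 + f2))` is accumulated and the averaged
#' magnitude returned on the principal domain `0 <= f2 <= f1`,
#' `f1 + f2 <= fs/2` (cells outside the domain are `NA`). The bispectrum
#' captures quadratic phase coupling between frequency pairs.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length (default 256).
#' @param overlap fractional overlap (default 0.5).
#' @return list of class `bispectrum_matrix`: `f1`, `f2` (Hz grids),
#'   `magnitude` (matrix indexed \[f1, f2\], symmetric where defined),
#'   `n_segments`.
#' @export
estimate_bispectrum <- function(x, fs, nperseg = 256, overlap = 0.5) {
  if (length(x) < 2 * nperseg)
    stop("input shorter than two segments", call. = FALSE)
  hop <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = hop)
  w <- hann_window(nperseg)
  nb <- nperseg %/% 2L + 1L              # bins 0..fs/2
  ## index matrix for f1+f2 (1-based bin index), NA outside principal domain
  i1 <- matrix(seq_len(nb), nb, nb)      # rows: f1
  i2 <- matrix(seq_len(nb), nb, nb, byrow = TRUE)
  isum <- i1 + i2 - 1L
  valid <- (i2 <= i1) & (isum <= nb)
  acc <- matrix(0 + 0i, nb, nb)
  for (s in starts) {
    X <- fft(x[s:(s + nperseg - 1L)] * w)
    Xh <- X[seq_len(nb)]
    tp <- (Xh %o% Xh)
    tp[valid] <- tp[valid] * Conj(X[isum[valid]])
    acc[valid] <- acc[valid] + tp[valid]
  }
  mag <- matrix(NA_real_, nb, nb)
  mag[valid] <- Mod(acc[valid]) / length(starts)
  ## mirror across the diagonal so magnitude(f1,f2) == magnitude(f2,f1)
  mag[upper.tri(mag)] <- t(mag)[upper.tri(mag)]
  freqs <- seq(0, nperseg / 2) * fs / nperseg
  structure(list(f1 = freqs, f2 = freqs, magnitude = mag,
                 n_segments = length(starts)),
            class = "bispectrum_matrix")
}

## Vectorized per-column quantiles (type-7 interpolation), NA columns pass
## through as NA.
col_quantiles <- function(mat, probs) {
  nb <- nrow(mat); nc <- ncol(mat)
  srt <- matrix(mat[order(col(mat), mat, na.last = TRUE)], nrow = nb)
  out <- matrix(NA_real_, length(probs), nc)
  na_col <- colSums(is.na(srt)) > 0
  h <- (nb - 1) * probs + 1
  lo_i <- floor(h); hi_i <- ceiling(h); g <- h - lo_i
  for (p in seq_along(probs)) {
    v <- srt[lo_i[p], ] * (1 - g[p]) + srt[hi_i[p], ] * g[p]
    v[na_col] <- NA_real_
    out[p, ] <- v
  }
  out
}

#' Bootstrap percentile confidence interval for a class mean spectrum
#'
#' Subjects (the exchangeable unit) are resampled with replacement; per-bin
#' percentile bounds of the bootstrap means are returned. Works for 1D
#' spectra (vectors) and 2D bispectra (matrices).
#'
#' @param spectra list of per-subject spectra sharing one grid (numeric
#'   vectors or matrices of identical dimension).
#' @param alpha two-sided miscoverage level (default 0.05 for 95% CIs).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param class_label optional label carried in the result.
#' @return list of class `class_band_ci`: `lower`, `upper`, `mean` (same
#'   shape as the inputs), `class_label`, `n_boot`, `n_subjects`, `alpha`.
#' @export
bootstrap_class_ci <- function(spectra, alpha = 0.05, n_boot = 1000,
                               seed = NULL, class_label = NULL) {
  stopifnot(length(spectra) >= 3)
  dims <- lapply(spectra, function(s) dim(s) %||% length(s))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("spectra must share one grid", call. = FALSE)
  shape <- dim(spectra[[1]])
  flat <- do.call(rbind, lapply(spectra, as.numeric))   # subjects x bins
  n <- nrow(flat)
  with_seed(seed, {
    ## resample subjects: bootstrap means as a count-matrix product
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    W <- matrix(0, n_boot, n)
    for (b in seq_len(n_boot)) {
      tb <- tabulate(idx[b, ], n)
      W[b, ] <- tb / n
    }
    boot_means <- W %*% flat
    qs <- col_quantiles(boot_means, c(alpha / 2, 1 - alpha / 2))
    lo <- qs[1, ]; hi <- qs[2, ]
    m <- colMeans(flat)
    reshape <- function(v) if (is.null(shape)) v else array(v, dim = shape)
    structure(list(lower = reshape(lo), upper = reshape(hi),
                   mean = reshape(m), class_label = class_label,
                   n_boot = n_boot, n_subjects = n, alpha = alpha),
              class = "class_band_ci")
  })
}

#' Detect 1D gap bands where two class CIs do not overlap
#'
#' A bin is a gap bin when `max(lower_a, lower_b) > min(upper_a, upper_b)`.
#' Adjacent gap bins are merged into maximal runs; runs shorter than
#' `min_bins` are dropped. The `direction` reports which class's CI lies
#' above within the band.
#'
#' @param ci_a,ci_b `class_band_ci` objects on a shared 1D grid.
#' @param min_bins minimum run length in bins (default 2).
#' @param freqs optional frequency grid (Hz) for reporting band extents.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `f_lo`, `f_hi`,
#'   `direction` (label or "a"/"b"); zero rows when no gaps exist.
#' @export
detect_gap_bands_1d <- function(ci_a, ci_b, min_bins = 2, freqs = NULL) {
  la <- as.numeric(ci_a$lower); ua <- as.numeric(ci_a$upper)
  lb <- as.numeric(ci_b$lower); ub <- as.numeric(ci_b$upper)
  if (length(la) != length(lb)) stop("grids differ", call. = FALSE)
  gap <- pmax(la, lb) > pmin(ua, ub)
  gap[is.na(gap)] <- FALSE
  runs <- rle(gap)
  ends <- cumsum(runs$lengths); starts <- c(1L, head(ends, -1) + 1L)
  keep <- which(runs$values & runs$lengths >= min_bins)
  if (length(keep) == 0)
    return(data.frame(bin_lo = integer(0), bin_hi = integer(0),
                      f_lo = numeric(0), f_hi = numeric(0),
                      direction = character(0)))
  lab_a <- ci_a$class_label %||% "a"
  lab_b <- ci_b$class_label %||% "b"
  out <- data.frame(bin_lo = starts[keep], bin_hi = ends[keep])
  out$f_lo <- if (!is.null(freqs)) freqs[out$bin_lo] else NA_real_
  out$f_hi <- if (!is.null(freqs)) freqs[out$bin_hi] else NA_real_
  out$direction <- vapply(seq_len(nrow(out)), function(i) {
    bins <- out$bin_lo[i]:out$bin_hi[i]
    if (mean(la[bins]) > mean(ub[bins])) lab_a else lab_b
  }, character(1))
  out
}

## Connected-component labelling of a logical matrix via row-run union-find:
## horizontal runs are extracted per row and runs in adjacent rows are merged
## when they touch (column overlap, extended by one for diagonal adjacency).
## connectivity: 8 (queen) or 4 (rook).
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  adj <- if (connectivity == 8) 1L else 0L

  ## runs per row
  run_row <- integer(0); run_lo <- integer(0); run_hi <- integer(0)
  row_first <- integer(nr); row_count <- integer(nr)
  for (r in seq_len(nr)) {
    rl <- rle(mask[r, ])
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    sel <- rl$values
    row_first[r] <- length(run_row) + 1L
    row_count[r] <- sum(sel)
    if (any(sel)) {
      run_row <- c(run_row, rep.int(r, sum(sel)))
      run_lo <- c(run_lo, starts[sel]); run_hi <- c(run_hi, ends[sel])
    }
  }
  n_runs <- length(run_row)
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nr)[-1]) {
    if (row_count[r] == 0L || row_count[r - 1L] == 0L) next
    a <- row_first[r - 1L]:(row_first[r - 1L] + row_count[r - 1L] - 1L)
    b <- row_first[r]:(row_first[r] + row_count[r] - 1L)
    for (i in b) {
      lo_i <- run_lo[i] - adj; hi_i <- run_hi[i] + adj
      for (j in a) {
        if (run_lo[j] <= hi_i && run_hi[j] >= lo_i) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  comp <- match(roots, unique(roots))
  for (i in seq_len(n_runs))
    lab[run_row[i], run_lo[i]:run_hi[i]] <- comp[i]
  lab
}

#' Detect 2D gap bounding boxes where two class CIs do not overlap
#'
#' The binary disjoint-CI mask is labelled into 8-connected components and
#' the tight bounding box of each component (of at least `min_area` cells) is
#' returned, ordered by descending component size with ties broken by the
#' top-left corner.
#'
#' @param ci_a,ci_b `class_band_ci` objects on a shared 2D grid.
#' @param min_area minimum component area in cells (default 4).
#' @param f1,f2 optional axis grids (Hz) for reporting box extents.
#' @return data.frame with `component_id`, index bounds `row_lo`, `row_hi`,
#'   `col_lo`, `col_hi`, `n_cells`, and Hz extents `f1_lo`, `f1_hi`, `f2_lo`,
#'   `f2_hi` when grids are given.
#' @export
detect_gap_boxes_2d <- function(ci_a, ci_b, min_area = 4,
                                f1 = NULL, f2 = NULL) {
  la <- ci_a$lower; ua <- ci_a$upper
  lb <- ci_b$lower; ub <- ci_b$upper
  if (!all(dim(la) == dim(lb))) stop("grids differ", call. = FALSE)
  gap <- pmax(la, lb) > pmin(ua, ub)
  gap[is.na(gap)] <- FALSE
  lab <- label_components(gap, connectivity = 8)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  empty <- data.frame(component_id = integer(0), row_lo = integer(0),
                      row_hi = integer(0), col_lo = integer(0),
                      col_hi = integer(0), n_cells = integer(0),
                      f1_lo = numeric(0), f1_hi = numeric(0),
                      f2_lo = numeric(0), f2_hi = numeric(0))
  if (length(ids) == 0) return(empty)
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(component_id = id,
               row_lo = min(w[, 1]), row_hi = max(w[, 1]),
               col_lo = min(w[, 2]), col_hi = max(w[, 2]),
               n_cells = nrow(w))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_cells >= min_area, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out <- out[order(-out$n_cells, out$row_lo, out$col_lo), , drop = FALSE]
  out$component_id <- seq_len(nrow(out))
  out$f1_lo <- if (!is.null(f1)) f1[out$row_lo] else NA_real_
  out$f1_hi <- if (!is.null(f1)) f1[out$row_hi] else NA_real_
  out$f2_lo <- if (!is.null(f2)) f2[out$col_lo] else NA_real_
  out$f2_hi <- if (!is.null(f2)) f2[out$col_hi] else NA_real_
  rownames(out) <- NULL
  out
}
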