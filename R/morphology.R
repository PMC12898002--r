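## Image-style statistics, binary morphology/topology, GLCM texture, and
## box-counting fractal dimension for spectrogram/bispectrum regions.

#' Intensity statistics of a rectangular region
#'
#' Scalar statistics of the cell values of a sub-matrix cut from a
#' spectrogram or bispectrum: moments, quantile spread, Shannon entropy of
#' the L1-normalized values, energy, peak, intensity-weighted centroids, and
#' (when a frequency axis is supplied) the weighted frequency centroid and
#' bandwidth along that axis.
#'
#' @param region numeric matrix of non-negative values.
#' @param freq_axis optional frequency calibration (Hz) of the rows.
#' @return named numeric vector: `MeanValue`, `MedianValue`, `StdValue`,
#'   `IQRValue`, `SkewValue`, `KurtosisValue`, `EntropyValue`, `EnergyValue`,
#'   `PeakValue`, `CentroidX` (column axis, 0-based), `CentroidY` (row axis,
#'   0-based), `FrequencyCentroid`, `FrequencyBandwidth`. Entropy and
#'   centroids are `NA` for an all-zero region; higher moments are `NA` below
#'   4 cells.
#' @export
region_statistics <- function(region, freq_axis = NULL) {
  v <- as.numeric(region)
  if (length(v) == 0 || !all(is.finite(v))) stop("region must be non-empty and finite", call. = FALSE)
  n <- length(v)
  out <- c(MeanValue = mean(v), MedianValue = median(v),
           StdValue = sqrt(mean((v - mean(v))^2)),
           IQRValue = stats::IQR(v, type = 7),
           SkewValue = if (n >= 4) moment_skewness(v) else NA_real_,
           KurtosisValue = if (n >= 4) moment_kurtosis_excess(v) else NA_real_,
           EntropyValue = NA_real_, EnergyValue = sum(v^2),
           PeakValue = max(v), CentroidX = NA_real_, CentroidY = NA_real_,
           FrequencyCentroid = NA_real_, FrequencyBandwidth = NA_real_)
  tot <- sum(v)
  if (tot > 0) {
    p <- v / tot
    nz <- p > 0
    out["EntropyValue"] <- -sum(p[nz] * log(p[nz]))
    cols <- matrix(rep(seq_len(ncol(region)) - 1, each = nrow(region)),
                   nrow(region))
    rows <- matrix(rep(seq_len(nrow(region)) - 1, ncol(region)), nrow(region))
    out["CentroidX"] <- sum(region * cols) / tot
    out["CentroidY"] <- sum(region * rows) / tot
    if (!is.null(freq_axis)) {
      rowp <- rowSums(region) / tot
      fc <- sum(rowp * freq_axis)
      out["FrequencyCentroid"] <- fc
      out["FrequencyBandwidth"] <- sqrt(sum(rowp * (freq_axis - fc)^2))
    }
  }
  out
}

## Otsu threshold on a 256-bin histogram of the region values.
otsu_threshold <- function(v, n_bins = 256) {
  r <- range(v)
  if (r[1] == r[2]) return(r[2] / 2)     # degenerate: max/2 fallback
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  centers[k]
}

#' Binarize a region by Otsu thresholding
#'
#' Otsu's method on a 256-bin value histogram; the mask is `values >
#' threshold`. A constant region falls back to a threshold of `max/2`
#' (yielding an all-false mask, flagged).
#'
#' @param region numeric matrix.
#' @return list of class `binary_mask`: `mask` (logical matrix, same shape),
#'   `threshold`, `method` ("otsu" or "max/2"), `flagged`.
#' @export
binarize_region <- function(region) {
  v <- as.numeric(region)
  degenerate <- length(unique(v)) < 2
  thr <- otsu_threshold(v)
  mask <- if (degenerate) matrix(FALSE, nrow(region), ncol(region))
          else matrix(region > thr, nrow(region), ncol(region))
  structure(list(mask = mask, threshold = thr,
                 method = if (degenerate) "max/2" else "otsu",
                 flagged = degenerate),
            class = "binary_mask")
}

## Perimeter = count of exposed cell edges of the foreground.
mask_perimeter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up <- pad[1:nr, 2:(nc + 1)]
  down <- pad[3:(nr + 2), 2:(nc + 1)]
  left <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  sum(core & !up) + sum(core & !down) + sum(core & !left) + sum(core & !right)
}

## Box-counting fractal dimension of a mask: least-squares slope of
## log N(s) vs log (1/s) over box sizes 1, 2, 4, ...
box_counting_dimension <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  smax <- min(nr, nc)
  sizes <- 2^(0:floor(log2(smax)))
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 2 || !any(m)) return(NA_real_)
  counts <- vapply(sizes, function(s) {
    ri <- ceiling(seq_len(nr) / s)
    ci <- ceiling(seq_len(nc) / s)
    ## aggregate into s x s blocks, count non-empty blocks
    agg <- rowsum(t(rowsum(m + 0, ri)), ci)
    sum(agg > 0)
  }, numeric(1))
  lx <- log(1 / sizes); ly <- log(counts)
  unname(stats::lm.fit(cbind(1, lx), ly)$coefficients[2])
}

#' Morphological and topological descriptors of a binary mask
#'
#' Foreground area, tight bounding-box geometry, perimeter (exposed cell
#' edges), compactness, connected components (8-connectivity), holes
#' (4-connected background components not touching the border), Euler number
#' (components - holes), and box-counting fractal dimension.
#'
#' @param mask a `binary_mask` from [binarize_region()] or a logical matrix.
#' @return named numeric vector: `Area`, `BoundingBoxWidth`,
#'   `BoundingBoxHeight`, `BoundingBoxDiagonal`, `AspectRatio`, `Perimeter`,
#'   `Compactness`, `ConnectedComponents`, `Holes`, `EulerNumber`,
#'   `FractalDimension`. All zero (with `NA` ratios) for an all-false mask.
#' @export
region_morphology <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  stopifnot(is.logical(m), is.matrix(m), length(m) > 0)
  if (!any(m)) {
    return(c(Area = 0, BoundingBoxWidth = 0, BoundingBoxHeight = 0,
             BoundingBoxDiagonal = 0, AspectRatio = NA_real_, Perimeter = 0,
             Compactness = NA_real_, ConnectedComponents = 0, Holes = 0,
             EulerNumber = 0, FractalDimension = NA_real_))
  }
  w <- which(m, arr.ind = TRUE)
  bb_h <- diff(range(w[, 1])) + 1L      # rows
  bb_w <- diff(range(w[, 2])) + 1L      # cols
  area <- sum(m)
  perim <- mask_perimeter(m)
  comp <- max(label_components(m, connectivity = 8))
  ## holes: 4-connected background components not touching the border
  bg <- label_components(!m, connectivity = 4)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- length(setdiff(unique(as.integer(bg)), c(0L, border_ids)))
  c(Area = area,
    BoundingBoxWidth = bb_w, BoundingBoxHeight = bb_h,
    ## diagonal between the centres of the opposite corner cells
    BoundingBoxDiagonal = sqrt((bb_w - 1)^2 + (bb_h - 1)^2),
    AspectRatio = bb_w / bb_h,
    Perimeter = perim,
    Compactness = 4 * pi * area / perim^2,
    ConnectedComponents = comp,
    Holes = holes,
    EulerNumber = comp - holes,
    FractalDimension = box_counting_dimension(m))
}

#' Gray-level co-occurrence texture descriptors
#'
#' The region is quantized to `levels` equal-width gray levels; symmetric
#' normalized co-occurrence matrices for the supplied offsets are averaged
#' and summarized as contrast, homogeneity, correlation, and energy.
#'
#' @param region numeric matrix (>= 2x2).
#' @param levels number of gray levels (default 8).
#' @param offsets list of integer `c(dr, dc)` offsets
#'   (default `list(c(0, 1), c(1, 0))`, distance-1 horizontal and vertical).
#' @return named numeric vector: `TextureContrast`, `TextureHomogeneity`,
#'   `TextureCorrelation` (NA for a single-level region), `TextureEnergy`,
#'   plus attribute `glcm` (the averaged normalized matrix).
#' @export
glcm_texture <- function(region, levels = 8,
                         offsets = list(c(0, 1), c(1, 0))) {
  stopifnot(is.matrix(region), nrow(region) >= 2, ncol(region) >= 2)
  r <- range(region)
  q <- if (r[1] == r[2]) matrix(1L, nrow(region), ncol(region))
       else {
         cuts <- seq(r[1], r[2], length.out = levels + 1)
         matrix(pmin(levels, findInterval(region, cuts, rightmost.closed = TRUE)),
                nrow(region))
       }
  P <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
    a <- q[r1 + max(0, -dr), c1 + max(0, -dc)]
    b <- q[r1 + max(0, dr), c1 + max(0, dc)]
    counts <- tabulate((a - 1L) * levels + b, nbins = levels * levels)
    Pk <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + Pk + t(Pk)                       # symmetric
  }
  P <- P / sum(P)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else NA_real_
  out <- c(TextureContrast = sum(P * (i - j)^2),
           TextureHomogeneity = sum(P / (1 + (i - j)^2)),
           TextureCorrelation = corr,
           TextureEnergy = sum(P^2))
  attr(out, "glcm") <- P
  out
}

#' Cut a rectangular region out of a spectrogram or bispectrum matrix
#'
#' @param mat numeric matrix.
#' @param box one row of a [detect_gap_boxes_2d()] result (or any list with
#'   `row_lo`, `row_hi`, `col_lo`, `col_hi`).
#' @return the sub-matrix.
#' @export
cut_region <- function(mat, box) {
  mat[box$row_lo:box$row_hi, box$col_lo:box$col_hi, drop = FALSE]
}
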