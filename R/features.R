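## Feature naming grammar and per-subject multi-domain feature extraction.

conditions_all <- function() c("NoseInspiration", "NoseExpiration",
                               "MouthInspiration", "MouthExpiration")

#' Compose a feature name
#'
#' Names follow `<Condition>_<Context>_<Descriptor>`: condition is a
#' route+phase pair (`MouthInspiration`, ...) or `Average` (mean over the
#' four conditions); context is `Full` (whole analysis band), `Range` (a
#' class-pair spectral gap band), or `BBox<i>` (the i-th bispectral gap
#' bounding box); the descriptor may itself contain underscores.
#'
#' @param condition,context,descriptor name parts.
#' @return character feature name.
#' @export
make_feature_name <- function(condition, context, descriptor) {
  stopifnot(condition %in% c(conditions_all(), "Average"),
            grepl("^(Full|Range|BBox[0-9]*)$", context),
            nzchar(descriptor))
  paste(condition, context, descriptor, sep = "_")
}

#' Parse a feature name back into its parts
#'
#' @param name feature name(s) produced by [make_feature_name()].
#' @return data.frame with `condition`, `context`, `descriptor`; errors on a
#'   name that does not follow the grammar.
#' @export
parse_feature_name <- function(name) {
  parts <- regmatches(name, regexec(
    "^(NoseInspiration|NoseExpiration|MouthInspiration|MouthExpiration|Average)_(Full|Range|BBox[0-9]*)_(.+)$",
    name))
  bad <- vapply(parts, length, integer(1)) != 4
  if (any(bad))
    stop("invalid feature name(s): ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  data.frame(condition = vapply(parts, `[`, character(1), 2),
             context = vapply(parts, `[`, character(1), 3),
             descriptor = vapply(parts, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Defaults chosen for a 10,240 Hz sampling rate and desk-scale cohorts; all
#' knobs are documented with their units.
#'
#' @param fs sampling rate, Hz.
#' @param k cross-validation folds.
#' @param criteria stratification criteria.
#' @param band analysis band, Hz.
#' @param nperseg_psd Welch segment length, samples.
#' @param nperseg_bispec bispectrum segment length, samples.
#' @param midflow_fraction central fraction of each breath phase analysed.
#' @param n_boot bootstrap replicates for gap-region CIs.
#' @param alpha CI miscoverage (0.05 gives 95% CIs).
#' @param min_bins minimum 1D gap-band width, bins.
#' @param min_area minimum 2D gap-component area, cells.
#' @param max_boxes bispectral boxes carried into features.
#' @param keep stage-1 univariate retention count.
#' @param target_n final selected feature count.
#' @param rfe_step RFE elimination fraction per iteration.
#' @param n_bags trees in the final bagged model.
#' @param n_bags_select trees in selection-stage ensembles.
#' @param nonlinear_n maximum series length for O(n^2) nonlinear estimators.
#' @param include_families feature families to extract.
#' @param min_snr_db segment SNR gate, dB.
#' @return named list of configuration values.
#' @export
tbs_config <- function(fs = 10240, k = 3,
                       criteria = c("age", "bmi", "nc", "ahi", "sex", "mps"),
                       band = c(75, 3000),
                       nperseg_psd = 1024, nperseg_bispec = 256,
                       midflow_fraction = 0.5,
                       n_boot = 200, alpha = 0.05,
                       min_bins = 2, min_area = 4, max_boxes = 2,
                       keep = 200, target_n = 35, rfe_step = 0.1,
                       n_bags = 100, n_bags_select = 30,
                       nonlinear_n = 400,
                       include_families = c("spectral", "time", "nonlinear",
                                            "wavelet", "mfcc", "cqt",
                                            "morphology"),
                       min_snr_db = 5) {
  as.list(environment())
}

## ---- per-subject condition processing ---------------------------------------

## Preprocess one subject's recordings into per-condition cached data:
## averaged mid-flow PSD, bispectrum, and the fold-independent "Full"
## descriptors.
process_subject <- function(rec, cfg) {
  out <- list()
  for (route in c("nose", "mouth")) {
    r <- rec[[route]]
    filt <- bandpass_filter(r$samples, r$fs, band = cfg$band)
    segs <- segment_breath_phases(filt, r$fs, route = route,
                                  params = segmentation_config(
                                    min_snr_db = cfg$min_snr_db))
    segs <- Filter(function(s) s$retained, segs)
    for (phase in c("inspiration", "expiration")) {
      cond <- paste0(if (route == "nose") "Nose" else "Mouth",
                     if (phase == "inspiration") "Inspiration" else "Expiration")
      ph_segs <- Filter(function(s) s$phase == phase, segs)
      if (!length(ph_segs)) { out[[cond]] <- NULL; next }
      mids <- lapply(ph_segs, extract_midflow, fraction = cfg$midflow_fraction)
      x <- unlist(mids)
      psd <- welch_psd(x, r$fs, nperseg = min(cfg$nperseg_psd, length(x)))
      bis <- estimate_bispectrum(x, r$fs, nperseg = cfg$nperseg_bispec)
      out[[cond]] <- list(psd = psd, bispec = bis, fs = r$fs,
                          base = condition_base_features(x, r$fs, psd, cfg))
    }
  }
  out
}

## Fold-independent descriptors of one condition ("Full" context).
condition_base_features <- function(x, fs, psd, cfg) {
  fam <- cfg$include_families
  feats <- c()
  if ("spectral" %in% fam) {
    feats <- c(feats, spectral_descriptors(psd, band = cfg$band))
    feats <- c(feats, SpectralFlux = spectral_flux(x, fs))
  }
  if ("time" %in% fam) {
    td <- time_domain_descriptors(x, fs)
    feats <- c(feats, td,
               CoefVariation = sd(abs(x)) / mean(abs(x)))
  }
  if ("nonlinear" %in% fam) {
    ds <- max(1L, length(x) %/% cfg$nonlinear_n)
    xs <- x[seq(1, length(x), by = ds)]
    feats <- c(feats, KatzFD = katz_fd(xs))
    if (length(xs) >= 100) feats <- c(feats, HiguchiFD = higuchi_fd(xs))
    if (length(xs) >= 256) feats <- c(feats, Hurst = hurst_exponent(xs))
    nl <- try(suppressWarnings(
      rqa_metrics(xs, embedding_config(m = 3, radius = 0.1))), silent = TRUE)
    if (!inherits(nl, "try-error")) feats <- c(feats, nl)
    ly <- try(suppressWarnings(
      largest_lyapunov(xs, embedding_config(m = 3))), silent = TRUE)
    if (!inherits(ly, "try-error")) feats <- c(feats, Lyapunov = ly)
  }
  if ("wavelet" %in% fam && length(x) >= 32)
    feats <- c(feats, wavelet_stats(x, levels = 5))
  if ("mfcc" %in% fam) feats <- c(feats, mfcc_stats(x, fs))
  if ("cqt" %in% fam) {
    cq <- try(cqt_stats(x, fs), silent = TRUE)
    if (!inherits(cq, "try-error")) feats <- c(feats, cq)
  }
  feats
}

## ---- gap learning (training subjects only) ----------------------------------

## Learn, per condition, the 1D PSD gap bands and 2D bispectral gap boxes
## separating the two classes, from training subjects only.
learn_gap_regions <- function(cond_data, train_ids, labels, cfg, seed = NULL) {
  classes <- sort(unique(as.character(labels[train_ids])))
  stopifnot(length(classes) == 2)
  gaps <- list()
  for (cond in conditions_all()) {
    per_class <- lapply(classes, function(cl) {
      ids <- train_ids[as.character(labels[train_ids]) == cl]
      keep <- Filter(function(id) !is.null(cond_data[[id]][[cond]]), ids)
      list(psd = lapply(keep, function(id) cond_data[[id]][[cond]]$psd$power),
           bis = lapply(keep, function(id) cond_data[[id]][[cond]]$bispec$magnitude))
    })
    if (length(per_class[[1]]$psd) < 3 || length(per_class[[2]]$psd) < 3) {
      gaps[[cond]] <- list(bands = NULL, boxes = NULL)
      next
    }
    ci1 <- bootstrap_class_ci(per_class[[1]]$psd, alpha = cfg$alpha,
                              n_boot = cfg$n_boot,
                              seed = child_seed(seed, 1L),
                              class_label = classes[1])
    ci2 <- bootstrap_class_ci(per_class[[2]]$psd, alpha = cfg$alpha,
                              n_boot = cfg$n_boot,
                              seed = child_seed(seed, 2L),
                              class_label = classes[2])
    ref_id <- Filter(function(id) !is.null(cond_data[[id]][[cond]]),
                     names(cond_data))[[1]]
    freqs <- cond_data[[ref_id]][[cond]]$psd$freqs
    bands <- detect_gap_bands_1d(ci1, ci2, min_bins = cfg$min_bins,
                                 freqs = freqs)
    bi1 <- bootstrap_class_ci(per_class[[1]]$bis, alpha = cfg$alpha,
                              n_boot = cfg$n_boot,
                              seed = child_seed(seed, 3L),
                              class_label = classes[1])
    bi2 <- bootstrap_class_ci(per_class[[2]]$bis, alpha = cfg$alpha,
                              n_boot = cfg$n_boot,
                              seed = child_seed(seed, 4L),
                              class_label = classes[2])
    f1 <- cond_data[[ref_id]][[cond]]$bispec$f1
    boxes <- detect_gap_boxes_2d(bi1, bi2, min_area = cfg$min_area,
                                 f1 = f1, f2 = f1)
    gaps[[cond]] <- list(bands = bands, boxes = boxes, freqs = freqs, f1 = f1)
  }
  gaps
}

## ---- feature table assembly --------------------------------------------------

## Region-dependent (Range / BBox) descriptors of one condition given frozen
## gap regions.
condition_region_features <- function(cd, gap, cfg) {
  feats <- list()
  ## Range: spectral descriptors inside each gap band, averaged across bands;
  ## falls back to the full analysis band when no gap band was found.
  bands <- gap$bands
  if (is.null(bands) || nrow(bands) == 0) {
    rng <- spectral_descriptors(cd$psd, band = cfg$band)
  } else {
    per_band <- lapply(seq_len(nrow(bands)), function(i) {
      f_lo <- gap$freqs[bands$bin_lo[i]]
      f_hi <- gap$freqs[bands$bin_hi[i]]
      tryCatch(spectral_descriptors(cd$psd, band = c(f_lo, f_hi)),
               error = function(e) NULL)
    })
    per_band <- Filter(Negate(is.null), per_band)
    rng <- if (length(per_band)) Reduce(`+`, per_band) / length(per_band)
           else spectral_descriptors(cd$psd, band = cfg$band)
  }
  feats$Range <- rng

  if ("morphology" %in% cfg$include_families) {
    mag <- cd$bispec$magnitude
    mag[is.na(mag)] <- 0
    boxes <- gap$boxes
    for (b in seq_len(cfg$max_boxes)) {
      region <- if (!is.null(boxes) && nrow(boxes) >= b)
        cut_region(mag, boxes[b, ])
      else if (!is.null(boxes) && nrow(boxes) >= 1)
        cut_region(mag, boxes[1, ])
      else mag
      fr <- if (!is.null(boxes) && nrow(boxes) >= min(b, 1))
        cd$bispec$f1[boxes[min(b, nrow(boxes)), "row_lo"]:boxes[min(b, nrow(boxes)), "row_hi"]]
      else cd$bispec$f1
      rs <- region_statistics(region, freq_axis = fr)
      gl <- if (nrow(region) >= 2 && ncol(region) >= 2)
        glcm_texture(region) else NULL
      bm <- binarize_region(region)
      mo <- region_morphology(bm)
      v <- c(rs, gl, mo)
      attr(v, "glcm") <- NULL
      feats[[paste0("BBox", b)]] <- v
    }
  }
  feats
}

## Assemble the subjects x features matrix for a set of subjects under frozen
## gap regions. Adds the "Average" condition (mean over available conditions)
## and imputes residual non-finite cells with the column median.
assemble_feature_table <- function(cond_data, subject_ids, gaps, cfg) {
  rows <- lapply(subject_ids, function(id) {
    sd_ <- cond_data[[id]]
    per_cond <- list()
    for (cond in conditions_all()) {
      cd <- sd_[[cond]]
      if (is.null(cd)) next
      vals <- c()
      base <- cd$base
      if (length(base))
        vals <- c(vals, setNames(as.numeric(base),
                                 make_feature_name(cond, "Full", names(base))))
      reg <- condition_region_features(cd, gaps[[cond]], cfg)
      for (ctx in names(reg)) {
        v <- reg[[ctx]]
        vals <- c(vals, setNames(as.numeric(v),
                                 make_feature_name(cond, ctx, names(v))))
      }
      per_cond[[cond]] <- vals
    }
    all_vals <- unlist(per_cond, use.names = TRUE)
    names(all_vals) <- sub("^[^.]*\\.", "", names(all_vals))
    ## Average condition: mean across conditions per Context_Descriptor
    tails <- sub("^[A-Za-z]+_", "", names(all_vals))
    avg <- tapply(all_vals, tails, mean, na.rm = TRUE)
    all_vals <- c(all_vals, setNames(as.numeric(avg),
                                     paste0("Average_", names(avg))))
    all_vals
  })
  names(rows) <- subject_ids
  all_names <- unique(unlist(lapply(rows, names)))
  X <- matrix(NA_real_, length(rows), length(all_names),
              dimnames = list(subject_ids, all_names))
  for (i in seq_along(rows)) X[i, names(rows[[i]])] <- rows[[i]]
  ## drop mostly-missing columns, impute the rest with the column median
  frac_bad <- colMeans(!is.finite(X))
  X <- X[, frac_bad <= 0.2, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- median(X[!bad, j])
  }
  ## constant columns carry no information and break normalization
  keep <- apply(X, 2, function(v) length(unique(v)) > 1)
  X[, keep, drop = FALSE]
}
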