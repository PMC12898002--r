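## End-to-end evaluation: preprocess -> gap learning on fold-train ->
## feature extraction -> normalization choice -> three-stage selection ->
## bagged one-vs-one models -> metrics and reports.

severity_pairs <- function(levels_present = severity_levels()) {
  lv <- intersect(severity_levels(), levels_present)
  if (length(lv) < 2) stop("need at least two severity classes", call. = FALSE)
  pairs <- combn(lv, 2, simplify = FALSE)
  vapply(pairs, paste, character(1), collapse = "_vs_")
}

#' Evaluate the full tracheal-breathing-sound pipeline
#'
#' Orchestrates, for every one-vs-one severity pair and every
#' cross-validation fold: band-pass filtering and breath-phase segmentation,
#' gap-region learning on the fold's training subjects only, feature
#' extraction under the frozen gaps, mutual-information normalization choice
#' (training statistics only), three-stage feature selection, bagged CART
#' training, and the metric suite (train/test AUC, per-feature stability
#' deltas, SHAP summaries, fold-wise anthropometric correlations).
#'
#' @param recordings per-subject list of `nose`/`mouth` waveforms as produced
#'   by [generate_cohort()] (each with `samples` and `fs`), or a directory of
#'   `<subject>_<route>.wav` files.
#' @param metadata subject records (`subject_id`, `severity`, `ahi`, `age`,
#'   `sex`, `bmi`, `nc`, `mps`).
#' @param config a [tbs_config()].
#' @param seed integer seed controlling folds, bootstraps, and ensembles.
#' @param pairs optional subset of pair labels such as `"Non_vs_Severe"`
#'   (default: all pairs present in the metadata).
#' @param verbose print stage progress.
#' @return object of class `tbs_report`; see [print.tbs_report()].
#' @export
evaluate_pipeline <- function(recordings, metadata, config = tbs_config(),
                              seed = NULL, pairs = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(recordings) && length(recordings) == 1)
    recordings <- read_recordings_dir(recordings, metadata)
  stopifnot(all(metadata$subject_id %in% names(recordings)))

  say("preprocessing %d subjects", nrow(metadata))
  t0 <- proc.time()[3]
  cond_data <- lapply(metadata$subject_id, function(id)
    process_subject(recordings[[id]], config))
  names(cond_data) <- metadata$subject_id
  say("  done in %.1f s", proc.time()[3] - t0)

  folds <- stratified_multicriteria_kfold(metadata, k = config$k,
                                          criteria = config$criteria,
                                          seed = child_seed(seed, 1L))
  fold_vec <- folds$fold[metadata$subject_id]
  labels_all <- setNames(as.character(metadata$severity), metadata$subject_id)

  pair_labels <- pairs %||% severity_pairs(unique(metadata$severity))
  model_results <- list()
  stability <- list()
  rankings <- list()
  correlations <- list()

  for (pl in pair_labels) {
    cls <- strsplit(pl, "_vs_")[[1]]
    pair_ids <- metadata$subject_id[metadata$severity %in% cls]
    y_pair <- labels_all[pair_ids]
    fold_results <- list()
    feat_stats <- list()
    say("pair %s (%d subjects)", pl, length(pair_ids))

    for (f in seq_len(config$k)) {
      train_ids <- pair_ids[fold_vec[pair_ids] != f]
      test_ids <- pair_ids[fold_vec[pair_ids] == f]
      if (length(unique(y_pair[train_ids])) < 2 ||
          length(unique(y_pair[test_ids])) < 2) next
      t0 <- proc.time()[3]
      gaps <- learn_gap_regions(cond_data, train_ids, labels_all, config,
                                seed = child_seed(seed, 10L * f))
      X <- assemble_feature_table(cond_data, pair_ids, gaps, config)
      tr_rows <- match(train_ids, rownames(X))
      te_rows <- match(test_ids, rownames(X))
      norm <- select_normalization(X, y_pair, train_rows = tr_rows)
      Xn <- norm$normalized
      sel <- select_features(Xn[tr_rows, , drop = FALSE], y_pair[train_ids],
                             keep = config$keep, target_n = config$target_n,
                             step = config$rfe_step,
                             n_bags = config$n_bags_select,
                             seed = child_seed(seed, 100L * f))
      Xs <- Xn[, sel$selected, drop = FALSE]
      model <- train_bagged_ovo(Xs[tr_rows, , drop = FALSE], y_pair[train_ids],
                                n_bags = config$n_bags,
                                seed = child_seed(seed, 200L * f))
      s_tr <- predict(model, Xs[tr_rows, , drop = FALSE])
      s_te <- predict(model, Xs[te_rows, , drop = FALSE])
      auc_tr <- auc(s_tr, y_pair[train_ids])
      auc_te <- auc(s_te, y_pair[test_ids])
      sv <- shap_values(model, Xs[tr_rows, , drop = FALSE])

      ## per-feature single-feature AUC and label correlation, train and test
      ybin_tr <- as.numeric(y_pair[train_ids] == cls[2])
      ybin_te <- as.numeric(y_pair[test_ids] == cls[2])
      pf <- lapply(sel$selected, function(fn) {
        xtr <- Xs[tr_rows, fn]; xte <- Xs[te_rows, fn]
        c(auc_tr = auc(xtr, y_pair[train_ids]),
          auc_te = auc(xte, y_pair[test_ids]),
          cor_tr = if (sd(xtr) > 0) cor(xtr, ybin_tr) else 0,
          cor_te = if (sd(xte) > 0) cor(xte, ybin_te) else 0)
      })
      pf <- do.call(rbind, pf)
      rownames(pf) <- sel$selected
      feat_stats[[length(feat_stats) + 1L]] <-
        data.frame(feature = sel$selected, fold = f,
                   train_auc = pf[, "auc_tr"], test_auc = pf[, "auc_te"],
                   train_corr = pf[, "cor_tr"], test_corr = pf[, "cor_te"],
                   corr_rank = rank(-abs(pf[, "cor_tr"]), ties.method = "min"),
                   shap_rank = rank(-sv$mean_abs[sel$selected],
                                    ties.method = "min"),
                   mean_abs_shap = sv$mean_abs[sel$selected],
                   stringsAsFactors = FALSE, row.names = NULL)

      correlations[[length(correlations) + 1L]] <-
        feature_anthro_correlations(
          Xs[te_rows, , drop = FALSE],
          metadata[match(test_ids, metadata$subject_id), , drop = FALSE],
          rep(f, length(te_rows)), pair = pl)

      fold_results[[length(fold_results) + 1L]] <- list(
        fold = f, train_auc = auc_tr, test_auc = auc_te,
        normalization = norm$method,
        n_features = length(sel$selected),
        selected = sel$selected,
        gap_summary = vapply(conditions_all(), function(cn) {
          g <- gaps[[cn]]
          c(bands = if (is.null(g$bands)) 0L else nrow(g$bands),
            boxes = if (is.null(g$boxes)) 0L else nrow(g$boxes))
        }, integer(2)))
      say("  fold %d: train AUC %.3f / test AUC %.3f (%.1f s)",
          f, auc_tr, auc_te, proc.time()[3] - t0)
    }

    fs_all <- do.call(rbind, feat_stats)
    model_results[[pl]] <- list(
      pair = pl, classes = cls, folds = fold_results,
      mean_train_auc = mean(vapply(fold_results, `[[`, numeric(1), "train_auc")),
      mean_test_auc = mean(vapply(fold_results, `[[`, numeric(1), "test_auc")),
      feature_stats = fs_all)

    ## stability and ranking aggregated over folds
    ag <- aggregate(cbind(train_auc, test_auc, train_corr, test_corr,
                          corr_rank, shap_rank) ~ feature, fs_all, mean)
    ## fold-averaged absolute deltas, classified by the stability rule
    d_auc <- tapply(abs(fs_all$train_auc - fs_all$test_auc), fs_all$feature, mean)
    d_corr <- tapply(abs(fs_all$train_corr - fs_all$test_corr), fs_all$feature, mean)
    st <- stability_assess(names(d_auc), as.numeric(d_auc),
                           numeric(length(d_auc)),
                           as.numeric(d_corr), numeric(length(d_corr)))
    st$pair <- pl
    stability[[pl]] <- st

    rk <- data.frame(feature = ag$feature,
                     corr_rank = ag$corr_rank, shap_rank = ag$shap_rank,
                     overall_rank = aggregate_ranks(ag$corr_rank, ag$shap_rank),
                     pair = pl, stringsAsFactors = FALSE)
    rankings[[pl]] <- rk[order(rk$overall_rank, rk$feature), , drop = FALSE]
  }

  ranking_all <- do.call(rbind, rankings)
  overall <- aggregate(cbind(corr_rank, shap_rank, overall_rank) ~ feature,
                       ranking_all, mean)
  overall <- overall[order(overall$overall_rank, overall$feature), , drop = FALSE]

  structure(list(
    pairs = model_results,
    ranking = overall,
    ranking_by_pair = ranking_all,
    stability = do.call(rbind, stability),
    correlations = do.call(rbind, correlations),
    folds = folds,
    config = config,
    seed = seed
  ), class = "tbs_report")
}

## read <subject>_<route>.wav files from a directory
read_recordings_dir <- function(dir, metadata) {
  recs <- lapply(metadata$subject_id, function(id) {
    lapply(c(nose = "nose", mouth = "mouth"), function(route) {
      w <- read_wav(file.path(dir, paste0(id, "_", route, ".wav")))
      list(samples = w$samples, fs = w$fs)
    })
  })
  names(recs) <- metadata$subject_id
  recs
}

#' @export
print.tbs_report <- function(x, ...) {
  cat("Tracheal breathing sound severity evaluation (", x$folds$k,
      "-fold CV)\n", sep = "")
  for (pl in names(x$pairs)) {
    p <- x$pairs[[pl]]
    cat(sprintf("  %-22s mean train AUC %.3f | mean test AUC %.3f (%d folds)\n",
                pl, p$mean_train_auc, p$mean_test_auc, length(p$folds)))
  }
  cat("Top-ranked features (overall average rank):\n")
  print(utils::head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.tbs_report <- function(object, ...) {
  auc_tab <- data.frame(
    pair = names(object$pairs),
    mean_train_auc = vapply(object$pairs, `[[`, numeric(1), "mean_train_auc"),
    mean_test_auc = vapply(object$pairs, `[[`, numeric(1), "mean_test_auc"),
    row.names = NULL)
  st <- object$stability
  out <- list(auc = auc_tab,
              stability_counts = table(st$stability_class),
              n_features_ranked = nrow(object$ranking),
              top_features = utils::head(object$ranking, 10),
              strongest_correlations = utils::head(
                object$correlations[order(-abs(object$correlations$r)), ], 10))
  class(out) <- "summary.tbs_report"
  out
}

#' @export
print.summary.tbs_report <- function(x, ...) {
  cat("Per-pair AUC:\n"); print(x$auc, row.names = FALSE)
  cat("\nFeature stability classes:\n"); print(x$stability_counts)
  cat("\nTop features by overall rank:\n")
  print(x$top_features, row.names = FALSE)
  cat("\nStrongest fold-wise anthropometric correlations:\n")
  print(x$strongest_correlations, row.names = FALSE)
  invisible(x)
}

#' Write a report's tables to CSV/JSON files
#'
#' Emits `ranking.csv` (feature ranks), `stability.csv` (per-feature deltas
#' and stability classes), `correlations.csv` (fold-wise anthropometric
#' correlations), `fold_balance.csv`, and `auc.json` (per-pair fold AUCs).
#'
#' @param report a `tbs_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tbs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$ranking, file.path(dir, "ranking.csv"), row.names = FALSE)
  write.csv(report$stability, file.path(dir, "stability.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(report$folds$balance, file.path(dir, "fold_balance.csv"),
            row.names = FALSE)
  aucs <- lapply(report$pairs, function(p) {
    list(mean_train_auc = p$mean_train_auc,
         mean_test_auc = p$mean_test_auc,
         folds = lapply(p$folds, function(fr)
           list(fold = fr$fold, train_auc = fr$train_auc,
                test_auc = fr$test_auc, normalization = fr$normalization)))
  })
  jsonlite::write_json(aucs, file.path(dir, "auc.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
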