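## Three-stage per-pair feature selection: univariate AUC filter,
## tree-SHAP ranking, recursive feature elimination; plus rank aggregation.

#' Univariate discrimination filter
#'
#' Each feature is scored as `|AUC - 0.5|` (rank-sum AUC of the feature as a
#' raw score against the binary labels); the top `keep` features are
#' retained, ties broken by feature-name lexical order.
#'
#' @param features numeric matrix/data.frame (rows = subjects, named columns).
#' @param labels binary class labels.
#' @param keep number of features to retain (default 200). When `keep`
#'   exceeds the feature count, all are retained with a warning.
#' @return the filtered feature matrix, with attribute `scores` (named,
#'   sorted by retention order).
#' @export
univariate_filter <- function(features, labels, keep = 200) {
  X <- as.matrix(features)
  stopifnot(!is.null(colnames(X)))
  if (length(unique(labels)) != 2) stop("labels must be binary", call. = FALSE)
  if (keep < 1) stop("keep must be >= 1", call. = FALSE)
  scores <- vapply(seq_len(ncol(X)), function(j)
    abs(auc(X[, j], labels) - 0.5), numeric(1))
  names(scores) <- colnames(X)
  if (keep > ncol(X)) {
    warning("keep exceeds feature count; retaining all features")
    keep <- ncol(X)
  }
  ord <- order(-scores, colnames(X))
  sel <- ord[seq_len(keep)]
  out <- X[, sel, drop = FALSE]
  attr(out, "scores") <- scores[sel]
  out
}

#' Rank features by mean absolute tree-SHAP attribution
#'
#' @param model a [train_bagged_ovo()] ensemble trained on exactly the
#'   table's features.
#' @param features the feature table to explain.
#' @return data.frame with `feature`, `mean_abs_shap`, `shap_rank` (minimum
#'   rank on ties; rank 1 = most important), sorted by rank.
#' @export
shap_rank <- function(model, features) {
  sv <- shap_values(model, features)
  imp <- sv$mean_abs
  rk <- rank(-imp, ties.method = "min")
  out <- data.frame(feature = names(imp), mean_abs_shap = unname(imp),
                    shap_rank = as.integer(rk), stringsAsFactors = FALSE)
  out[order(out$shap_rank, out$feature), , drop = FALSE]
}

#' Recursive feature elimination with SHAP importance
#'
#' Iteratively trains the bagged ensemble, drops the lowest-importance `step`
#' fraction of features (at least one per iteration, never crossing
#' `target_n`), and stops at exactly `target_n` features.
#'
#' @param features numeric matrix/data.frame with named columns.
#' @param labels binary labels.
#' @param target_n final feature-subset size (default 35).
#' @param step fraction of features eliminated per iteration (default 0.1).
#' @param n_bags trees per intermediate ensemble (default 50).
#' @param seed integer seed.
#' @return the reduced feature matrix, with attribute `trace`: a list of
#'   character vectors of the features dropped at each iteration.
#' @export
rfe_select <- function(features, labels, target_n = 35, step = 0.1,
                       n_bags = 50, seed = NULL) {
  X <- as.matrix(features)
  stopifnot(!is.null(colnames(X)))
  if (target_n > ncol(X)) stop("target_n exceeds feature count", call. = FALSE)
  ## univariate discrimination as a deterministic tie-break: correlated
  ## informative features can carry zero ensemble attribution (the trees pick
  ## one of them), and ties must not be resolved by column order
  uni <- vapply(seq_len(ncol(X)), function(j)
    abs(auc(X[, j], labels) - 0.5), numeric(1))
  names(uni) <- colnames(X)
  trace <- list()
  it <- 0L
  while (ncol(X) > target_n) {
    it <- it + 1L
    model <- train_bagged_ovo(X, labels, n_bags = n_bags,
                              seed = child_seed(seed, it))
    imp <- shap_values(model, X)$mean_abs
    n_drop <- min(max(1L, floor(step * ncol(X))), ncol(X) - target_n)
    ord <- order(imp, uni[names(imp)], names(imp))
    drop_names <- names(imp)[ord][seq_len(n_drop)]
    trace[[it]] <- drop_names
    X <- X[, setdiff(colnames(X), drop_names), drop = FALSE]
  }
  attr(X, "trace") <- trace
  X
}

#' Aggregate correlation and SHAP ranks into an overall rank
#'
#' Overall rank is the arithmetic mean of the correlation-based and
#' SHAP-based average ranks (lower is better); `(1, 2)` gives 1.5.
#'
#' @param corr_rank,shap_rank positive ranks (vectorized).
#' @return numeric overall rank(s).
#' @export
aggregate_ranks <- function(corr_rank, shap_rank) {
  if (any(corr_rank < 1) || any(shap_rank < 1))
    stop("ranks must be >= 1", call. = FALSE)
  (corr_rank + shap_rank) / 2
}

#' Run the three-stage selection pipeline on a training table
#'
#' Univariate AUC filter to `keep`, then SHAP ranking (recorded), then RFE to
#' `target_n`.
#'
#' @param features training feature matrix (named columns).
#' @param labels binary labels.
#' @param keep stage-1 retention count (default 200).
#' @param target_n final subset size (default 35).
#' @param step RFE elimination fraction (default 0.1).
#' @param n_bags trees per selection-stage ensemble (default 50).
#' @param seed integer seed.
#' @return list with `selected` (feature names), `table` (reduced matrix),
#'   `univariate_scores`, `shap_ranking`, `rfe_trace`.
#' @export
select_features <- function(features, labels, keep = 200, target_n = 35,
                            step = 0.1, n_bags = 50, seed = NULL) {
  stage1 <- suppressWarnings(univariate_filter(features, labels, keep = keep))
  model <- train_bagged_ovo(stage1, labels, n_bags = n_bags,
                            seed = child_seed(seed, 1000L))
  ranking <- shap_rank(model, stage1)
  target_n <- min(target_n, ncol(stage1))
  stage3 <- rfe_select(stage1, labels, target_n = target_n, step = step,
                       n_bags = n_bags, seed = child_seed(seed, 2000L))
  list(selected = colnames(stage3), table = stage3,
       univariate_scores = attr(stage1, "scores"),
       shap_ranking = ranking,
       rfe_trace = attr(stage3, "trace"))
}
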