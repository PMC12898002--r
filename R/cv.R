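## Multi-criteria stratified k-fold, AUC, stability classes, and fold-wise
## anthropometric correlations.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a positive-class score
#' exceeds a negative-class score, with ties credited 0.5.
#'
#' @param scores numeric score per subject.
#' @param labels binary labels; the second sorted unique value is positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  lab <- as.character(labels)
  classes <- sort(unique(lab))
  if (length(classes) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  pos <- lab == classes[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## balance cost of a fold assignment: squared standardized fold-mean
## deviations for continuous criteria + chi-square-style divergence for
## categorical criteria, summed over folds.
balance_cost <- function(cohort, fold, criteria_cont, criteria_cat, k) {
  cost <- 0
  for (v in criteria_cont) {
    x <- cohort[[v]]
    mu <- mean(x); s <- sd(x)
    if (s == 0) next
    z <- (x - mu) / s
    for (f in seq_len(k)) {
      zi <- z[fold == f]
      if (length(zi)) cost <- cost + mean(zi)^2
    }
  }
  for (v in criteria_cat) {
    x <- as.character(cohort[[v]])
    p_all <- table(x) / length(x)
    for (f in seq_len(k)) {
      xi <- x[fold == f]
      if (!length(xi)) next
      p_f <- table(factor(xi, levels = names(p_all))) / length(xi)
      cost <- cost + sum((p_f - p_all)^2 / pmax(p_all, 1e-12))
    }
  }
  cost
}

#' Multi-criteria stratified k-fold assignment
#'
#' Within each severity class, subjects are sorted by a composite z-score of
#' the continuous criteria and snake-dealt to folds (preserving class
#' proportions); local pairwise swaps between folds are then accepted while
#' they reduce the balance cost (squared standardized fold-mean deviations
#' for continuous criteria plus a chi-square-style divergence for categorical
#' criteria) without moving fold sizes outside the tolerance.
#'
#' @param cohort data.frame of subject records with at least `subject_id` and
#'   `severity`, plus the criteria columns.
#' @param k number of folds (>= 2; default 3).
#' @param criteria subset of `c("age", "bmi", "nc", "ahi", "sex", "mps")`
#'   (default all six).
#' @param seed integer seed.
#' @param size_tol allowed relative deviation of fold sizes from `n/k`
#'   (default 0.15).
#' @param max_sweeps swap-improvement sweeps (default 3).
#' @return object of class `fold_assignment`: `fold` (named integer vector,
#'   subject_id -> fold), `k`, `balance` (per fold x class counts and per-fold
#'   summaries of the criteria), `cost`.
#' @export
stratified_multicriteria_kfold <- function(cohort, k = 3,
                                           criteria = c("age", "bmi", "nc",
                                                        "ahi", "sex", "mps"),
                                           seed = NULL, size_tol = 0.15,
                                           max_sweeps = 3) {
  stopifnot(k >= 2, all(c("subject_id", "severity") %in% names(cohort)))
  criteria <- match.arg(criteria, c("age", "bmi", "nc", "ahi", "sex", "mps"),
                        several.ok = TRUE)
  cont <- intersect(criteria, c("age", "bmi", "nc", "ahi"))
  cat_ <- intersect(criteria, c("sex", "mps"))
  n <- nrow(cohort)
  fold <- integer(n)

  with_seed(seed, {
    for (sev in unique(cohort$severity)) {
      idx <- which(cohort$severity == sev)
      if (length(idx) < k)
        warning("class ", sev, " has fewer members than k; absent from some folds")
      ## composite z-score ordering
      if (length(cont)) {
        z <- rowSums(scale(as.matrix(cohort[idx, cont, drop = FALSE])),
                     na.rm = TRUE)
        z[is.na(z)] <- 0
      } else z <- runif(length(idx))
      ord <- idx[order(z, runif(length(idx)))]
      ## snake deal: 1..k, k..1, 1..k, ...
      snake <- rep(c(seq_len(k), rev(seq_len(k))), length.out = length(ord))
      fold[ord] <- snake
    }

    base_size <- n / k
    size_ok <- function(f) {
      sz <- tabulate(f, k)
      all(abs(sz - base_size) <= size_tol * base_size + 1)
    }
    cur_cost <- balance_cost(cohort, fold, cont, cat_, k)
    ## pairwise swap refinement within each severity class
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (sev in unique(cohort$severity)) {
        idx <- which(cohort$severity == sev)
        if (length(idx) < 2) next
        cand <- idx[sample.int(length(idx))]
        for (a_i in seq_along(cand)) {
          for (b_i in seq_len(a_i - 1L)) {
            a <- cand[a_i]; b <- cand[b_i]
            if (fold[a] == fold[b]) next
            f2 <- fold
            f2[c(a, b)] <- fold[c(b, a)]
            nc2 <- balance_cost(cohort, f2, cont, cat_, k)
            if (nc2 < cur_cost - 1e-12 && size_ok(f2)) {
              fold <- f2; cur_cost <- nc2; improved <- TRUE
            }
          }
        }
      }
      if (!improved) break
    }

    balance <- fold_balance_report(cohort, fold, k)
    structure(list(fold = setNames(fold, cohort$subject_id), k = k,
                   balance = balance, cost = cur_cost,
                   criteria = criteria),
              class = "fold_assignment")
  })
}

## per fold x class: counts and summaries of the balance criteria
fold_balance_report <- function(cohort, fold, k) {
  rows <- list()
  for (sev in unique(cohort$severity)) {
    for (f in seq_len(k)) {
      sel <- cohort$severity == sev & fold == f
      if (!any(sel)) {
        rows[[length(rows) + 1L]] <- data.frame(
          severity = sev, fold = f, n = 0L, ahi_mean = NA, ahi_sd = NA,
          age_mean = NA, bmi_mean = NA, nc_mean = NA, n_male = NA,
          stringsAsFactors = FALSE)
        next
      }
      s <- cohort[sel, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        severity = sev, fold = f, n = nrow(s),
        ahi_mean = mean(s$ahi), ahi_sd = sd(s$ahi),
        age_mean = mean(s$age), bmi_mean = mean(s$bmi),
        nc_mean = mean(s$nc),
        n_male = sum(s$sex == "M"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Multi-criteria stratified ", x$k, "-fold assignment (",
      length(x$fold), " subjects; balance cost ", signif(x$cost, 4), ")\n",
      sep = "")
  print(stats::xtabs(n ~ severity + fold, x$balance))
  invisible(x)
}

#' Classify feature stability from train/test AUC and correlation deltas
#'
#' A feature is `stable` when the mean absolute train-test AUC difference is
#' at most 0.01 and the mean absolute train-test correlation difference is at
#' most 0.1; `slightly_unstable` when the AUC delta still passes but the
#' correlation delta lies in (0.1, 0.15\]; otherwise `unstable`.
#'
#' @param feature character vector of feature names.
#' @param train_auc,test_auc per-feature AUCs (matrices features x folds or
#'   vectors of fold-averaged values).
#' @param train_corr,test_corr per-feature label correlations, same shape.
#' @return data.frame with `feature`, `abs_delta_auc`, `abs_delta_corr`,
#'   `stability_class`.
#' @export
stability_assess <- function(feature, train_auc, test_auc,
                             train_corr, test_corr) {
  fold_mean <- function(m) if (is.matrix(m)) rowMeans(abs(m)) else abs(m)
  d_auc <- fold_mean(train_auc - test_auc)
  d_corr <- fold_mean(train_corr - test_corr)
  if (anyNA(d_auc) || anyNA(d_corr))
    stop("missing fold values", call. = FALSE)
  cls <- ifelse(d_auc <= 0.01 & d_corr <= 0.1, "stable",
         ifelse(d_auc <= 0.01 & d_corr <= 0.15, "slightly_unstable",
                "unstable"))
  data.frame(feature = feature, abs_delta_auc = d_auc,
             abs_delta_corr = d_corr, stability_class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold-wise Pearson correlations between features and anthropometrics
#'
#' Pearson r per (feature, anthropometric variable) computed independently
#' within each fold's subject subset (sex encoded 0/1, Mallampati score as
#' integers). Reporting only: the values never feed back into selection or
#' training.
#'
#' @param features numeric matrix (rows aligned with `cohort`).
#' @param cohort subject records with `age`, `bmi`, `nc`, `ahi`, `sex`, `mps`.
#' @param fold_assignment a [stratified_multicriteria_kfold()] result (or an
#'   integer fold vector aligned with rows).
#' @param pair optional pair label carried into the records.
#' @return data.frame with `feature`, `variable`, `fold`, `pair`, `r`
#'   (`NA`-flagged when a column has zero variance within a fold).
#' @export
feature_anthro_correlations <- function(features, cohort, fold_assignment,
                                        pair = NA_character_) {
  fold <- if (inherits(fold_assignment, "fold_assignment"))
    fold_assignment$fold[cohort$subject_id] else fold_assignment
  X <- as.matrix(features)
  vars <- list(age = cohort$age, bmi = cohort$bmi, nc = cohort$nc,
               ahi = cohort$ahi,
               sex = as.numeric(cohort$sex == "M"),
               mps = as.numeric(cohort$mps))
  rows <- list()
  for (f in sort(unique(fold))) {
    sel <- which(fold == f)
    if (length(sel) < 3) next
    for (v in names(vars)) {
      y <- vars[[v]][sel]
      sy <- sd(y)
      for (j in seq_len(ncol(X))) {
        xj <- X[sel, j]
        r <- if (sd(xj) == 0 || sy == 0) NA_real_ else cor(xj, y)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = colnames(X)[j], variable = v, fold = f, pair = pair,
          r = r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
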