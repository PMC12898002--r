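## Bagged CART ensembles and exact path-dependent tree-SHAP attributions.

## Convert an rpart classification tree into an explicit node-array form:
## children (NA at leaves), split feature index, threshold, direction,
## training cover, and leaf value = probability of the positive class.
## rpart must be fitted with maxcompete = 0, maxsurrogate = 0.
parse_rpart <- function(fit, feature_names) {
  fr <- fit$frame
  node_num <- as.integer(rownames(fr))
  n_nodes <- nrow(fr)
  is_leaf <- fr$var == "<leaf>"
  feature <- rep(NA_integer_, n_nodes)
  threshold <- rep(NA_real_, n_nodes)
  right_if_ge <- rep(NA, n_nodes)
  cl <- rep(NA_integer_, n_nodes); cr <- rep(NA_integer_, n_nodes)
  pos <- match(node_num, node_num)  # identity; lookup helper below
  lookup <- function(num) match(num, node_num)
  sp <- fit$splits
  si <- 0L
  for (i in seq_len(n_nodes)) {
    if (is_leaf[i]) next
    si <- si + 1L
    feature[i] <- match(as.character(fr$var[i]), feature_names)
    threshold[i] <- sp[si, "index"]
    ## ncat = -1: left branch is x < threshold; +1: left branch is x >= threshold
    right_if_ge[i] <- sp[si, "ncat"] < 0
    cl[i] <- lookup(2L * node_num[i])
    cr[i] <- lookup(2L * node_num[i] + 1L)
  }
  ## positive-class probability per node (second level of the response)
  yval2 <- fr$yval2
  value <- yval2[, 1 + ncol(yval2) %/% 2 + 1]  # prob columns follow counts
  list(children_left = cl, children_right = cr, feature = feature,
       threshold = threshold, right_if_ge = right_if_ge,
       value = as.numeric(value), cover = as.numeric(fr$n),
       feature_names = feature_names)
}

## Does x go left at node j?
goes_left <- function(tree, j, x) {
  v <- x[tree$feature[j]]
  if (tree$right_if_ge[j]) v < tree$threshold[j] else v >= tree$threshold[j]
}

tree_predict_row <- function(tree, x) {
  j <- 1L
  while (!is.na(tree$children_left[j])) {
    j <- if (goes_left(tree, j, x)) tree$children_left[j] else tree$children_right[j]
  }
  tree$value[j]
}

tree_predict <- function(tree, X) {
  apply(X, 1, function(x) tree_predict_row(tree, x))
}

## path-dependent expected value given a feature subset (oracle helper,
## exported for tests through tbsa:::)
tree_expvalue <- function(tree, x, S) {
  g <- function(j) {
    if (is.na(tree$children_left[j])) return(tree$value[j])
    l <- tree$children_left[j]; r <- tree$children_right[j]
    if (tree$feature[j] %in% S) {
      if (goes_left(tree, j, x)) g(l) else g(r)
    } else {
      (g(l) * tree$cover[l] + g(r) * tree$cover[r]) / tree$cover[j]
    }
  }
  g(1L)
}

## Exact path-dependent tree-SHAP for one sample on one parsed tree.
## Returns phi (length M); sum(phi) + E[f] equals the tree prediction.
treeshap_tree <- function(tree, x, M) {
  phi <- numeric(M)

  extend <- function(m, pz, po, pi) {
    L <- length(m$d) + 1L
    m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
    m$w <- c(m$w, if (L == 1L) 1 else 0)
    if (L > 1L) for (i in (L - 1L):1L) {
      m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / L
      m$w[i] <- pz * m$w[i] * (L - i) / L
    }
    m
  }
  unwind <- function(m, i) {
    L <- length(m$d)
    n <- m$w[L]
    oi <- m$o[i]; zi <- m$z[i]
    if (L - 1L >= 1L) for (j in (L - 1L):1L) {
      if (oi != 0) {
        t <- m$w[j]
        m$w[j] <- n * L / (j * oi)
        n <- t - m$w[j] * zi * (L - j) / L
      } else {
        m$w[j] <- m$w[j] * L / (zi * (L - j))
      }
    }
    keep <- setdiff(seq_len(L), i)
    m$d <- m$d[keep]; m$z <- m$z[keep]; m$o <- m$o[keep]
    m$w <- m$w[-L]
    m
  }

  recurse <- function(j, m, pz, po, pi) {
    m <- extend(m, pz, po, pi)
    if (is.na(tree$children_left[j])) {
      L <- length(m$d)
      if (L >= 2L) for (i in 2L:L) {
        w <- sum(unwind(m, i)$w)
        phi[m$d[i]] <<- phi[m$d[i]] + w * (m$o[i] - m$z[i]) * tree$value[j]
      }
    } else {
      f <- tree$feature[j]
      l <- tree$children_left[j]; r <- tree$children_right[j]
      hot <- if (goes_left(tree, j, x)) l else r
      cold <- if (hot == l) r else l
      iz <- 1; io <- 1
      k <- match(f, m$d)
      if (!is.na(k)) { iz <- m$z[k]; io <- m$o[k]; m <- unwind(m, k) }
      recurse(hot,  m, iz * tree$cover[hot]  / tree$cover[j], io, f)
      recurse(cold, m, iz * tree$cover[cold] / tree$cover[j], 0,  f)
    }
  }
  m0 <- list(d = integer(0), z = numeric(0), o = numeric(0), w = numeric(0))
  recurse(1L, m0, 1, 1, 0L)
  phi
}

#' Train a bagged one-vs-one tree ensemble
#'
#' `n_bags` CART trees (rpart, unlimited depth, no pruning), each fitted on a
#' bootstrap resample of the training subjects; the ensemble score is the
#' mean predicted probability of the positive class (the second level of
#' `labels`).
#'
#' @param features numeric matrix/data.frame (rows = subjects).
#' @param labels factor or vector with exactly two classes; the second sorted
#'   unique value is the positive class.
#' @param n_bags number of bootstrap trees (default 100).
#' @param seed integer seed; identical seeds give identical ensembles.
#' @return object of class `bagged_ovo` with elements `trees` (parsed node
#'   arrays), `feature_names`, `classes`, `base_values` (per-tree training
#'   mean score).
#' @export
train_bagged_ovo <- function(features, labels, n_bags = 100, seed = NULL) {
  X <- as.matrix(features)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  y <- factor(as.character(labels), levels = classes)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  ## rpart needs syntactic names; keep a mapping
  safe <- make.names(colnames(X), unique = TRUE)
  d <- data.frame(X)
  colnames(d) <- safe
  d$..y <- y
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 4, minbucket = 2, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  n <- nrow(X)
  with_seed(seed, {
    trees <- vector("list", n_bags)
    for (b in seq_len(n_bags)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      fit <- rpart::rpart(..y ~ ., data = d[idx, , drop = FALSE],
                          method = "class", control = ctrl)
      trees[[b]] <- parse_rpart(fit, safe)
    }
    structure(list(trees = trees, feature_names = colnames(X),
                   safe_names = safe, classes = classes,
                   n_bags = n_bags),
              class = "bagged_ovo")
  })
}

#' Predict ensemble scores (positive-class probability)
#'
#' @param object a [train_bagged_ovo()] ensemble.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return numeric score per row in \[0, 1\].
#' @export
predict.bagged_ovo <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  scores <- vapply(object$trees, function(tr) tree_predict(tr, X),
                   numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X))
  rowMeans(scores)
}

#' @export
print.bagged_ovo <- function(x, ...) {
  cat("Bagged one-vs-one CART ensemble:", x$n_bags, "trees,",
      length(x$feature_names), "features;",
      "positive class:", x$classes[2], "\n")
  invisible(x)
}

#' Exact tree-SHAP attributions for a bagged ensemble
#'
#' Path-dependent tree-SHAP per tree, averaged over the ensemble. For every
#' row, the attributions plus the base value reproduce the ensemble score
#' (Shapley efficiency/additivity).
#'
#' @param model a [train_bagged_ovo()] ensemble.
#' @param features matrix/data.frame of rows to explain (must carry exactly
#'   the model's features).
#' @return list with `shap` (rows x features attribution matrix),
#'   `base_value` (scalar expected score), `mean_abs` (named mean absolute
#'   attribution per feature).
#' @export
shap_values <- function(model, features) {
  if (!inherits(model, "bagged_ovo")) stop("model must be a bagged_ovo", call. = FALSE)
  if (!setequal(colnames(features), model$feature_names) ||
      ncol(features) != length(model$feature_names))
    stop("feature-set mismatch between model and table", call. = FALSE)
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  M <- ncol(X)
  acc <- matrix(0, nrow(X), M)
  base <- 0
  for (tr in model$trees) {
    for (i in seq_len(nrow(X))) {
      acc[i, ] <- acc[i, ] + treeshap_tree(tr, X[i, ], M)
    }
    base <- base + tree_expvalue(tr, X[1, ], integer(0))
  }
  shap <- acc / length(model$trees)
  base <- base / length(model$trees)
  colnames(shap) <- model$feature_names
  list(shap = shap, base_value = base,
       mean_abs = colMeans(abs(shap)))
}
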