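## Independent brute-force oracles used across the suite.

## flood-fill connected-component labelling (queue-based)
flood_label <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  if (conn == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  for (st in which(mask)) {
    if (lab[st]) next
    cur <- cur + 1L; q <- st; lab[st] <- cur
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      r0 <- (v - 1) %% nr + 1; c0 <- (v - 1) %/% nr + 1
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- (cc[ok] - 1) * nr + rr[ok]
      idx <- idx[mask[idx] & lab[idx] == 0]
      lab[idx] <- cur; q <- c(q, idx)
    }
  }
  lab
}

## exhaustive-pair AUC
auc_pairs <- function(scores, labels) {
  lab <- as.character(labels)
  classes <- sort(unique(lab))
  sp <- scores[lab == classes[2]]; sn <- scores[lab == classes[1]]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

## brute-force Shapley values on a parsed tree (path-dependent expectations)
brute_shap_tree <- function(tree, x, M) {
  expv <- function(S) tbsa:::tree_expvalue(tree, x, S)
  phi <- numeric(M)
  for (i in seq_len(M)) {
    others <- setdiff(seq_len(M), i)
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else
        asplit(combn(others, k), 2)
      for (S in combs) {
        w <- factorial(k) * factorial(M - k - 1) / factorial(M)
        phi[i] <- phi[i] + w * (expv(c(S, i)) - expv(S))
      }
    }
  }
  phi
}

## random explicit tree over M features (same node-array layout as parsed rpart)
random_tree <- function(M, depth = 3, n0 = 64) {
  cl <- cr <- ft <- integer(0); th <- val <- cov <- numeric(0); rg <- logical(0)
  new_node <- function() {
    cl <<- c(cl, NA_integer_); cr <<- c(cr, NA_integer_)
    ft <<- c(ft, NA_integer_); th <<- c(th, NA_real_)
    val <<- c(val, NA_real_); cov <<- c(cov, NA_real_); rg <<- c(rg, TRUE)
    length(cl)
  }
  build <- function(d, n) {
    j <- new_node(); cov[j] <<- n
    if (d >= depth || n < 4 || runif(1) < 0.2) { val[j] <<- runif(1); return(j) }
    ft[j] <<- sample.int(M, 1); th[j] <<- rnorm(1)
    nl <- sample(seq(1, n - 1), 1)
    l <- build(d + 1, nl); r <- build(d + 1, n - nl)
    cl[j] <<- l; cr[j] <<- r
    j
  }
  build(0, n0)
  list(children_left = cl, children_right = cr, feature = ft, threshold = th,
       right_if_ge = rg, value = val, cover = cov)
}

## tiny in-memory synthetic cohort reused by pipeline-level tests
make_mini_cohort <- function(sizes = c(Non = 4, Severe = 4), seed = 77) {
  generate_cohort(sizes, seed = seed)
}

## fast pipeline configuration for tests
fast_config <- function(...) {
  tbs_config(k = 2, n_boot = 50, keep = 40, target_n = 8,
             n_bags = 15, n_bags_select = 10, max_boxes = 1,
             nonlinear_n = 300, ...)
}

## synthetic per-subject condition data (no audio) for leakage-guard tests:
## per condition a small PSD and bispectrum whose level depends on the class.
fake_cond_data <- function(ids, shift, seed = 1, nbins = 24, nb2 = 8) {
  withr::with_seed(seed, {
    out <- lapply(seq_along(ids), function(i) {
      sh <- shift[i]
      conds <- lapply(tbsa:::conditions_all(), function(cn) {
        power <- abs(rnorm(nbins, 10 + sh, 0.5))
        mag <- matrix(abs(rnorm(nb2 * nb2, 5 + sh, 0.5)), nb2, nb2)
        mag <- (mag + t(mag)) / 2
        list(psd = list(freqs = seq(0, 3000, length.out = nbins),
                        power = power),
             bispec = list(f1 = seq(0, 1500, length.out = nb2),
                           f2 = seq(0, 1500, length.out = nb2),
                           magnitude = mag),
             base = c(MeanPower = mean(power) + rnorm(1, 0, 0.05)))
      })
      names(conds) <- tbsa:::conditions_all()
      conds
    })
    names(out) <- ids
    out
  })
}
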