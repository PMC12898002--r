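test_that("AUC matches its closed forms and exhaustive pair counting", {
  expect_equal(auc(c(1, 2, 3, 10, 20), c("a", "a", "a", "b", "b")), 1)
  ## labels (+,-,+) with scores (0.9, 0.8, 0.4): one win, one loss
  expect_equal(auc(c(0.9, 0.8, 0.4), c("pos", "neg", "pos")), 0.5)
  expect_equal(auc(rep(1, 10), rep(c("a", "b"), 5)), 0.5)
  expect_error(auc(1:4, rep("a", 4)), "two classes")

  withr::with_seed(1, {
    for (r in 1:25) {
      n <- sample(6:30, 1)
      sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      lb <- sample(c("a", "b"), n, replace = TRUE)
      if (length(unique(lb)) < 2) next
      expect_equal(auc(sc, lb), auc_pairs(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("stratified splitter conserves class counts for the study cohort", {
  meta <- do.call(rbind, lapply(severity_levels(), function(sv)
    sample_anthropometrics(sv, tbsa:::cohort_reference()[[sv]]$n,
                           seed = match(sv, severity_levels()))))
  fa <- stratified_multicriteria_kfold(meta, k = 3, seed = 1)
  expect_s3_class(fa, "fold_assignment")
  ## exact partition: every subject in exactly one fold
  expect_setequal(names(fa$fold), meta$subject_id)
  expect_true(all(fa$fold %in% 1:3))
  ## per-class totals conserved (74 / 35 / 50 / 40), total 199
  counts <- tapply(fa$balance$n, fa$balance$severity, sum)
  expect_equal(as.numeric(counts[severity_levels()]), c(74, 35, 50, 40))
  expect_equal(sum(fa$balance$n), 199)
  ## every class present in every fold
  expect_true(all(fa$balance$n > 0))
})

test_that("a single-class cohort of identical subjects splits evenly", {
  meta <- data.frame(subject_id = sprintf("s%02d", 1:10), severity = "Mild",
                     ahi = 8, age = 50, sex = "M", bmi = 30, nc = 40, mps = 2)
  fa <- stratified_multicriteria_kfold(meta, k = 2, seed = 3)
  expect_equal(sort(unname(tabulate(fa$fold, 2))), c(5, 5))
})

test_that("the balanced assignment beats random class-stratified splits", {
  meta <- do.call(rbind, lapply(c("Non", "Severe"), function(sv)
    sample_anthropometrics(sv, 30, seed = match(sv, severity_levels()) + 10)))
  fa <- stratified_multicriteria_kfold(meta, k = 3, seed = 2)
  cont <- c("age", "bmi", "nc", "ahi"); cat_ <- c("sex", "mps")
  rand_costs <- withr::with_seed(99, vapply(1:100, function(r) {
    f <- integer(nrow(meta))
    for (sv in unique(meta$severity)) {
      idx <- which(meta$severity == sv)
      f[idx] <- sample(rep(1:3, length.out = length(idx)))
    }
    tbsa:::balance_cost(meta, f, cont, cat_, 3)
  }, numeric(1)))
  expect_lte(fa$cost, median(rand_costs))
})

test_that("a class smaller than k warns and may be absent from folds", {
  meta <- rbind(sample_anthropometrics("Non", 9, seed = 1),
                sample_anthropometrics("Severe", 2, seed = 2))
  expect_warning(fa <- stratified_multicriteria_kfold(meta, k = 3, seed = 4),
                 "fewer members")
  expect_equal(sum(fa$balance$n[fa$balance$severity == "Severe"]), 2)
})

test_that("fold assignment is deterministic given a seed", {
  meta <- sample_anthropometrics("Moderate", 30, seed = 5)
  f1 <- stratified_multicriteria_kfold(meta, k = 3, seed = 6)
  f2 <- stratified_multicriteria_kfold(meta, k = 3, seed = 6)
  expect_identical(f1$fold, f2$fold)
})

test_that("stability classes follow the caption thresholds", {
  st <- stability_assess(c("f1", "f2", "f3"),
                         train_auc = c(0.9, 0.901806, 0.92),
                         test_auc = c(0.9, 0.9, 0.9),
                         train_corr = c(0.5, 0.637229, 0.7),
                         test_corr = c(0.45, 0.5, 0.5))
  expect_equal(st$stability_class, c("stable", "slightly_unstable", "unstable"))

  ## matrix input: deltas averaged across folds
  tr <- matrix(c(0.9, 0.9, 0.95, 0.93), 2, 2, byrow = TRUE)
  te <- matrix(c(0.895, 0.905, 0.90, 0.90), 2, 2, byrow = TRUE)
  trc <- matrix(0.5, 2, 2); tec <- matrix(0.45, 2, 2)
  st2 <- stability_assess(c("a", "b"), tr, te, trc, tec)
  expect_equal(st2$abs_delta_auc, c(0.005, 0.04))
  expect_equal(st2$stability_class, c("stable", "unstable"))
  expect_error(stability_assess("a", NA_real_, 1, 0.1, 0.1), "missing")
})

test_that("fold-wise anthropometric correlations match the textbook formula", {
  meta <- sample_anthropometrics("Mild", 12, seed = 7)
  fold <- rep(1:2, each = 6)
  X <- cbind(nc_copy = meta$nc, other = seq_len(12))
  rec <- feature_anthro_correlations(X, meta, fold, pair = "p")
  r_nc <- rec[rec$feature == "nc_copy" & rec$variable == "nc", ]
  expect_equal(r_nc$r, c(1, 1), tolerance = 1e-12)

  ## 5-point hand computation
  x5 <- c(1, 2, 4, 5, 9); y5 <- c(2, 1, 5, 4, 8)
  meta5 <- data.frame(subject_id = paste0("q", 1:5), severity = "Non",
                      ahi = 1, age = y5, sex = "F", bmi = 25, nc = 38, mps = 1)
  rec5 <- feature_anthro_correlations(cbind(f = x5), meta5, rep(1, 5))
  r_hand <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((y5 - mean(y5))^2))
  expect_equal(rec5$r[rec5$variable == "age"], r_hand, tolerance = 1e-12)

  ## affine invariance and zero-variance flagging
  rec_aff <- feature_anthro_correlations(cbind(f = 3 * x5 + 7), meta5,
                                         rep(1, 5))
  expect_equal(rec_aff$r[rec_aff$variable == "age"], r_hand, tolerance = 1e-12)
  expect_true(is.na(rec5$r[rec5$variable == "bmi"]))
})
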