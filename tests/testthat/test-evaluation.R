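test_that("confusion counts match a four-way counting loop", {
  ct <- confusion_counts(c(1, 1, -1), c(1, 1, -1))
  expect_equal(unclass(ct)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L), ignore_attr = TRUE)

  yt <- withr::with_seed(2, sample(c(1, -1), 200, replace = TRUE))
  yp <- withr::with_seed(3, sample(c(1, -1), 200, replace = TRUE))
  ct2 <- confusion_counts(yt, yp)
  loop <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    cell <- if (yt[i] == 1 && yp[i] == 1) "TP" else
      if (yt[i] == -1 && yp[i] == 1) "FP" else
        if (yt[i] == -1 && yp[i] == -1) "TN" else "FN"
    loop[cell] <- loop[cell] + 1
  }
  expect_equal(unlist(unclass(ct2)), loop[c("TP", "FP", "TN", "FN")])

  # flipping all predictions swaps TP<->FN and TN<->FP
  ct3 <- confusion_counts(yt, -yp)
  expect_equal(ct3$TP, ct2$FN); expect_equal(ct3$FN, ct2$TP)
  expect_equal(ct3$TN, ct2$FP); expect_equal(ct3$FP, ct2$TN)

  expect_error(confusion_counts(c(1, -1), c(1)), "equal length")
  expect_error(confusion_counts(c(1, 0), c(1, 1)), "\\+1 or -1")
})

test_that("metrics follow the printed formulas including the worked case", {
  # chance-level symmetric counts
  ch <- compute_metrics(structure(list(TP = 25, FP = 25, TN = 25, FN = 25),
                                  class = "confusion_counts"))
  expect_equal(ch$Ac, 0.5); expect_equal(ch$MCC, 0)

  # perfect counts
  pf <- compute_metrics(structure(list(TP = 10, FP = 0, TN = 30, FN = 0),
                                  class = "confusion_counts"))
  expect_equal(unlist(pf[c("Ac", "Sn", "Sp", "Pe", "MCC")]),
               c(Ac = 1, Sn = 1, Sp = 1, Pe = 1, MCC = 1))

  # direct arithmetic case: TP=8, FN=2, TN=85, FP=5
  r <- compute_metrics(structure(list(TP = 8, FP = 5, TN = 85, FN = 2),
                                 class = "confusion_counts"))
  expect_equal(r$Ac, 0.93)
  expect_equal(r$Sn, 0.8)
  expect_equal(r$Sp, 85 / 90, tolerance = 1e-12)
  expect_equal(r$Pe, 8 / 13, tolerance = 1e-12)
  expect_equal(r$MCC, (8 * 85 - 5 * 2) / sqrt(10 * 90 * 13 * 87),
               tolerance = 1e-12)
  expect_equal(round(r$MCC, 4), 0.6641)

  # zero denominators report 0 with a flag
  z <- compute_metrics(structure(list(TP = 0, FP = 0, TN = 10, FN = 0),
                                 class = "confusion_counts"))
  expect_equal(z$Sn, 0); expect_equal(z$Pe, 0)
  expect_true(all(c("Sn", "Pe", "MCC") %in% z$zero_denominator))
})

test_that("metric computation is invariant to sample order", {
  yt <- withr::with_seed(5, sample(c(1, -1), 60, replace = TRUE))
  yp <- withr::with_seed(6, sample(c(1, -1), 60, replace = TRUE))
  perm <- withr::with_seed(7, sample(60))
  a <- compute_metrics(confusion_counts(yt, yp))
  b <- compute_metrics(confusion_counts(yt[perm], yp[perm]))
  expect_equal(a[c("Ac", "Sn", "Sp", "Pe", "MCC")],
               b[c("Ac", "Sn", "Sp", "Pe", "MCC")])
})

test_that("AUC equals the pairwise Mann-Whitney oracle", {
  # perfect separation
  expect_equal(roc_auc(c(-1, -1, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  # all-tied scores
  expect_equal(roc_auc(c(-1, 1, -1, 1), rep(0.5, 4))$auc, 0.5)

  withr::with_seed(8, {
    y <- rep(c(1, -1), each = 250)
    s <- rnorm(500) + (y == 1) * 0.7
    expect_equal(roc_auc(y, s)$auc, pairwise_auc(y, s), tolerance = 1e-12)
    # with heavy ties
    s2 <- round(s)
    expect_equal(roc_auc(y, s2)$auc, pairwise_auc(y, s2), tolerance = 1e-12)
  })
  # invariance under strictly increasing transforms
  y <- rep(c(1, -1), each = 50)
  s <- withr::with_seed(9, rnorm(100) + (y == 1))
  expect_equal(roc_auc(y, s)$auc, roc_auc(y, exp(s))$auc, tolerance = 1e-12)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("ROC points trace a valid curve", {
  y <- rep(c(1, -1), each = 30)
  s <- withr::with_seed(10, rnorm(60) + (y == 1))
  r <- roc_auc(y, s)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_equal(range(r$points$fpr), c(0, 1))
  expect_equal(range(r$points$tpr), c(0, 1))
})

test_that("holdout split honours the 1/6 fraction with stratification", {
  fm <- feature_matrix(withr::with_seed(11, matrix(rnorm(120 * 4), 120, 4)),
                       sprintf("s%03d", 1:120),
                       y = c(rep(1, 24), rep(-1, 96)), stage = "lag")
  sp <- holdout_split(fm, 1 / 6, seed = 4)
  expect_equal(nrow(sp$test$X), 20L)
  expect_equal(nrow(sp$train$X), 100L)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0L)
  expect_setequal(c(sp$train$ids, sp$test$ids), fm$ids)
  # class ratio in test within one sample of the global ratio
  expect_equal(sum(sp$test$y == 1), 4L)

  sp2 <- holdout_split(fm, 1 / 6, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- holdout_split(fm, 1 / 6, seed = 5)
  expect_false(identical(sp$test_idx, sp3$test_idx))
  expect_error(holdout_split(fm, 1e-9), "empty")
})

test_that("fold assignment partitions samples and respects class balance", {
  y <- c(rep(1, 23), rep(-1, 77))
  f <- make_folds(y, 5, seed = 3)
  expect_length(f, 100L)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_gte(sum(y[f == k] == 1), 4L)  # 23 positives over 5 folds
  }
  expect_identical(f, make_folds(y, 5, seed = 3))
  expect_error(make_folds(c(rep(1, 3), rep(-1, 50)), 5), "fewer members")
})

test_that("cross-validation aggregates match recomputation and determinism holds", {
  spec <- synthetic_spec(n_pos = 15L, n_neg = 60L, seed = 13)
  d <- generate_dataset(spec)
  fm <- lag_feature_matrix(d$pssms, d$labels)
  cfg <- welm_config(L_hidden = 200L, seed = 17)
  rep1 <- five_fold_cv(fm, cfg, pca_dim = 50, seed = 19)

  # every sample tested exactly once
  expect_length(rep1$fold_assignments, 75L)
  expect_setequal(unique(rep1$fold_assignments), 1:5)
  expect_false(anyNA(rep1$scores))

  # mean/sd recomputable from per-fold reports (population sd)
  acs <- vapply(rep1$per_fold, function(r) r$Ac, numeric(1))
  srow <- rep1$summary[rep1$summary$metric == "Ac", ]
  expect_equal(srow$mean, mean(acs))
  expect_equal(srow$sd, sqrt(mean((acs - mean(acs))^2)))

  rep2 <- five_fold_cv(fm, cfg, pca_dim = 50, seed = 19)
  expect_equal(rep1$summary, rep2$summary)
  expect_identical(rep1$scores, rep2$scores)

  # strongly separable generator -> high accuracy
  expect_gt(srow$mean, 0.95)
})
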