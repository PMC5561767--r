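#' Confusion-matrix counts
#'
#' Positive class is `+1` (SIP). `TP`/`FN` count true positives predicted
#' `+1`/`-1`; `TN`/`FP` count true negatives predicted `-1`/`+1`.
#'
#' @param y_true,y_pred Equal-length label vectors in `{+1, -1}`.
#' @return Object of class `"confusion_counts"` with integer fields `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop("labels must be +1 or -1")
  }
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == -1 & y_pred == 1),
    TN = sum(y_true == -1 & y_pred == -1),
    FN = sum(y_true == 1 & y_pred == -1)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as 0 and its name listed
#' in the `zero_denominator` field. `AUC` is `NA` here and filled by callers
#' that have scores (see [roc_auc()]).
#'
#' @param counts A [confusion_counts()] object.
#' @return Object of class `"metrics_report"`: `Ac`, `Sn`, `Sp`, `Pe`,
#'   `MCC`, `AUC`, `counts`, `zero_denominator`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (min(TP, FP, TN, FN) < 0) stop("negative counts")
  total <- TP + FP + TN + FN
  if (total == 0) stop("no samples")
  flags <- character()
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  Ac <- (TP + TN) / total
  Sn <- safe(TP, TP + FN, "Sn")
  Sp <- safe(TN, TN + FP, "Sp")
  Pe <- safe(TP, TP + FP, "Pe")
  mcc_den <- sqrt(prod(c(TP + FN, TN + FP, TP + FP, TN + FN)))
  MCC <- if (mcc_den == 0) { flags <- c(flags, "MCC"); 0 } else {
    (TP * TN - FP * FN) / mcc_den
  }
  structure(list(Ac = Ac, Sn = Sn, Sp = Sp, Pe = Pe, MCC = MCC, AUC = NA_real_,
                 counts = counts, zero_denominator = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Ac %.*f  Sn %.*f  Sp %.*f  Pe %.*f  MCC %.*f  AUC %s\n",
              digits, x$Ac, digits, x$Sn, digits, x$Sp, digits, x$Pe,
              digits, x$MCC,
              if (is.na(x$AUC)) "NA" else sprintf("%.*f", digits, x$AUC)))
  if (length(x$zero_denominator)) {
    cat("zero-denominator metrics reported as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC of decision scores
#'
#' Threshold sweep over the unique scores with trapezoidal AUC (equivalent
#' to the Mann-Whitney U statistic, ties counting one half). Computed with
#' \pkg{pROC}.
#'
#' @param y_true Labels in `{+1, -1}`; both classes must be present.
#' @param scores Real decision scores (higher = more positive).
#' @return List with `points` (data frame of `fpr`, `tpr` ordered by
#'   increasing `fpr`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("lengths differ")
  if (!all(y_true %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(y_true)) < 2L) {
    stop("ROC requires both classes present")
  }
  r <- pROC::roc(response = factor(y_true, levels = c(-1, 1)),
                 predictor = as.numeric(scores),
                 levels = c("-1", "1"), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(r$auc))
}

#' Stratified holdout split
#'
#' Reserves `round(fraction * n)` samples as the test set (1/6 in the
#' reference protocol), stratified by class under a seeded shuffle so the
#' test class ratio stays within one sample of the global ratio per class.
#'
#' @param fm A [feature_matrix()] with labels.
#' @param fraction Test fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List with `train` and `test` [feature_matrix()]s and the
#'   `test_idx` used.
#' @export
holdout_split <- function(fm, fraction = 1 / 6, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$y)) stop("holdout_split requires labels")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(fm$X)
  n_test <- round(fraction * n)
  if (n_test == 0 || n_test == n) {
    stop("fraction ", fraction, " yields an empty split side for n = ", n)
  }
  test_idx <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      idx <- integer(0)
      for (cl in c(1, -1)) {
        members <- which(fm$y == cl)
        k <- round(fraction * length(members))
        idx <- c(idx, sample(members, k))
      }
      # stratified rounding can drift by one from round(fraction * n)
      sort(idx)
    } else {
      sort(sample(n, n_test))
    }
  })
  subset_fm <- function(i) feature_matrix(fm$X[i, , drop = FALSE],
                                          fm$ids[i], fm$y[i], stage = fm$stage)
  list(train = subset_fm(setdiff(seq_len(n), test_idx)),
       test = subset_fm(test_idx), test_idx = test_idx)
}

#' Stratified fold assignment
#'
#' @param y Labels in `{+1, -1}`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(y, k = 5L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (k < 2L) stop("need at least 2 folds")
  withr::with_seed(as.integer(seed), {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        members <- which(y == cl)
        if (length(members) < k) {
          stop("class ", cl, " has fewer members (", length(members),
               ") than folds (", k, ")")
        }
        folds[sample(members)] <- rep_len(seq_len(k), length(members))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

#' Five-fold cross-validation of the WELM pipeline
#'
#' Stratified k-fold CV of the full classification stage: per fold, a PCA
#' model is (optionally) fitted on the training folds only and applied to
#' both sides (`pca_scope = "train"`, the leakage-free default; `"all"`
#' fits once on the full data beforehand), a WELM is trained and the held
#' fold evaluated. The fold-level confusion metrics are aggregated as mean
#' and population standard deviation.
#'
#' @param fm A [feature_matrix()] with labels (stage `"lag"`).
#' @param cfg A [welm_config()]; the model seed is offset by the fold index
#'   so folds draw distinct hidden layers reproducibly.
#' @param pca_dim PCA output dimension, or `NULL` to skip PCA.
#' @param seed Seed for the fold assignment.
#' @param folds Number of folds (default 5).
#' @param pca_scope `"train"` or `"all"`.
#' @param stratified Stratify folds by class.
#' @return Object of class `"cv_report"`: `per_fold` (list of
#'   [compute_metrics()] reports with AUC filled), `summary` (data frame of
#'   mean/sd per metric), `fold_assignments`, `seed`, `scores`
#'   (out-of-fold scores aligned with `fm`).
#' @export
five_fold_cv <- function(fm, cfg = welm_default_config(), pca_dim = 300L,
                         seed = 1L, folds = 5L, pca_scope = c("train", "all"),
                         stratified = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  pca_scope <- match.arg(pca_scope)
  if (is.null(fm$y)) stop("cross-validation requires labels")
  assign <- make_folds(fm$y, folds, seed, stratified)
  if (pca_scope == "all" && !is.null(pca_dim)) {
    fm <- pca_apply(pca_fit(fm, pca_dim), fm)
  }
  oof_scores <- rep(NA_real_, nrow(fm$X))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    Xtr <- fm$X[tr, , drop = FALSE]; Xte <- fm$X[te, , drop = FALSE]
    if (pca_scope == "train" && !is.null(pca_dim)) {
      pm <- suppressWarnings(pca_fit(Xtr, pca_dim))
      Xtr <- pca_apply(pm, Xtr); Xte <- pca_apply(pm, Xte)
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- welm_train(Xtr, fm$y[tr], fold_cfg)
    sc <- welm_score(model, Xte)
    oof_scores[te] <- sc
    pred <- ifelse(sc >= 0, 1, -1)
    rep_f <- compute_metrics(confusion_counts(fm$y[te], pred))
    rep_f$AUC <- if (length(unique(fm$y[te])) == 2L) {
      roc_auc(fm$y[te], sc)$auc
    } else NA_real_
    per_fold[[f]] <- rep_f
  }
  metrics <- c("Ac", "Sn", "Sp", "Pe", "MCC", "AUC")
  tab <- sapply(per_fold, function(r) unlist(r[metrics]))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  summary_df <- data.frame(
    metric = metrics,
    mean = apply(tab, 1L, mean),
    sd = apply(tab, 1L, pop_sd),
    row.names = NULL
  )
  structure(list(per_fold = per_fold, summary = summary_df,
                 fold_assignments = assign, seed = as.integer(seed),
                 scores = oof_scores),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n",
              length(x$per_fold), x$seed))
  df <- x$summary
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-3s %.4f +/- %.4f\n", df$metric[i], df$mean[i], df$sd[i]))
  }
  invisible(x)
}

#' Write a CV report as CSV (per-fold rows plus an aggregate row)
#'
#' @param report A [five_fold_cv()] report.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  metrics <- c("Ac", "Sn", "Sp", "Pe", "MCC", "AUC")
  rows <- lapply(seq_along(report$per_fold), function(f) {
    r <- report$per_fold[[f]]
    c(fold = as.character(f), unlist(r[metrics]))
  })
  agg <- c(fold = "mean", stats::setNames(report$summary$mean, metrics))
  sds <- c(fold = "sd", stats::setNames(report$summary$sd, metrics))
  df <- as.data.frame(do.call(rbind, c(rows, list(agg, sds))),
                      stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
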