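#' Grid search over WELM hyper-parameters
#'
#' Evaluates every combination of the supplied hyper-parameter values by
#' internal stratified cross-validation on the training data only and
#' returns the configuration maximizing the chosen metric. Ties keep the
#' first combination in grid order (the order of `expand.grid` over the
#' supplied lists).
#'
#' @param X `n x d` matrix or labelled [feature_matrix()].
#' @param y Labels in `{+1, -1}` (taken from `X$y` when omitted).
#' @param grid Named list with any of `C`, `L_hidden`, `activation`,
#'   `scheme`; unsupplied entries use the defaults of [welm_config()].
#' @param folds Internal CV folds (default 5, minimum 2).
#' @param metric One of `"Ac"`, `"Sn"`, `"Sp"`, `"Pe"`, `"MCC"`, `"AUC"`,
#'   `"gmean"` (geometric mean of Sn and Sp).
#' @param seed Seed driving fold assignment and hidden layers.
#' @return List with `best` (a [welm_config()]), `table` (data frame of all
#'   combinations with their mean CV metric), `metric`.
#' @export
grid_search <- function(X, y = NULL, grid = list(C = c(1, 100)),
                        folds = 5L, metric = "Ac", seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(y)) stop("labels y are required")
  allowed <- c("Ac", "Sn", "Sp", "Pe", "MCC", "AUC", "gmean")
  if (!metric %in% allowed) {
    stop("unknown metric '", metric, "'; supported: ",
         paste(allowed, collapse = ", "))
  }
  if (folds < 2L) stop("need at least 2 folds")
  if (length(grid) == 0L || is.null(names(grid))) {
    stop("grid must be a non-empty named list")
  }
  bad <- setdiff(names(grid), c("C", "L_hidden", "activation", "scheme"))
  if (length(bad)) stop("unknown grid dimension(s): ", paste(bad, collapse = ", "))
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  assign <- make_folds(y, folds, seed)
  eval_cfg <- function(cfg) {
    vals <- vapply(seq_len(folds), function(f) {
      tr <- which(assign != f); te <- which(assign == f)
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + f
      m <- welm_train(X[tr, , drop = FALSE], y[tr], fold_cfg)
      sc <- welm_score(m, X[te, , drop = FALSE])
      r <- compute_metrics(confusion_counts(y[te], ifelse(sc >= 0, 1, -1)))
      switch(metric,
             AUC = if (length(unique(y[te])) == 2L) roc_auc(y[te], sc)$auc else NA_real_,
             gmean = sqrt(r$Sn * r$Sp),
             r[[metric]])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  scores <- numeric(nrow(combos))
  cfgs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    args <- as.list(combos[i, , drop = FALSE])
    cfg <- welm_config(
      activation = args$activation %||% "tribas",
      L_hidden = args$L_hidden %||% 100L,
      C = args$C %||% 100,
      scheme = args$scheme %||% "W1",
      seed = seed
    )
    cfgs[[i]] <- cfg
    scores[i] <- eval_cfg(cfg)
  }
  best_i <- which.max(scores)  # ties -> first in grid order
  tab <- cbind(combos, score = scores)
  names(tab)[ncol(tab)] <- metric
  list(best = cfgs[[best_i]], table = tab, metric = metric)
}
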