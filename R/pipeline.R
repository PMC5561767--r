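#' Read a two-column id/label table
#'
#' @param path CSV with columns `id` and `label` (+1 SIP / -1 non-SIP).
#' @return Data frame with `id` (character) and `label` (numeric).
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("labels CSV must have columns 'id' and 'label': ", path)
  }
  if (!all(df$label %in% c(-1, 1))) stop("labels must be +1 or -1")
  df$id <- as.character(df$id)
  df
}

#' Simulate a synthetic SIP fixture tree
#'
#' Generates a labelled synthetic PSSM dataset ([generate_dataset()]) and
#' writes it as an on-disk tree of ASCII PSSMs, FASTA, labels CSV and a
#' manifest recording the spec and seed ([write_fixture_tree()]).
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated dataset.
#' @export
cmd_simulate <- function(spec, out_dir) {
  dataset <- generate_dataset(spec)
  write_fixture_tree(dataset, out_dir)
  message("simulated ", length(dataset$ids), " PSSMs (",
          spec$n_pos, " pos / ", spec$n_neg, " neg) into ", out_dir)
  invisible(dataset)
}

#' Extract LAG features from a directory of ASCII PSSM files
#'
#' Parses every `*.pssm` file under `pssm_dir`, applies [lag_transform()],
#' and writes one CSV row per parseable file. Unparseable files are skipped
#' with a logged reason; the command fails if no file parses.
#'
#' @param pssm_dir Directory of `.pssm` files.
#' @param out_csv Output feature CSV (`id`, `f0001..f0400`).
#' @param labels_csv Optional labels CSV to join (adds a `label` column).
#' @return Invisibly, the [feature_matrix()] written.
#' @export
cmd_features <- function(pssm_dir, out_csv, labels_csv = NULL) {
  files <- list.files(pssm_dir, pattern = "\\.pssm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .pssm files found in ", pssm_dir)
  pssms <- list(); skipped <- character()
  for (f in files) {
    p <- tryCatch(parse_ascii_pssm(f), error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(p)) skipped <- c(skipped, basename(f))
    else pssms[[length(pssms) + 1L]] <- p
  }
  if (length(pssms) == 0L) stop("no parseable PSSM files in ", pssm_dir)
  y <- NULL
  if (!is.null(labels_csv)) {
    labs <- read_labels_csv(labels_csv)
    ids <- vapply(pssms, function(p) p$protein_id, character(1))
    miss <- setdiff(ids, labs$id)
    if (length(miss)) {
      stop("missing label for id(s): ", paste(miss, collapse = ", "))
    }
    y <- labs$label[match(ids, labs$id)]
  }
  fm <- lag_feature_matrix(pssms, y)
  write_feature_csv(fm, out_csv)
  message("wrote ", length(pssms), " feature rows to ", out_csv,
          if (length(skipped)) paste0(" (skipped ", length(skipped), ")") else "")
  invisible(fm)
}

join_features_labels <- function(features_csv, labels_csv) {
  fm <- read_feature_csv(features_csv)
  labs <- read_labels_csv(labels_csv)
  orphans <- setdiff(fm$ids, labs$id)
  if (length(orphans)) {
    stop("missing label for id(s): ", paste(orphans, collapse = ", "))
  }
  feature_matrix(fm$X, fm$ids, labs$label[match(fm$ids, labs$id)],
                 stage = fm$stage)
}

#' Run cross-validation and write the report files
#'
#' Joins features with labels (erroring on ids without a label), runs
#' [five_fold_cv()], and writes `cv_report.csv` (per-fold + aggregate rows),
#' `roc_points.csv` (out-of-fold ROC curve) and `config.yaml` (resolved
#' configuration) into `out_dir`. Deterministic given the seeds in `cfg`
#' and `seed`.
#'
#' @param features_csv Feature CSV from [cmd_features()].
#' @param labels_csv Labels CSV.
#' @param out_dir Output directory.
#' @param cfg A [welm_config()].
#' @param pca_dim PCA dimension or NULL.
#' @param seed Fold-assignment seed.
#' @param folds Number of folds.
#' @return Invisibly, the [five_fold_cv()] report.
#' @export
cmd_cv <- function(features_csv, labels_csv, out_dir,
                   cfg = welm_default_config(), pca_dim = 300L, seed = 1L,
                   folds = 5L) {
  fm <- join_features_labels(features_csv, labels_csv)
  report <- five_fold_cv(fm, cfg, pca_dim = pca_dim, seed = seed,
                         folds = folds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cv_report(report, file.path(out_dir, "cv_report.csv"))
  roc <- roc_auc(fm$y, report$scores)
  utils::write.csv(roc$points, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(config = unclass(cfg), pca_dim = pca_dim,
                        seed = seed, folds = folds),
                   file.path(out_dir, "config.yaml"))
  invisible(report)
}

#' Train a model and persist it as a checksummed archive
#'
#' Fits PCA (when `pca_dim` is given) and a WELM on all supplied data, and
#' saves both with the training-time scores so later predictions can be
#' verified bit-for-bit against training.
#'
#' @inheritParams cmd_cv
#' @param archive_dir Output archive directory.
#' @return Invisibly, the archive directory.
#' @export
cmd_train <- function(features_csv, labels_csv, archive_dir,
                      cfg = welm_default_config(), pca_dim = 300L) {
  fm <- join_features_labels(features_csv, labels_csv)
  pca <- NULL
  if (!is.null(pca_dim)) {
    pca <- suppressWarnings(pca_fit(fm, pca_dim))
    fm <- pca_apply(pca, fm)
  }
  model <- welm_train(fm, cfg = cfg)
  scores <- data.frame(id = fm$ids, score = welm_score(model, fm))
  save_model_archive(model, archive_dir, pca = pca,
                     training_scores = scores,
                     stage = if (is.null(pca)) "lag" else "pca")
  message("saved model archive to ", archive_dir)
  invisible(archive_dir)
}

#' Predict SIP labels for new PSSMs from a model archive
#'
#' Verifies the archive checksums, extracts LAG features from `pssm_dir`,
#' applies the archived PCA model when present, and writes
#' `id, score, label` per protein. An empty input directory yields an
#' empty CSV (header only) with a warning.
#'
#' @param archive_dir Archive from [cmd_train()].
#' @param pssm_dir Directory of `.pssm` files to score.
#' @param out_csv Output predictions CSV.
#' @return Invisibly, the predictions data frame.
#' @export
cmd_predict <- function(archive_dir, pssm_dir, out_csv) {
  ar <- load_model_archive(archive_dir)
  files <- list.files(pssm_dir, pattern = "\\.pssm$", full.names = TRUE)
  if (length(files) == 0L) {
    warning("no .pssm files in ", pssm_dir, "; writing empty predictions")
    df <- data.frame(id = character(), score = numeric(), label = numeric())
    utils::write.csv(df, out_csv, row.names = FALSE)
    return(invisible(df))
  }
  pssms <- lapply(files, parse_ascii_pssm)
  fm <- lag_feature_matrix(pssms)
  if (identical(ar$stage, "pca")) {
    if (is.null(ar$pca)) stop("archive stage is 'pca' but holds no PCA model")
    fm <- pca_apply(ar$pca, fm)
  }
  expected_d <- if (!is.null(ar$model$norm)) length(ar$model$norm$lo) else
    ncol(ar$model$hidden$input_weights)
  if (ncol(fm$X) != expected_d) {
    stop("feature stage mismatch: model expects ", expected_d,
         " features (stage '", ar$stage, "'), inputs provide ", ncol(fm$X))
  }
  sc <- welm_score(ar$model, fm)
  df <- data.frame(id = fm$ids, score = sc, label = ifelse(sc >= 0, 1, -1))
  utils::write.csv(df, out_csv, row.names = FALSE)
  invisible(df)
}
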