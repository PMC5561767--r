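#' Save a trained pipeline model as a checksummed archive
#'
#' The archive is a directory holding `model.rds` (WELM model), optionally
#' `pca.rds` (the PCA model applied before classification),
#' `training_scores.csv` (id, score at training time), `config.yaml`
#' (resolved configuration and feature stage) and `MANIFEST` with the md5
#' checksum of every payload file. [load_model_archive()] refuses archives
#' whose checksums do not match.
#'
#' @param model A [welm_train()] model.
#' @param dir Archive directory (created; must not already contain a
#'   MANIFEST).
#' @param pca Optional [pca_fit()] model.
#' @param training_scores Optional data frame `id`, `score`.
#' @param stage Feature stage the model expects (`"lag"` or `"pca"`).
#' @return Invisibly, `dir`.
#' @export
save_model_archive <- function(model, dir, pca = NULL,
                               training_scores = NULL,
                               stage = if (is.null(pca)) "lag" else "pca") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  files <- "model.rds"
  if (!is.null(pca)) {
    saveRDS(pca, file.path(dir, "pca.rds"))
    files <- c(files, "pca.rds")
  }
  if (!is.null(training_scores)) {
    ts <- training_scores
    # full 17-digit precision so scores reproduce bit-for-bit after reload
    num <- vapply(ts, is.numeric, logical(1))
    ts[num] <- lapply(ts[num], function(v) sprintf("%.17g", v))
    utils::write.csv(ts, file.path(dir, "training_scores.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "training_scores.csv")
  }
  meta <- list(format = "sipwelm-model-archive", version = 1L,
               stage = stage,
               config = unclass(model$cfg))
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  files <- c(files, "config.yaml")
  sums <- tools::md5sum(file.path(dir, files))
  writeLines(sprintf("%s  %s", sums, files), file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' Load a checksummed model archive
#'
#' @param dir Archive directory written by [save_model_archive()].
#' @return List with `model`, `pca` (or NULL), `training_scores` (or NULL),
#'   `stage`, `meta`.
#' @export
load_model_archive <- function(dir) {
  manifest <- file.path(dir, "MANIFEST")
  if (!file.exists(manifest)) stop("not a model archive (no MANIFEST): ", dir)
  entries <- strsplit(readLines(manifest), "  ", fixed = TRUE)
  for (e in entries) {
    path <- file.path(dir, e[2])
    if (!file.exists(path)) stop("archive member missing: ", e[2])
    actual <- unname(tools::md5sum(path))
    if (!identical(actual, e[1])) {
      stop("archive integrity check failed for ", e[2],
           ": checksum mismatch (file modified or corrupted)")
    }
  }
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  if (!identical(meta$format, "sipwelm-model-archive")) {
    stop("unrecognized archive format in ", dir)
  }
  pca_path <- file.path(dir, "pca.rds")
  ts_path <- file.path(dir, "training_scores.csv")
  list(
    model = readRDS(file.path(dir, "model.rds")),
    pca = if (file.exists(pca_path)) readRDS(pca_path) else NULL,
    training_scores = if (file.exists(ts_path)) {
      utils::read.csv(ts_path, stringsAsFactors = FALSE)
    } else NULL,
    stage = meta$stage,
    meta = meta
  )
}
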