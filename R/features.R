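#' Partition L positions into 20 contiguous groups
#'
#' Each group covers ~5% of the sequence. Boundaries are
#' `b_g = floor(g * L / 20)` for `g = 0..20`; group g is the half-open
#' 1-based position range `(b_{g-1}, b_g]`. The groups tile `1..L` without
#' overlap and are all non-empty for `L >= 20`.
#'
#' @param L Sequence length, at least 20.
#' @return Object of class `"group_partition"`: list with `length`,
#'   `boundaries` (21 integers) and `groups` (list of 20 index vectors).
#' @export
make_partition <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 20L) {
    stop("sequence too short for 20 groups (L = ", L, ", need >= 20)")
  }
  b <- as.integer(floor((0:20) * L / 20))
  groups <- lapply(1:20, function(g) seq.int(b[g] + 1L, b[g + 1L]))
  structure(list(length = L, boundaries = b, groups = groups),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("Partition of %d positions into 20 groups (sizes %d..%d)\n",
              x$length, min(sizes), max(sizes)))
  invisible(x)
}

#' Local Average Group (LAG) transform of a PSSM
#'
#' Maps an `L x 20` PSSM to a fixed 400-dimensional vector: positions are
#' split into 20 contiguous groups of ~5% of the length each
#' ([make_partition()]), and within each group every residue column is
#' averaged. When 20 divides L the within-group mean equals the
#' `(20/L) * sum` normalization of the defining formula; for other lengths
#' the per-group arithmetic mean is its natural extension. Feature
#' `(g-1)*20 + j` is the group-g mean of column j (columns in the PSSM's
#' `column_order`).
#'
#' @param pssm A [new_pssm()] object with `length >= 20`.
#' @param warn_short Warn when `length < 50` (such short sequences were
#'   excluded from the curated SIP datasets); default `TRUE`.
#' @return Numeric vector of length 400 named `f0001..f0400`, with
#'   attributes `protein_id` and `stage = "lag"`.
#' @export
lag_transform <- function(pssm, warn_short = TRUE) {
  stopifnot(inherits(pssm, "pssm"))
  if (warn_short && pssm$length < 50L) {
    warning("sequence ", pssm$protein_id, " is shorter than 50 residues; ",
            "LAG features from very short sequences are noisy")
  }
  part <- make_partition(pssm$length)
  out <- vapply(part$groups, function(idx) {
    colMeans(pssm$scores[idx, , drop = FALSE])
  }, numeric(20))          # 20 x 20: rows = columns j, cols = groups g
  v <- as.vector(out)      # group-major: (g-1)*20 + j
  names(v) <- sprintf("f%04d", seq_len(400L))
  attr(v, "protein_id") <- pssm$protein_id
  attr(v, "stage") <- "lag"
  v
}

#' Assemble a labelled feature matrix
#'
#' Container aligning feature rows with protein ids and optional +1/-1
#' labels; the unit every classifier and evaluation routine consumes.
#'
#' @param X Numeric matrix, one row per protein.
#' @param ids Character vector of row ids.
#' @param y Optional numeric labels in `{+1, -1}`.
#' @param stage `"lag"` or `"pca"`.
#' @return Object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(X, ids, y = NULL, stage = c("lag", "pca")) {
  stage <- match.arg(stage)
  X <- as.matrix(X)
  if (length(ids) != nrow(X)) stop("ids must match rows of X")
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("y must match rows of X")
    if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
    y <- as.numeric(y)
  }
  rownames(X) <- ids
  structure(list(ids = as.character(ids), X = X, y = y, stage = stage),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d proteins x %d features (stage %s)%s\n",
              nrow(x$X), ncol(x$X), x$stage,
              if (is.null(x$y)) "" else
                sprintf(", labels %d pos / %d neg", sum(x$y == 1), sum(x$y == -1))))
  invisible(x)
}

#' LAG features for a list of PSSMs
#'
#' @param pssms List of [new_pssm()] objects.
#' @param y Optional labels in `{+1, -1}`.
#' @param warn_short Passed to [lag_transform()].
#' @return A [feature_matrix()] with stage `"lag"` (n x 400).
#' @export
lag_feature_matrix <- function(pssms, y = NULL, warn_short = FALSE) {
  X <- t(vapply(pssms, function(p) as.numeric(lag_transform(p, warn_short)),
                numeric(400L)))
  colnames(X) <- sprintf("f%04d", seq_len(400L))
  ids <- vapply(pssms, function(p) p$protein_id, character(1))
  feature_matrix(X, ids, y, stage = "lag")
}

#' Fit a principal component analysis model
#'
#' Classical PCA on centred (not rescaled) features via [stats::prcomp()].
#' Components are ordered by explained variance; each component's sign is
#' fixed so its largest-magnitude loading is positive, making the fit
#' deterministic. `n_components` is clamped, with a warning, to the realized
#' rank (components with `sdev > 1e-8 * sdev[1]`); projections onto
#' numerically-null directions are meaningless and destabilize downstream
#' normalization.
#'
#' @param fm A [feature_matrix()] (or plain matrix) with at least 2 rows.
#' @param n_components Requested output dimensionality. The pipeline default
#'   of 300 (from 400 LAG features) is set by callers.
#' @return Object of class `"pca_model"`: `mean` (d-vector), `components`
#'   (`k x d`, orthonormal rows), `explained_variance` (decreasing),
#'   `n_components` (realized k), `requested` (as asked).
#' @export
pca_fit <- function(fm, n_components) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be positive")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank_real <- sum(p$sdev > 1e-8 * p$sdev[1L])
  k <- min(n_components, rank_real, ncol(X), nrow(X) - 1L)
  if (k < n_components) {
    warning("n_components clamped from ", n_components, " to ", k,
            " (realized rank)")
  }
  comp <- t(p$rotation[, seq_len(k), drop = FALSE])  # k x d
  flip <- apply(comp, 1L, function(r) r[which.max(abs(r))] < 0)
  comp[flip, ] <- -comp[flip, ]
  structure(
    list(mean = p$center, components = comp,
         explained_variance = p$sdev[seq_len(k)]^2,
         n_components = k, requested = n_components),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d -> %d dims, %.1f%% variance retained\n",
              ncol(x$components), x$n_components,
              100 * sum(x$explained_variance) /
                max(sum(x$explained_variance), .Machine$double.eps)))
  invisible(x)
}

#' Project features onto a fitted PCA model
#'
#' Rows are mapped to `(x - mean) %*% t(components)`. Ids and labels are
#' carried through; the stage becomes `"pca"`.
#'
#' @param model A [pca_fit()] model.
#' @param fm A [feature_matrix()] or matrix whose column count matches the
#'   model input dimension.
#' @return A [feature_matrix()] with stage `"pca"` (or a plain matrix when
#'   a matrix was supplied).
#' @export
pca_apply <- function(model, fm) {
  stopifnot(inherits(model, "pca_model"))
  is_fm <- inherits(fm, "feature_matrix")
  X <- if (is_fm) fm$X else as.matrix(fm)
  d <- length(model$mean)
  if (ncol(X) != d) {
    stop("dimension mismatch: model expects ", d, " features, got ", ncol(X))
  }
  Z <- sweep(X, 2L, model$mean) %*% t(model$components)
  colnames(Z) <- sprintf("pc%03d", seq_len(ncol(Z)))
  if (!is_fm) return(Z)
  feature_matrix(Z, fm$ids, fm$y, stage = "pca")
}

#' Invert a PCA projection (reconstruction)
#'
#' @param model A [pca_fit()] model.
#' @param Z Projected matrix (`n x k`).
#' @return Reconstructed matrix in the original feature space.
#' @export
pca_invert <- function(model, Z) {
  Z <- as.matrix(Z)
  sweep(Z %*% model$components, 2L, model$mean, `+`)
}

#' Write / read feature tables as CSV
#'
#' Layout: one row per protein, columns `id`, optional `label`, then the
#' feature columns (`f0001..` for LAG, `pc001..` for PCA scores).
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns a [feature_matrix()].
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = fm$ids, stringsAsFactors = FALSE)
  if (!is.null(fm$y)) df$label <- fm$y
  # 17 significant digits: doubles survive the text round-trip exactly
  vals <- as.data.frame(matrix(sprintf("%.17g", fm$X), nrow(fm$X)))
  names(vals) <- colnames(fm$X)
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param stage Stage to record when reading (`"lag"` or `"pca"`).
#' @export
read_feature_csv <- function(path, stage = "lag") {
  if (!file.exists(path)) stop("feature CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("feature CSV lacks an 'id' column: ", path)
  y <- if ("label" %in% names(df)) df$label else NULL
  keep <- setdiff(names(df), c("id", "label"))
  X <- vapply(df[keep], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, 1L, dimnames = list(NULL, keep))
  feature_matrix(X, df$id, y, stage = stage)
}
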