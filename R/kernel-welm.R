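#' Kernel specification for kernel WELM
#'
#' Supported kernels: `"linear"` (`x . y`), `"rbf"`
#' (`exp(-gamma ||x - y||^2)`), and `"feature_map"` — the explicit random
#' hidden layer used as a finite-dimensional feature map,
#' `K(x, y) = h(x) . h(y)`, which makes the kernel solver and the explicit
#' solver two routes to the same classifier.
#'
#' @param kind `"linear"`, `"rbf"` or `"feature_map"`.
#' @param gamma RBF width (required for `"rbf"`).
#' @param L_hidden,activation,seed Hidden-layer parameters for
#'   `"feature_map"`.
#' @return Object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "feature_map"),
                        gamma = NULL, L_hidden = 100L,
                        activation = "tribas", seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "rbf" && (is.null(gamma) || gamma <= 0)) {
    stop("rbf kernel requires gamma > 0")
  }
  structure(list(kind = kind, gamma = gamma, L_hidden = as.integer(L_hidden),
                 activation = activation, seed = as.integer(seed)),
            class = "kernel_spec")
}

kernel_feature_layer <- function(spec, d) {
  init_hidden_layer(d, spec$L_hidden, spec$activation, spec$seed)
}

#' Kernel matrix between two sample sets
#'
#' @param spec A [kernel_spec()].
#' @param X `n x d` matrix.
#' @param Y `m x d` matrix (defaults to `X`).
#' @return `n x m` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(spec$kind,
    linear = X %*% t(Y),
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
      exp(-spec$gamma * pmax(d2, 0))
    },
    feature_map = {
      hl <- kernel_feature_layer(spec, ncol(X))
      hidden_output(hl, X) %*% t(hidden_output(hl, Y))
    }
  )
}

#' Train a kernel WELM
#'
#' Kernel form of the weighted ELM classifier: with kernel matrix
#' `Omega_ij = K(x_i, x_j)` and weight matrix `W = diag(w)`, the coefficient
#' vector is `alpha = (I/C + W Omega)^{-1} W y` and a new sample scores
#' `[K(x, x_1) ... K(x, x_n)] alpha`. For the linear kernel (or the
#' `feature_map` kernel) this coincides with the explicit right-form
#' solution of [welm_train()].
#'
#' @param X `n x d` matrix or [feature_matrix()].
#' @param y Labels in `{+1, -1}`.
#' @param kernel A [kernel_spec()].
#' @param C Positive regularization constant.
#' @param scheme Weighting scheme (see [compute_class_weights()]).
#' @return Object of class `"kernel_welm_model"`: `train_X`, `kernel`,
#'   `alpha`, `C`, `scheme`.
#' @export
kernel_welm_train <- function(X, y = NULL, kernel = kernel_spec("linear"),
                              C = 100, scheme = "none") {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(y) || length(y) != nrow(X)) stop("labels y must match rows of X")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (C <= 0) stop("C must be positive")
  stopifnot(inherits(kernel, "kernel_spec"))
  Omega <- kernel_matrix(kernel, X)
  ws <- compute_class_weights(y, scheme)
  w <- ws$weights
  n <- nrow(X)
  A <- diag(n) / C + w * Omega   # W Omega
  alpha <- tryCatch(solve(A, w * as.numeric(y)), error = function(e) {
    stop("kernel system is numerically singular (", conditionMessage(e),
         "); a larger C or an rbf kernel may help")
  })
  structure(list(train_X = X, kernel = kernel, alpha = as.numeric(alpha),
                 C = C, scheme = ws),
            class = "kernel_welm_model")
}

#' @export
print.kernel_welm_model <- function(x, ...) {
  cat(sprintf("kernel_welm_model: %s kernel, %d support samples, C = %g, scheme %s\n",
              x$kernel$kind, nrow(x$train_X), x$C, x$scheme$name))
  invisible(x)
}

#' Decision scores / labels of a kernel WELM
#'
#' @param model A [kernel_welm_train()] model.
#' @param X `n x d` matrix or [feature_matrix()].
#' @return `kernel_welm_score`: numeric scores; `kernel_welm_predict`:
#'   labels in `{+1, -1}` (score 0 predicts +1).
#' @export
kernel_welm_score <- function(model, X) {
  stopifnot(inherits(model, "kernel_welm_model"))
  if (inherits(X, "feature_matrix")) X <- X$X
  K <- kernel_matrix(model$kernel, as.matrix(X), model$train_X)
  as.numeric(K %*% model$alpha)
}

#' @rdname kernel_welm_score
#' @export
kernel_welm_predict <- function(model, X) {
  ifelse(kernel_welm_score(model, X) >= 0, 1, -1)
}
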