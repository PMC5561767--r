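#' Hidden-node activation functions
#'
#' Supported activations for the random hidden layer: `tribas` (triangular
#' basis, `max(0, 1 - |z|)`), `sigmoid`, `sin`, `hardlim` (`1` for
#' `z >= 0`, else `0`) and `radbas` (`exp(-z^2)`).
#'
#' @param name Activation name.
#' @param z Numeric vector or matrix of pre-activations.
#' @return Activations with the shape of `z`.
#' @examples
#' activation_apply("tribas", c(-2, -0.5, 0, 1))
#' @export
activation_apply <- function(name, z) {
  f <- switch(name,
    tribas  = function(z) pmax(1 - abs(z), 0),
    sigmoid = function(z) 1 / (1 + exp(-z)),
    sin     = sin,
    hardlim = function(z) (z >= 0) + 0,
    radbas  = function(z) exp(-z^2),
    stop("unknown activation '", name, "'; supported: ",
         paste(welm_activations(), collapse = ", "))
  )
  out <- f(z)
  if (is.matrix(z)) dim(out) <- dim(z)
  out
}

#' @rdname activation_apply
#' @export
welm_activations <- function() c("tribas", "sigmoid", "sin", "hardlim", "radbas")

#' WELM training configuration
#'
#' Bundles the classifier hyper-parameters. `welm_default_config()` is the
#' reference profile used throughout the SIP experiments: `tribas`
#' activation, 5000 hidden neurons, regularization `C = 100`, weighting
#' scheme `W1`.
#'
#' @param activation One of [welm_activations()].
#' @param L_hidden Number of hidden neurons.
#' @param C Positive regularization constant; `I/C` is added to the Gram
#'   diagonal before inversion.
#' @param scheme Class-weighting scheme: `"none"`, `"W1"` (weight
#'   `1/n_class`), `"W2"` (golden-ratio `0.618/n_majority`).
#' @param seed Integer seed for the random hidden layer.
#' @param solver_form `"auto"` picks the right-pseudo-inverse form when
#'   `n <= L_hidden` and the left form otherwise; `"right"`/`"left"` force
#'   one.
#' @param normalize `"minmax"` (default) rescales each input feature to
#'   `[-1, 1]` on the training data and then applies one global scale to
#'   unit mean row norm, keeping pre-activations inside the responsive
#'   range of bounded activations; `"none"` uses raw inputs.
#' @return Object of class `"welm_config"`.
#' @export
welm_config <- function(activation = "tribas", L_hidden = 5000L, C = 100,
                        scheme = c("W1", "W2", "none"), seed = 1L,
                        solver_form = c("auto", "right", "left"),
                        normalize = c("minmax", "none")) {
  scheme <- match.arg(scheme)
  solver_form <- match.arg(solver_form)
  normalize <- match.arg(normalize)
  if (!activation %in% welm_activations()) {
    stop("unknown activation '", activation, "'; supported: ",
         paste(welm_activations(), collapse = ", "))
  }
  if (C <= 0) stop("C must be positive")
  if (L_hidden < 1L) stop("L_hidden must be at least 1")
  structure(list(activation = activation, L_hidden = as.integer(L_hidden),
                 C = C, scheme = scheme, seed = as.integer(seed),
                 solver_form = solver_form, normalize = normalize),
            class = "welm_config")
}

#' @rdname welm_config
#' @export
welm_default_config <- function(seed = 1L) {
  welm_config(activation = "tribas", L_hidden = 5000L, C = 100,
              scheme = "W1", seed = seed)
}

#' Initialise a random hidden layer
#'
#' Input weights are i.i.d. uniform on `[-1, 1]`, biases i.i.d. uniform on
#' `[0, 1]` (the usual ELM convention), drawn from an isolated RNG stream
#' seeded by `seed`: the same seed always reproduces the identical layer
#' and the caller's RNG state is untouched.
#'
#' @param d Input dimension.
#' @param L_hidden Number of hidden neurons.
#' @param activation One of [welm_activations()].
#' @param seed Integer seed.
#' @return Object of class `"hidden_layer"`: `input_weights`
#'   (`L_hidden x d`), `biases`, `activation`, `seed`.
#' @export
init_hidden_layer <- function(d, L_hidden, activation = "tribas", seed = 1L) {
  d <- as.integer(d); L_hidden <- as.integer(L_hidden)
  if (d < 1L || L_hidden < 1L) stop("dimensions must be positive")
  if (!activation %in% welm_activations()) {
    stop("unknown activation '", activation, "'")
  }
  pars <- withr::with_seed(as.integer(seed), {
    list(W = matrix(stats::runif(L_hidden * d, -1, 1), L_hidden, d),
         b = stats::runif(L_hidden))
  })
  structure(list(input_weights = pars$W, biases = pars$b,
                 activation = activation, seed = as.integer(seed)),
            class = "hidden_layer")
}

#' Hidden-layer output matrix
#'
#' Entry `(i, l)` is `activation(w_l . x_i + b_l)`: the feature map
#' `F = [f_1(m_1) ... f_L(m_n)]` of the single-hidden-layer network.
#'
#' @param hidden A [init_hidden_layer()] object.
#' @param X Numeric `n x d` matrix.
#' @return `n x L_hidden` matrix.
#' @export
hidden_output <- function(hidden, X) {
  stopifnot(inherits(hidden, "hidden_layer"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(hidden$input_weights)) {
    stop("dimension mismatch: hidden layer expects ",
         ncol(hidden$input_weights), " inputs, got ", ncol(X))
  }
  Z <- X %*% t(hidden$input_weights) +
    rep(hidden$biases, each = nrow(X))
  activation_apply(hidden$activation, Z)
}

#' Per-sample weights for imbalanced classification
#'
#' `none` gives unit weights (plain ELM). `W1` weights each sample by the
#' reciprocal of its class count, so both classes contribute equally to the
#' weighted least-squares fit. `W2` keeps `1/n_minority` for the minority
#' class but shrinks the majority to `0.618/n_majority` (the golden-ratio
#' variant), pushing the boundary further into the majority class.
#'
#' @param y Labels in `{+1, -1}`.
#' @param scheme `"none"`, `"W1"` or `"W2"`.
#' @return Object of class `"weight_scheme"`: `name` and `weights`
#'   (n non-negative reals, the diagonal of W).
#' @export
compute_class_weights <- function(y, scheme = c("W1", "W2", "none")) {
  scheme <- match.arg(scheme)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  n <- length(y)
  if (scheme == "none") {
    w <- rep(1, n)
  } else {
    counts <- c(`-1` = sum(y == -1), `1` = sum(y == 1))
    if (any(counts == 0L)) {
      stop("scheme ", scheme, " requires both classes present")
    }
    w <- 1 / counts[as.character(y)]
    if (scheme == "W2") {
      majority <- if (counts["1"] >= counts["-1"]) 1 else -1
      w[y == majority] <- 0.618 / counts[as.character(majority)]
    }
    w <- as.numeric(w)
  }
  structure(list(name = scheme, weights = w), class = "weight_scheme")
}

# Fit/apply the min-max + row-norm input normalization stored in a model.
# Near-constant features (range < 1e-8 * largest range) are mapped to 0 so
# that null directions cannot blow up out-of-sample.
normalizer_fit <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  const <- rng < 1e-8 * max(rng, .Machine$double.eps)
  rng[const] <- 1
  Xs <- sweep(sweep(X, 2L, lo), 2L, rng, "/") * 2 - 1
  Xs[, const] <- 0
  rn <- mean(sqrt(rowSums(Xs^2)))
  if (!is.finite(rn) || rn <= 0) rn <- 1
  list(lo = lo, rng = rng, const = const, row_scale = rn)
}

normalizer_apply <- function(norm, X) {
  if (is.null(norm)) return(X)
  Xs <- sweep(sweep(X, 2L, norm$lo), 2L, norm$rng, "/") * 2 - 1
  Xs[, norm$const] <- 0
  Xs / norm$row_scale
}

#' Train a weighted extreme learning machine
#'
#' Builds the random hidden layer, computes the hidden output matrix `H`,
#' and solves the regularized weighted least-squares output weights in
#' closed form. With per-sample weight matrix `W = diag(w)` and targets
#' `p = y`:
#' \itemize{
#'   \item right form (`n <= L_hidden`):
#'     `beta = H' (I/C + W H H')^{-1} W p`
#'   \item left form (`n > L_hidden`):
#'     `beta = (I/C + H' W H)^{-1} H' W p`
#' }
#' The two forms are algebraically identical; `solver_form = "auto"` picks
#' the smaller matrix inversion. With `scheme = "none"` (W = I) both reduce
#' exactly to the unweighted regularized ELM solution.
#'
#' @param X `n x d` matrix or [feature_matrix()].
#' @param y Labels in `{+1, -1}` (taken from `X$y` when omitted and `X` is
#'   a feature_matrix).
#' @param cfg A [welm_config()].
#' @return Object of class `"welm_model"`: `hidden`, `beta`, `C`, `scheme`
#'   ([compute_class_weights()] result), `solver_form` used, `norm`
#'   (input normalizer or NULL), `cfg`.
#' @export
welm_train <- function(X, y = NULL, cfg = welm_default_config()) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(y)) stop("labels y are required")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  stopifnot(inherits(cfg, "welm_config"))

  norm <- NULL
  if (cfg$normalize == "minmax") {
    norm <- normalizer_fit(X)
    X <- normalizer_apply(norm, X)
  }
  hidden <- init_hidden_layer(ncol(X), cfg$L_hidden, cfg$activation, cfg$seed)
  H <- hidden_output(hidden, X)
  ws <- compute_class_weights(y, cfg$scheme)
  w <- ws$weights
  n <- nrow(H); L <- ncol(H)
  form <- cfg$solver_form
  if (form == "auto") form <- if (n <= L) "right" else "left"
  y <- as.numeric(y)
  if (form == "right") {
    # beta = H' (I/C + W H H')^{-1} W y  — n x n system
    A <- diag(n) / cfg$C + (w * H) %*% t(H)   # W H H'
    beta <- crossprod(H, solve(A, w * y))
  } else {
    # beta = (I/C + H' W H)^{-1} H' W y  — L x L system
    HtW <- t(H * w)
    A <- diag(L) / cfg$C + HtW %*% H
    beta <- solve(A, HtW %*% y)
  }
  structure(list(hidden = hidden, beta = as.numeric(beta), C = cfg$C,
                 scheme = ws, solver_form = form, norm = norm, cfg = cfg),
            class = "welm_model")
}

#' @export
print.welm_model <- function(x, ...) {
  cat(sprintf(
    "welm_model: %d hidden '%s' neurons, C = %g, scheme %s (%s form)\n",
    length(x$beta), x$hidden$activation, x$C, x$scheme$name, x$solver_form))
  invisible(x)
}

#' Real-valued decision scores of a WELM model
#'
#' `scores = H(X) beta`; the sign is the predicted class.
#'
#' @param model A [welm_train()] model.
#' @param X `n x d` matrix or [feature_matrix()].
#' @return Numeric vector of n scores.
#' @export
welm_score <- function(model, X) {
  stopifnot(inherits(model, "welm_model"))
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  X <- normalizer_apply(model$norm, X)
  as.numeric(hidden_output(model$hidden, X) %*% model$beta)
}

#' Predicted class labels of a WELM model
#'
#' `+1` when the score is `>= 0` (a score of exactly 0 predicts the
#' positive class), else `-1`.
#'
#' @inheritParams welm_score
#' @return Numeric vector of labels in `{+1, -1}`.
#' @export
welm_predict <- function(model, X) {
  ifelse(welm_score(model, X) >= 0, 1, -1)
}
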