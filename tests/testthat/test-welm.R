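test_that("activation functions match their definitions", {
  expect_equal(activation_apply("tribas", c(0, 1, -1, 2, -0.5, 0.25)),
               c(1, 0, 0, 0, 0.5, 0.75))
  expect_equal(activation_apply("sigmoid", 0), 0.5)
  expect_equal(activation_apply("hardlim", c(-0.1, 0, 2)), c(0, 1, 1))
  expect_equal(activation_apply("radbas", c(0, 1)), c(1, exp(-1)))
  expect_equal(activation_apply("sin", pi / 2), 1)
  expect_error(activation_apply("cube", 1), "supported")
})

test_that("hidden layer is seed-deterministic with the stated ranges", {
  h1 <- init_hidden_layer(12, 40, "tribas", seed = 7)
  h2 <- init_hidden_layer(12, 40, "tribas", seed = 7)
  expect_identical(h1, h2)
  h3 <- init_hidden_layer(12, 40, "tribas", seed = 8)
  expect_false(identical(h1$input_weights, h3$input_weights))

  big <- init_hidden_layer(5, 10000, "tribas", seed = 1)
  expect_true(all(big$input_weights >= -1 & big$input_weights <= 1))
  expect_true(all(big$biases >= 0 & big$biases <= 1))
  # both halves of the ranges are reached
  expect_lt(min(big$input_weights), -0.99)
  expect_gt(max(big$input_weights), 0.99)
})

test_that("hidden_output equals the elementwise loop", {
  h <- init_hidden_layer(4, 6, "sigmoid", seed = 3)
  X <- withr::with_seed(5, matrix(rnorm(8 * 4), 8, 4))
  H <- hidden_output(h, X)
  expect_equal(dim(H), c(8L, 6L))
  loop <- matrix(0, 8, 6)
  for (i in 1:8) for (l in 1:6) {
    loop[i, l] <- 1 / (1 + exp(-(sum(h$input_weights[l, ] * X[i, ]) + h$biases[l])))
  }
  expect_equal(H, loop)

  hz <- init_hidden_layer(4, 6, "tribas", seed = 3)
  hz$input_weights[] <- 0; hz$biases[] <- 0
  expect_true(all(hidden_output(hz, X) == 1))
  expect_error(hidden_output(h, X[, 1:2]), "dimension mismatch")
})

test_that("class weights implement none / W1 / W2", {
  y <- c(rep(1, 10), rep(-1, 10))
  expect_equal(compute_class_weights(y, "none")$weights, rep(1, 20))
  expect_equal(compute_class_weights(y, "W1")$weights, rep(0.1, 20))

  y2 <- c(rep(-1, 9), 1)
  w1 <- compute_class_weights(y2, "W1")$weights
  expect_equal(w1[10] / w1[1], 9)
  w2 <- compute_class_weights(y2, "W2")$weights
  expect_equal(w2[10], 1)            # minority keeps 1/n_minority
  expect_equal(w2[1], 0.618 / 9)     # majority shrunk by the golden ratio
  expect_error(compute_class_weights(rep(1, 5), "W1"), "both classes")
  expect_equal(compute_class_weights(rep(1, 5), "none")$weights, rep(1, 5))
})

test_that("left and right solver forms agree and reduce to unweighted ELM", {
  for (case in list(c(n = 8, L = 6), c(n = 30, L = 60), c(n = 60, L = 25))) {
    g <- gaussian_data(ceiling(case["n"] / 3), floor(2 * case["n"] / 3),
                       d = 5, sep = 1, seed = case["n"] + case["L"])
    for (scheme in c("none", "W1")) {
      cfgR <- welm_config(activation = "sigmoid", L_hidden = case[["L"]],
                          C = 50, scheme = scheme, seed = 2,
                          solver_form = "right", normalize = "none")
      cfgL <- cfgR; cfgL$solver_form <- "left"
      bR <- welm_train(g$X, g$y, cfgR)$beta
      bL <- welm_train(g$X, g$y, cfgL)$beta
      expect_lt(max(abs(bR - bL)), 1e-8)
    }
    # scheme = none equals the hand-computed unweighted closed form
    cfg <- welm_config(activation = "sigmoid", L_hidden = case[["L"]], C = 50,
                       scheme = "none", seed = 2, solver_form = "left",
                       normalize = "none")
    m <- welm_train(g$X, g$y, cfg)
    H <- hidden_output(m$hidden, g$X)
    beta_ref <- solve(diag(ncol(H)) / 50 + crossprod(H), crossprod(H, g$y))
    expect_equal(m$beta, as.numeric(beta_ref), tolerance = 1e-8)
  }
})

test_that("large-C WELM separates well-separated training points", {
  X <- rbind(matrix(5, 3, 2), matrix(-5, 3, 2)) +
    withr::with_seed(1, matrix(rnorm(12, 0, 0.1), 6, 2))
  y <- c(1, 1, 1, -1, -1, -1)
  cfg <- welm_config(activation = "sigmoid", L_hidden = 30, C = 1e6,
                     scheme = "none", seed = 4, normalize = "none")
  m <- welm_train(X, y, cfg)
  expect_equal(welm_predict(m, X), y)
  expect_equal(sign(welm_score(m, X)), y)
})

test_that("scores and predictions are consistent with the tie rule", {
  m <- structure(list(hidden = init_hidden_layer(2, 3, "sigmoid", 1),
                      beta = rep(0, 3), C = 1,
                      scheme = compute_class_weights(c(1, -1), "none"),
                      solver_form = "left", norm = NULL,
                      cfg = welm_config(L_hidden = 3, scheme = "none")),
                 class = "welm_model")
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(welm_score(m, X), rep(0, 5))
  expect_equal(welm_predict(m, X), rep(1, 5))  # tie at 0 -> +1

  g <- gaussian_data(10, 10, 4, 2, seed = 6)
  cfg <- welm_config(activation = "tribas", L_hidden = 25, C = 10,
                     scheme = "W1", seed = 3)
  mm <- welm_train(g$X, g$y, cfg)
  sc <- welm_score(mm, g$X)
  expect_equal(welm_predict(mm, g$X), ifelse(sc >= 0, 1, -1))
})

test_that("regularization limits behave as expected", {
  g <- gaussian_data(6, 6, 3, 4, seed = 12)
  base <- welm_config(activation = "sigmoid", L_hidden = 40, scheme = "none",
                      seed = 9, normalize = "none")
  small <- base; small$C <- 1e-9
  big <- base; big$C <- 1e9
  b_small <- welm_train(g$X, g$y, small)$beta
  b_big <- welm_train(g$X, g$y, big)
  expect_lt(sqrt(sum(b_small^2)), 1e-5)            # C -> 0 shrinks beta to 0
  expect_equal(welm_predict(b_big, g$X), g$y)      # C -> Inf fits the data
  expect_error(welm_config(C = 0), "positive")
})

test_that("W1 weighting lifts minority sensitivity on imbalanced Gaussians", {
  # 10:1 imbalance, 20 seeds; weighted vs unweighted ELM on the same layers
  res <- vapply(1:20, function(s) {
    g <- gaussian_data(40, 400, d = 30, sep = 2.0, seed = 3000 + s)
    te <- gaussian_data(80, 800, d = 30, sep = 2.0, seed = 7000 + s)
    out <- vapply(c("W1", "none"), function(scheme) {
      cfg <- welm_config(activation = "tribas", L_hidden = 200, C = 100,
                         scheme = scheme, seed = s)
      m <- welm_train(g$X, g$y, cfg)
      pred <- welm_predict(m, te$X)
      r <- compute_metrics(confusion_counts(te$y, pred))
      c(sn = r$Sn, gm = sqrt(r$Sn * r$Sp))
    }, c(sn = 0, gm = 0))
    c(snW = out["sn", "W1"], snU = out["sn", "none"],
      gmW = out["gm", "W1"], gmU = out["gm", "none"])
  }, c(snW = 0, snU = 0, gmW = 0, gmU = 0))
  expect_gte(mean(res["snW", ]), mean(res["snU", ]))
  wins <- sum(res["gmW", ] > res["gmU", ])
  p <- stats::binom.test(wins, 20, alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
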