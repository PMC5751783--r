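test_that("forward pass matches hand computations", {
  # zero network: tanh(0) = 0 regardless of input
  zero <- structure(list(
    layers = list(list(W = matrix(0, 2, 2), b = c(0, 0)),
                  list(W = matrix(0, 2, 1), b = 0)),
    act_hidden = "tanh", act_output = "tanh",
    n_hidden = 2L, hidden_layers = 1L), class = "sdar_mlp")
  expect_equal(mlp_forward(zero, c(3, -5)), 0)

  # identity composition: 1 hidden unit, all unit weights, zero bias
  ident <- structure(list(
    layers = list(list(W = matrix(1, 1, 1), b = 0),
                  list(W = matrix(1, 1, 1), b = 0)),
    act_hidden = "identity", act_output = "identity",
    n_hidden = 1L, hidden_layers = 1L), class = "sdar_mlp")
  expect_equal(mlp_forward(ident, matrix(0.3)), 0.3)

  # hand-built 2-unit tanh network on x = (1, -1)
  W1 <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  b1 <- c(0.05, -0.1)
  w2 <- matrix(c(0.7, -0.4), 2, 1)
  b2 <- 0.2
  net <- structure(list(
    layers = list(list(W = W1, b = b1), list(W = w2, b = b2)),
    act_hidden = "tanh", act_output = "tanh",
    n_hidden = 2L, hidden_layers = 1L), class = "sdar_mlp")
  h <- tanh(c(1, -1) %*% W1 + b1)
  hand <- tanh(h %*% w2 + b2)
  expect_equal(mlp_forward(net, c(1, -1), clamp = FALSE), as.numeric(hand),
               tolerance = 1e-12)

  # identity output above 1 is clamped for prediction
  big <- ident
  big$layers[[2]]$W <- matrix(5, 1, 1)
  expect_equal(mlp_forward(big, matrix(0.5)), 1)
  expect_equal(mlp_forward(big, matrix(0.5), clamp = FALSE), 2.5)

  expect_error(mlp_forward(net, c(1, 2, 3)), class = "sdar_contract_error")
})

test_that("analytic gradient of the penalized loss matches hand derivation", {
  # 1-weight linear network: y = w * x, E = (y - t)^2 + lambda * w^2
  # dE/dw = 2 (w x - t) x + 2 lambda w
  w0 <- 0.7; x <- 1.3; t <- 1; lambda <- 0.05
  net <- structure(list(
    layers = list(list(W = matrix(w0, 1, 1), b = 0)),
    act_hidden = "identity", act_output = "identity",
    n_hidden = 1L, hidden_layers = 0L), class = "sdar_mlp")
  g <- sdar3d:::mlp_gradient(net, matrix(x), t, lambda)
  hand <- 2 * (w0 * x - t) * x + 2 * lambda * w0
  expect_equal(as.numeric(g$grads[[1]]$W), hand, tolerance = 1e-10)

  # and a single explicit gradient-descent step lands where it should
  eta <- 0.1
  cfg <- mlp_config(learning_rate = eta, weight_decay = lambda,
                    max_epochs = 1, patience = 5, init_scale = 0)
  # numerical check on a 2-feature tanh net against finite differences
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  y <- c(1, 0, 1, 0)
  net2 <- sdar3d:::mlp_init(2, 3, "tanh", "tanh", 0.3)
  g2 <- sdar3d:::mlp_gradient(net2, X, y, lambda)
  loss_at <- function(net) {
    out <- mlp_forward(net, X, clamp = FALSE)
    sum((out - y)^2) + lambda * sum(vapply(net$layers,
                                           function(L) sum(L$W^2),
                                           numeric(1)))
  }
  eps <- 1e-6
  for (l in 1:2) for (idx in seq_along(net2$layers[[l]]$W)) {
    up <- net2; up$layers[[l]]$W[idx] <- up$layers[[l]]$W[idx] + eps
    dn <- net2; dn$layers[[l]]$W[idx] <- dn$layers[[l]]$W[idx] - eps
    fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(g2$grads[[l]]$W[idx], fd, tolerance = 1e-5)
  }
})

test_that("training reaches accuracy 1 on a linearly separable toy", {
  toy <- separable_toy()
  m <- train_member(toy$X, toy$y, cfg = mlp_config(weight_decay = 1e-4),
                    n_hidden = 3, act_hidden = "tanh", act_output = "tanh",
                    seed = 4)
  pred <- as.integer(mlp_forward(m, toy$X) >= 0.5)
  expect_identical(pred, unname(toy$y))
})

test_that("huge weight decay shrinks weights toward zero", {
  toy <- separable_toy()
  m <- train_member(toy$X, toy$y,
                    cfg = mlp_config(weight_decay = 1e3, max_epochs = 200),
                    n_hidden = 2, act_hidden = "tanh", act_output = "identity",
                    seed = 4)
  w_norm <- sum(vapply(m$layers, function(L) sum(L$W^2), numeric(1)))
  expect_lt(w_norm, 1e-3)
})

test_that("training loss is non-increasing across epochs (lambda = 0)", {
  toy <- separable_toy()
  m <- train_member(toy$X, toy$y,
                    cfg = mlp_config(weight_decay = 0, max_epochs = 100,
                                     patience = 100),
                    n_hidden = 3, act_hidden = "tanh", act_output = "tanh",
                    seed = 9)
  tr <- m$trace[, "train"]
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("ensemble honors member count, holdout size and determinism", {
  rec <- small_recovery()
  ens <- rec$ensemble
  n <- length(ens$features$modeling_ids)
  expect_length(ens$members, 8)
  for (m in ens$members) {
    expect_length(m$holdout_ids, round(0.25 * n))
    expect_length(intersect(m$holdout_ids, m$train_ids), 0)
  }
  # same master seed -> identical partitions and weights
  ens2 <- train_ensemble(rec$features,
                         setNames(rec$synth$manifest$activity,
                                  rec$synth$manifest$id),
                         n_members = 8, cfg = ens$mlp_config,
                         master_seed = ens$master_seed)
  expect_identical(lapply(ens2$members, `[[`, "holdout_ids"),
                   lapply(ens$members, `[[`, "holdout_ids"))
  expect_identical(lapply(ens2$members, `[[`, "layers"),
                   lapply(ens$members, `[[`, "layers"))
})

test_that("holdout draws cover compounds at the binomial rate", {
  set.seed(1)
  y <- setNames(rep(c(0, 1), 20), paste0("c", 1:40))
  hits <- integer(40)
  n_draws <- 200
  for (i in seq_len(n_draws)) {
    hold <- sdar3d:::draw_holdout(y, 10)
    hits[hold] <- hits[hold] + 1L
  }
  # binomial(200, 0.25): 3 sigma ~ 18.4 around 50
  expect_true(all(hits > 50 - 19 & hits < 50 + 19))
})

test_that("median aggregation and the 0.5 tie rule govern predictions", {
  mk_const <- function(v) structure(list(
    layers = list(list(W = matrix(0, 2, 1), b = 0),
                  list(W = matrix(0, 1, 1), b = v)),
    act_hidden = "identity", act_output = "identity",
    n_hidden = 1L, hidden_layers = 1L), class = "sdar_mlp")
  feats <- list(bin_ids = 1:2, modeling_ids = "a",
                X = matrix(0, 1, 2, dimnames = list("a", NULL)),
                center = c(0, 0), scale = c(1, 1), scaling = "zscore")
  base <- structure(list(members = list(mk_const(0.2), mk_const(0.6),
                                        mk_const(0.7)),
                         features = feats, threshold = 0.5),
                    class = "sdar_ensemble")
  X <- matrix(rnorm(2), 1, 2)
  p <- predict(base, X)
  expect_equal(p$score, 0.6)
  expect_identical(p$class, 1L)

  base$members <- list(mk_const(0.4), mk_const(0.6))
  p <- predict(base, X)
  expect_equal(p$score, 0.5)
  expect_identical(p$class, 1L)  # tie favors the TdP-positive class

  base$members <- list(mk_const(1), mk_const(1), mk_const(1))
  p <- predict(base, X)
  expect_equal(p$score, 1)
  expect_identical(p$class, 1L)

  # median lies within the member output range
  set.seed(12)
  outs <- runif(5)
  base$members <- lapply(outs, mk_const)
  p <- predict(base, X)
  expect_gte(p$score, min(outs))
  expect_lte(p$score, max(outs))

  expect_error(predict(base, matrix(0, 1, 5)),
               class = "sdar_contract_error")
})

test_that("evaluation metrics match direct confusion-matrix counts", {
  # perfect predictor on 10 compounds (6 active)
  y <- c(rep(1, 6), rep(0, 4))
  pred <- data.frame(id = paste0("c", 1:10), score = y, class = y)
  s <- sdar3d:::set_metrics(pred, y)
  expect_equal(s$accuracy, 1)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$auc, 1)

  # one active flipped: sensitivity 5/6
  cls <- y; cls[1] <- 0
  pred2 <- data.frame(id = paste0("c", 1:10), score = cls, class = cls)
  s2 <- sdar3d:::set_metrics(pred2, y)
  expect_equal(s2$sensitivity, 5 / 6)
  expect_equal(s2$accuracy, 9 / 10)
  expect_equal(sum(s2$confusion), 10)

  # single-class set: ROC undefined, accuracy still reported
  y1 <- rep(1, 5)
  pred3 <- data.frame(id = paste0("c", 1:5), score = rep(1, 5),
                      class = rep(1L, 5))
  s3 <- sdar3d:::set_metrics(pred3, y1)
  expect_true(is.na(s3$auc))
  expect_equal(s3$accuracy, 1)
})

test_that("AUC of random scores is near one half", {
  set.seed(77)
  y <- rep(c(0, 1), 500)
  pred <- data.frame(id = seq_along(y), score = runif(1000),
                     class = rep(0L, 1000))
  s <- sdar3d:::set_metrics(pred, y)
  expect_gt(s$auc, 0.45)
  expect_lt(s$auc, 0.55)
})

test_that("gain curve captures everything once all compounds are examined", {
  set.seed(5)
  y <- rbinom(30, 1, 0.4)
  g <- gain_curve(runif(30), y, positive = 1L)
  expect_equal(g$fraction_captured[30], 1)
  expect_true(all(diff(g$fraction_captured) >= 0))
  # a perfect ranker captures all actives within the active fraction
  gp <- gain_curve(y + runif(30) * 0.1, y, positive = 1L)
  expect_equal(gp$fraction_captured[sum(y)], 1)
})

test_that("model JSON persistence round-trips predictions exactly", {
  rec <- small_recovery()
  path <- tempfile(fileext = ".json")
  save_model(rec$ensemble, path, config_hash = "abc")
  back <- load_model(path)
  expect_identical(attr(back, "config_hash"), "abc")
  X <- rec$features$X[rec$features$modeling_ids, , drop = FALSE]
  expect_equal(predict(back, X), predict(rec$ensemble, X), tolerance = 1e-12)
})
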