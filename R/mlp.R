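#' Multilayer-perceptron configuration
#'
#' Training hyperparameters for one ensemble member. Each member samples
#' its hidden-unit count from `hidden_range` and its hidden/output
#' activations from `activations`, emulating an automated network search.
#' Training is full-batch gradient descent on the sum-of-squares error
#' \eqn{E = \sum_i (y_i - t_i)^2} plus a weight-decay penalty
#' \eqn{\lambda \sum w^2} (connection weights only, not biases), with
#' early stopping on the member's holdout error.
#'
#' @param hidden_range Integer range `c(lo, hi)` for hidden units per
#'   member (default 3..16).
#' @param activations Candidate activation functions, subset of
#'   `c("identity", "tanh")`; hidden and output activations are sampled
#'   independently.
#' @param learning_rate Initial gradient-descent step size eta
#'   (default 0.1). During training the step is halved (persistently)
#'   whenever a full step would increase the penalized training loss, so
#'   descent is monotone regardless of the conditioning of the feature
#'   matrix.
#' @param weight_decay Decay coefficient lambda (default 0.3). The
#'   feature matrix is far wider than the modeling set is tall, so the
#'   decay term must be strong enough to keep noise-bin weights near zero;
#'   values in 0.1..0.7 behave very similarly on planted-rule data.
#' @param max_epochs Maximum full-batch epochs (default 500).
#' @param patience Early-stopping patience: epochs without holdout-error
#'   improvement before training stops (default 20).
#' @param init_scale Standard deviation of the Gaussian weight
#'   initialization (default 0.1).
#' @param hidden_layers 1 (default) or 2 stacked hidden layers.
#' @return An object of class `sdar_mlp_config`.
#' @export
mlp_config <- function(hidden_range = c(3, 16),
                       activations = c("identity", "tanh"),
                       learning_rate = 0.1, weight_decay = 0.3,
                       max_epochs = 500, patience = 20,
                       init_scale = 0.1, hidden_layers = 1) {
  stopifnot(learning_rate > 0, weight_decay >= 0, hidden_range[1] >= 1,
            all(activations %in% c("identity", "tanh")),
            hidden_layers %in% c(1, 2))
  structure(list(hidden_range = as.integer(hidden_range),
                 activations = activations,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 init_scale = init_scale,
                 hidden_layers = as.integer(hidden_layers)),
            class = "sdar_mlp_config")
}

act_fun <- function(name) switch(name, identity = identity, tanh = tanh)
act_grad <- function(name, z) {
  if (name == "identity") array(1, dim(as.matrix(z))) else 1 - tanh(z)^2
}

mlp_init <- function(n_in, n_hidden, act_hidden, act_output, init_scale,
                     hidden_layers = 1L) {
  layers <- list()
  dims <- c(n_in, rep(n_hidden, hidden_layers), 1L)
  for (l in seq_len(length(dims) - 1L)) {
    layers[[l]] <- list(
      W = matrix(rnorm(dims[l] * dims[l + 1], sd = init_scale),
                 dims[l], dims[l + 1]),
      b = rep(0, dims[l + 1]))
  }
  structure(list(layers = layers, act_hidden = act_hidden,
                 act_output = act_output, n_hidden = n_hidden,
                 hidden_layers = hidden_layers),
            class = "sdar_mlp")
}

#' Forward pass of one MLP member
#'
#' Computes the network output for each row of `x`. The raw output of an
#' identity output unit may exceed `[0, 1]`; set `clamp = TRUE` (the
#' default used for prediction and aggregation) to clamp it.
#'
#' @param member An `sdar_mlp` member.
#' @param x Numeric matrix (rows = compounds) or vector (one compound)
#'   with one column per retained bin.
#' @param clamp Clamp outputs into `[0, 1]`?
#' @return Numeric vector of outputs, one per row of `x`.
#' @export
mlp_forward <- function(member, x, clamp = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(member$layers[[1]]$W)) {
    sdar_error(sprintf("feature dimension mismatch: got %d, member expects %d",
                       ncol(x), nrow(member$layers[[1]]$W)),
               "sdar_contract_error")
  }
  h <- x
  nl <- length(member$layers)
  for (l in seq_len(nl)) {
    z <- sweep(h %*% member$layers[[l]]$W, 2, member$layers[[l]]$b, "+")
    act <- if (l < nl) member$act_hidden else member$act_output
    h <- act_fun(act)(z)
  }
  out <- as.numeric(h)
  if (clamp) clamp01(out) else out
}

# full forward with cached pre-activations, for backprop
mlp_forward_cache <- function(member, X) {
  nl <- length(member$layers)
  zs <- vector("list", nl); hs <- vector("list", nl + 1L)
  hs[[1]] <- X
  for (l in seq_len(nl)) {
    zs[[l]] <- sweep(hs[[l]] %*% member$layers[[l]]$W, 2,
                     member$layers[[l]]$b, "+")
    act <- if (l < nl) member$act_hidden else member$act_output
    hs[[l + 1L]] <- act_fun(act)(zs[[l]])
  }
  list(zs = zs, hs = hs, y = as.numeric(hs[[nl + 1L]]))
}

# gradient of E = sum((y-t)^2) + lambda * sum(W^2) over all weight layers
mlp_gradient <- function(member, X, t, lambda) {
  nl <- length(member$layers)
  fc <- mlp_forward_cache(member, X)
  delta <- matrix(2 * (fc$y - t), ncol = 1) *
    act_grad(member$act_output, fc$zs[[nl]])
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(
      W = crossprod(fc$hs[[l]], delta) + 2 * lambda * member$layers[[l]]$W,
      b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(member$layers[[l]]$W)) *
        act_grad(member$act_hidden, fc$zs[[l - 1L]])
    }
  }
  list(grads = grads, loss = sum((fc$y - t)^2) +
         lambda * sum(vapply(member$layers,
                             function(L) sum(L$W^2), numeric(1))))
}

sse <- function(member, X, t) sum((mlp_forward(member, X, clamp = FALSE) - t)^2)

#' Train one MLP ensemble member
#'
#' Full-batch gradient descent on the penalized sum-of-squares error with
#' backtracking on the step size, and
#' early stopping: the holdout (validation) error is tracked every epoch,
#' the best-so-far weights are kept, and training stops after `patience`
#' epochs without improvement. On numerical divergence the member restarts
#' once with the learning rate divided by 10.
#'
#' @param X_train,y_train Training rows (scaled features) and 0/1 labels.
#' @param X_val,y_val Holdout rows used for early stopping; when `NULL`
#'   the training error is used (no true early stopping signal).
#' @param cfg An [mlp_config()].
#' @param n_hidden,act_hidden,act_output Architecture for this member;
#'   defaults are sampled by [train_ensemble()].
#' @param seed Integer seed for weight initialization.
#' @return An `sdar_mlp` with fields `trace` (per-epoch train/holdout
#'   error), `final_train_error`, `best_val_error`, `epochs_run`.
#' @export
train_member <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                         cfg = mlp_config(),
                         n_hidden = cfg$hidden_range[1],
                         act_hidden = "tanh", act_output = "tanh",
                         seed = 1L) {
  penalized <- function(member) {
    sse(member, X_train, y_train) +
      cfg$weight_decay * sum(vapply(member$layers,
                                    function(L) sum(L$W^2), numeric(1)))
  }
  take_step <- function(member, g, eta) {
    for (l in seq_along(member$layers)) {
      member$layers[[l]]$W <- member$layers[[l]]$W - eta * g$grads[[l]]$W
      member$layers[[l]]$b <- member$layers[[l]]$b - eta * g$grads[[l]]$b
    }
    member
  }
  run <- function(eta) {
    set.seed(seed)
    member <- mlp_init(ncol(X_train), n_hidden, act_hidden, act_output,
                       cfg$init_scale, cfg$hidden_layers)
    best <- member
    best_val <- Inf
    stall <- 0L
    trace <- matrix(NA_real_, nrow = cfg$max_epochs, ncol = 2,
                    dimnames = list(NULL, c("train", "holdout")))
    use_val <- !is.null(X_val) && nrow(X_val) > 0
    epochs <- 0L
    eta0 <- eta
    cur_loss <- penalized(member)
    for (ep in seq_len(cfg$max_epochs)) {
      g <- mlp_gradient(member, X_train, y_train, cfg$weight_decay)
      if (!is.finite(g$loss)) return(NULL)
      # backtracking with recovery: halve the step whenever it would
      # increase the penalized loss (descent is monotone by construction),
      # and let it grow back toward the configured rate after accepted
      # steps, so one badly conditioned epoch does not stall training
      repeat {
        cand <- take_step(member, g, eta)
        cand_loss <- penalized(cand)
        if (is.finite(cand_loss) && cand_loss <= cur_loss + 1e-12) break
        eta <- eta / 2
        if (eta < 1e-12) return(NULL)
      }
      member <- cand
      cur_loss <- cand_loss
      eta <- min(eta * 1.2, eta0)
      tr_err <- sse(member, X_train, y_train)
      # holdout monitored on clamped outputs: the scale classification uses
      val_err <- if (use_val) {
        sum((clamp01(mlp_forward(member, X_val, clamp = FALSE)) - y_val)^2)
      } else tr_err
      if (!is.finite(tr_err) || !is.finite(val_err)) return(NULL)
      trace[ep, ] <- c(tr_err, if (use_val) val_err else NA_real_)
      epochs <- ep
      if (val_err < best_val - 1e-12) {
        best_val <- val_err
        best <- member
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    best$trace <- trace[seq_len(epochs), , drop = FALSE]
    best$best_val_error <- best_val
    best$final_train_error <- sse(best, X_train, y_train)
    best$epochs_run <- epochs
    best$seed <- seed
    best
  }
  member <- run(cfg$learning_rate)
  if (is.null(member)) member <- run(cfg$learning_rate / 10)
  if (is.null(member)) {
    sdar_error("MLP training diverged (non-finite loss) even after learning-rate restart",
               "sdar_training_failure")
  }
  member
}
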