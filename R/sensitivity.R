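#' Mean-substitution sensitivity of one member
#'
#' For each retained bin `b`, the sensitivity ratio is `E_b / E_0`, where
#' `E_0` is the member's sum-of-squares error on its own training rows and
#' `E_b` the error after replacing column `b` with its training-partition
#' mean. A ratio above 1 means the network relies on the variable; a
#' column that already equals its mean everywhere (or that the weights
#' ignore) yields exactly 1.
#'
#' For a single-hidden-layer network the substitution changes the hidden
#' pre-activation by a rank-1 term, so each column is evaluated with an
#' O(n x hidden) update rather than a full forward pass; the result is
#' exact and identical to recomputing from scratch.
#'
#' @param member An `sdar_mlp` trained by [train_member()].
#' @param X_train The member's own (scaled) training rows.
#' @param y_train The member's training labels.
#' @return Numeric vector of sensitivity ratios, one per column, with
#'   attribute `flagged_zero_error` when `E_0` was zero and machine
#'   epsilon was substituted.
#' @export
member_sensitivity <- function(member, X_train, y_train) {
  raw <- mlp_forward(member, X_train, clamp = FALSE)
  e0 <- sum((raw - y_train)^2)
  flagged <- e0 == 0
  if (flagged) e0 <- .Machine$double.eps
  p <- ncol(X_train)
  ratios <- numeric(p)
  if (length(member$layers) == 2) {
    W1 <- member$layers[[1]]$W
    z1 <- sweep(X_train %*% W1, 2, member$layers[[1]]$b, "+")
    w2 <- member$layers[[2]]$W
    b2 <- member$layers[[2]]$b
    fh <- act_fun(member$act_hidden)
    fo <- act_fun(member$act_output)
    mu <- colMeans(X_train)
    for (b in seq_len(p)) {
      delta <- mu[b] - X_train[, b]
      zb <- z1 + tcrossprod(delta, W1[b, ])
      yb <- as.numeric(fo(fh(zb) %*% w2 + b2))
      ratios[b] <- sum((yb - y_train)^2) / e0
    }
  } else {
    mu <- colMeans(X_train)
    for (b in seq_len(p)) {
      Xb <- X_train
      Xb[, b] <- mu[b]
      yb <- mlp_forward(member, Xb, clamp = FALSE)
      ratios[b] <- sum((yb - y_train)^2) / e0
    }
  }
  structure(ratios, flagged_zero_error = flagged)
}

#' Permutation importance of one member
#'
#' Alternative importance offered for comparison with the
#' mean-substitution ratio: `E_b / E_0` where column `b` is randomly
#' permuted over the training rows instead of replaced by its mean.
#'
#' @inheritParams member_sensitivity
#' @param seed Seed for the permutation.
#' @return Numeric vector of ratios, one per column.
#' @export
member_permutation_importance <- function(member, X_train, y_train, seed = 1L) {
  raw <- mlp_forward(member, X_train, clamp = FALSE)
  e0 <- max(sum((raw - y_train)^2), .Machine$double.eps)
  set.seed(seed)
  vapply(seq_len(ncol(X_train)), function(b) {
    Xb <- X_train
    Xb[, b] <- sample(Xb[, b])
    sum((mlp_forward(member, Xb, clamp = FALSE) - y_train)^2) / e0
  }, numeric(1))
}

#' Aggregate sensitivity across the ensemble
#'
#' Averages the per-member mean-substitution ratios (each member evaluated
#' on its own training partition) and ranks bins by descending aggregate
#' sensitivity. The significant set is either the top `top_fraction` of
#' retained bins (default 5%, minimum 3 bins) or every bin whose aggregate
#' ratio reaches `threshold`.
#'
#' @param ensemble An `sdar_ensemble`.
#' @param top_fraction Fraction of retained bins selected as significant.
#' @param min_significant Minimum size of the significant set.
#' @param threshold Optional aggregate-ratio cutoff overriding the top-k
#'   rule.
#' @param method `"mean_substitution"` (default) or `"permutation"`.
#' @return An object of class `sdar_sensitivity`: `table` (data.frame with
#'   `bin_id`, `mean_ratio`, `rank`, `significant`), `member_ratios`
#'   (bins x members matrix), and the selection parameters.
#' @export
aggregate_sensitivity <- function(ensemble, top_fraction = 0.05,
                                  min_significant = 3, threshold = NULL,
                                  method = c("mean_substitution", "permutation")) {
  method <- match.arg(method)
  feats <- ensemble$features
  ids <- feats$modeling_ids
  X <- feats$X[ids, , drop = FALSE]
  y <- ensemble$y[ids]
  p <- ncol(X)
  ratios <- vapply(seq_along(ensemble$members), function(m) {
    mem <- ensemble$members[[m]]
    tr <- match(mem$train_ids, ids)
    Xt <- X[tr, , drop = FALSE]
    yt <- y[tr]
    if (method == "mean_substitution") {
      as.numeric(member_sensitivity(mem, Xt, yt))
    } else {
      member_permutation_importance(mem, Xt, yt, seed = mem$seed %||% m)
    }
  }, numeric(p))
  mean_ratio <- rowMeans(ratios)
  rank_ <- rank(-mean_ratio, ties.method = "first")
  if (is.null(threshold)) {
    k <- min(p, max(min_significant, ceiling(top_fraction * p)))
    significant <- rank_ <= k
  } else {
    significant <- mean_ratio >= threshold
  }
  tab <- data.frame(bin_id = feats$bin_ids, mean_ratio = mean_ratio,
                    rank = as.integer(rank_), significant = significant)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 member_ratios = matrix(ratios, nrow = p,
                                        dimnames = list(as.character(feats$bin_ids), NULL)),
                 top_fraction = top_fraction,
                 min_significant = min_significant,
                 threshold = threshold, method = method),
            class = "sdar_sensitivity")
}

#' @export
print.sdar_sensitivity <- function(x, ...) {
  cat(sprintf("<sdar_sensitivity> %d bins ranked (%s), %d significant\n",
              nrow(x$table), x$method, sum(x$table$significant)))
  print(head(x$table, 5))
  invisible(x)
}
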