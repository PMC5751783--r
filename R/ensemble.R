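#' Train the MLP ensemble
#'
#' Trains `n_members` multilayer perceptrons; each member draws an
#' independent uniform-random holdout of `round(holdout_fraction * n)`
#' modeling compounds (redrawn until both classes appear at least twice in
#' the training partition), samples its hidden-unit count and activation
#' pair from the configuration ranges, and is trained by
#' [train_member()]. All randomness (partitions, architectures, weight
#' initializations) derives reproducibly from `master_seed`.
#'
#' @param features An [build_feature_matrix()] result.
#' @param y Named 0/1 activity vector covering the modeling compounds, or
#'   an `sdar_manifest`.
#' @param n_members Number of members (default 200).
#' @param holdout_fraction Fraction of modeling compounds held out per
#'   member (default 0.25).
#' @param cfg An [mlp_config()].
#' @param master_seed Integer master seed.
#' @return An object of class `sdar_ensemble`.
#' @export
train_ensemble <- function(features, y, n_members = 200,
                           holdout_fraction = 0.25, cfg = mlp_config(),
                           master_seed = 1L) {
  y <- activity_vector(y)
  ids <- features$modeling_ids
  if (!all(ids %in% names(y))) {
    sdar_error("labels missing for some modeling compounds",
               "sdar_validation_error")
  }
  y <- y[ids]
  if (length(unique(y)) < 2) {
    sdar_error("modeling set must contain both classes",
               "sdar_validation_error")
  }
  X <- features$X[ids, , drop = FALSE]
  n <- length(ids)
  n_hold <- round(holdout_fraction * n)
  set.seed(master_seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n_members)
  members <- vector("list", n_members)
  stats <- data.frame(member = seq_len(n_members), n_hidden = NA_integer_,
                      act_hidden = NA_character_, act_output = NA_character_,
                      train_acc = NA_real_, holdout_acc = NA_real_,
                      epochs = NA_integer_)
  for (m in seq_len(n_members)) {
    set.seed(member_seeds[m])
    hold <- draw_holdout(y, n_hold)
    n_hidden <- sample(seq(cfg$hidden_range[1], cfg$hidden_range[2]), 1)
    act_h <- sample(cfg$activations, 1)
    act_o <- sample(cfg$activations, 1)
    init_seed <- sample.int(.Machine$integer.max - 1L, 1)
    train_idx <- setdiff(seq_len(n), hold)
    member <- tryCatch(
      train_member(X[train_idx, , drop = FALSE], y[train_idx],
                   X[hold, , drop = FALSE], y[hold],
                   cfg, n_hidden = n_hidden, act_hidden = act_h,
                   act_output = act_o, seed = init_seed),
      error = function(e) {
        sdar_error(sprintf("member %d: %s", m, conditionMessage(e)),
                   "sdar_training_failure")
      })
    member$train_ids <- ids[train_idx]
    member$holdout_ids <- ids[hold]
    members[[m]] <- member
    pred_tr <- as.integer(mlp_forward(member, X[train_idx, , drop = FALSE]) >= 0.5)
    pred_ho <- as.integer(mlp_forward(member, X[hold, , drop = FALSE]) >= 0.5)
    stats$n_hidden[m] <- n_hidden
    stats$act_hidden[m] <- act_h
    stats$act_output[m] <- act_o
    stats$train_acc[m] <- mean(pred_tr == y[train_idx])
    stats$holdout_acc[m] <- mean(pred_ho == y[hold])
    stats$epochs[m] <- member$epochs_run
  }
  structure(list(members = members, member_stats = stats,
                 features = features, y = y,
                 n_members = n_members, holdout_fraction = holdout_fraction,
                 mlp_config = cfg, master_seed = master_seed,
                 threshold = 0.5),
            class = "sdar_ensemble")
}

# holdout redrawn until the training partition keeps >= 2 of each class
draw_holdout <- function(y, n_hold, max_tries = 1000L) {
  n <- length(y)
  for (i in seq_len(max_tries)) {
    hold <- sort(sample.int(n, n_hold))
    rest <- y[-hold]
    if (sum(rest == 1) >= 2 && sum(rest == 0) >= 2) return(hold)
  }
  sdar_error("could not draw a holdout leaving >= 2 compounds per class",
             "sdar_validation_error")
}

activity_vector <- function(y) {
  if (inherits(y, "sdar_manifest") ||
      (is.data.frame(y) && all(c("id", "activity") %in% names(y)))) {
    return(setNames(as.integer(y$activity), y$id))
  }
  if (is.null(names(y))) {
    sdar_error("activity vector must be named by compound id",
               "sdar_validation_error")
  }
  y
}

#' @export
print.sdar_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sdar_ensemble> %d MLP members, %d modeling compounds, %d retained bins\n  mean member accuracy: train %.1f%%, holdout %.1f%% (seed %d)\n",
    x$n_members, length(x$features$modeling_ids), length(x$features$bin_ids),
    100 * mean(x$member_stats$train_acc),
    100 * mean(x$member_stats$holdout_acc), x$master_seed))
  invisible(x)
}

#' Predict TdP class by ensemble-median score
#'
#' Each member's output is clamped to `[0, 1]`; the compound score is the
#' median over members, and the class is 1 when the score is at or above
#' the 0.5 threshold (ties favor the TdP-positive class, since recall of
#' actives is the metric toxicophore construction depends on).
#'
#' @param object An `sdar_ensemble`.
#' @param newdata Scaled feature matrix (as produced by
#'   [scale_new_fingerprints()] or rows of `features$X`); defaults to the
#'   modeling rows.
#' @param ... Unused.
#' @return `data.frame` with `id`, `score`, `class`.
#' @export
predict.sdar_ensemble <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$features$X[object$features$modeling_ids, , drop = FALSE]
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$features$bin_ids)) {
    sdar_error(sprintf("feature dimension mismatch: got %d columns, ensemble expects %d",
                       ncol(newdata), length(object$features$bin_ids)),
               "sdar_contract_error")
  }
  scores <- member_scores(object, newdata)
  med <- apply(scores, 1, median)
  data.frame(id = rownames(newdata) %||% seq_len(nrow(newdata)),
             score = med,
             class = as.integer(med >= object$threshold),
             row.names = NULL)
}

member_scores <- function(ensemble, X) {
  matrix(vapply(ensemble$members, function(m) mlp_forward(m, X, clamp = TRUE),
                numeric(nrow(X))),
         nrow = nrow(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an ensemble on the modeling and external sets
#'
#' Reports two families of metrics. Per-member metrics average each
#' member's accuracy on its own training and holdout partition (the
#' headline convention of subsampled network ensembles). Ensemble metrics
#' use the median score: confusion matrix, accuracy, sensitivity (recall
#' of TdP-positives), specificity, ROC curve with AUC, and gain curves for
#' both classes. A set containing a single class gets its ROC marked
#' undefined while accuracy is still reported.
#'
#' @param ensemble An `sdar_ensemble`.
#' @param external_X Optional scaled matrix for the external (blind) set.
#' @param external_y Optional named 0/1 labels for the external set.
#' @return An object of class `sdar_evaluation`.
#' @export
evaluate_ensemble <- function(ensemble, external_X = NULL, external_y = NULL) {
  feats <- ensemble$features
  ids <- feats$modeling_ids
  y <- ensemble$y[ids]
  X <- feats$X[ids, , drop = FALSE]
  member_summary <- data.frame(
    mean_train_acc = mean(ensemble$member_stats$train_acc),
    mean_holdout_acc = mean(ensemble$member_stats$holdout_acc))
  sets <- list(training = set_metrics(predict(ensemble, X), y))
  # internal: median over the members that held each compound out (out-of-bag)
  S <- member_scores(ensemble, X)
  held <- vapply(ensemble$members, function(m) ids %in% m$holdout_ids,
                 logical(length(ids)))
  oob <- vapply(seq_along(ids), function(i) {
    if (any(held[i, ])) median(S[i, held[i, ]]) else NA_real_
  }, numeric(1))
  seen <- !is.na(oob)
  if (any(seen)) {
    oob_pred <- data.frame(id = ids[seen], score = oob[seen],
                           class = as.integer(oob[seen] >= ensemble$threshold))
    sets$internal <- set_metrics(oob_pred, y[seen])
  }
  if (!is.null(external_X)) {
    external_y <- activity_vector(external_y)
    ex_ids <- rownames(external_X)
    if (!all(ex_ids %in% names(external_y))) {
      sdar_error("labels missing for some external compounds",
                 "sdar_validation_error")
    }
    sets$external <- set_metrics(predict(ensemble, external_X),
                                 external_y[ex_ids])
  }
  structure(list(member_summary = member_summary, sets = sets),
            class = "sdar_evaluation")
}

set_metrics <- function(pred, y) {
  stopifnot(nrow(pred) == length(y))
  cm <- table(factor(y, levels = c(0, 1)),
              factor(pred$class, levels = c(0, 1)),
              dnn = c("truth", "predicted"))
  acc <- sum(diag(cm)) / sum(cm)
  sens <- if (sum(y == 1) > 0) cm["1", "1"] / sum(y == 1) else NA_real_
  spec <- if (sum(y == 0) > 0) cm["0", "0"] / sum(y == 0) else NA_real_
  roc <- NULL; auc <- NA_real_
  if (length(unique(y)) == 2) {
    roc <- pROC::roc(response = y, predictor = pred$score,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  list(n = length(y), confusion = cm, accuracy = acc,
       sensitivity = sens, specificity = spec,
       roc = roc, auc = auc,
       gain_active = gain_curve(pred$score, y, positive = 1L),
       gain_inactive = gain_curve(pred$score, y, positive = 0L))
}

#' Gain curve for one class
#'
#' Compounds are ranked by score (descending for the active class,
#' ascending for the inactive class); the curve gives the cumulative
#' fraction of that class captured against the fraction of compounds
#' examined.
#'
#' @param scores Numeric scores.
#' @param y 0/1 labels.
#' @param positive Which class the curve targets (1 or 0).
#' @return `data.frame` with `fraction_examined`, `fraction_captured`.
#' @export
gain_curve <- function(scores, y, positive = 1L) {
  ord <- order(scores, decreasing = positive == 1L)
  hits <- as.integer(y[ord] == positive)
  total <- sum(hits)
  data.frame(
    fraction_examined = seq_along(hits) / length(hits),
    fraction_captured = if (total > 0) cumsum(hits) / total else NA_real_)
}

#' @export
print.sdar_evaluation <- function(x, ...) {
  cat(sprintf("<sdar_evaluation> mean member accuracy: train %.1f%%, holdout %.1f%%\n",
              100 * x$member_summary$mean_train_acc,
              100 * x$member_summary$mean_holdout_acc))
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %s (n=%d): ensemble accuracy %.1f%%, sensitivity %s, AUC %s\n",
                nm, s$n, 100 * s$accuracy,
                ifelse(is.na(s$sensitivity), "NA",
                       sprintf("%.1f%%", 100 * s$sensitivity)),
                ifelse(is.na(s$auc), "undefined", sprintf("%.3f", s$auc))))
  }
  invisible(x)
}
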