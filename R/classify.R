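#' Train a random-forest SSM-prone gene classifier
#'
#' Follows the published protocol: a single random 2/3 train, 1/3
#' holdout split; 500 trees with `mtry = floor(sqrt(p))`; stratified
#' downsampling of the majority class to the rarest class's frequency
#' in every bootstrap sample; permutation importance (mean decrease in
#' accuracy) on out-of-bag data. The sign of association reported per
#' feature is the sign of the difference in class-conditional means
#' (positive = higher in the positive class).
#'
#' @param features Tibble with `gene_id` and numeric feature columns
#'   (a `label` column, if present, is ignored as a feature).
#' @param labels Vector (character/factor) with exactly two classes,
#'   aligned with `features` rows.
#' @param seed Integer seed controlling the split and the forest.
#' @param positive Label of the positive (SSM-prone) class
#'   (default `"upper"`).
#' @param ntree Number of trees (default 500).
#' @param holdout Holdout fraction (default 1/3).
#' @return Object of class `"splice_classifier"`: model handle,
#'   `importance` tibble (feature, importance, direction), holdout
#'   `roc` points, `auc`, per-gene holdout `predictions`. Use
#'   [tidy()] / [glance()] to extract tables.
#' @export
train_rf <- function(features, labels, seed = 1L, positive = "upper",
                     ntree = 500, holdout = 1 / 3) {
  prep <- prep_training(features, labels, positive, seed, holdout)
  set.seed(substream_seed(seed, "rf:fit"))
  samp <- rep(min(table(prep$y_train)), 2)
  fit <- randomForest::randomForest(
    x = as.data.frame(prep$x_train), y = prep$y_train,
    ntree = ntree, importance = TRUE,
    strata = prep$y_train, sampsize = samp
  )
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)
  prob <- predict(fit, newdata = as.data.frame(prep$x_test), type = "prob")[, "pos"]
  finish_classifier("rf", fit, prep, prob,
                    tibble(feature = rownames(imp),
                           importance = imp[, 1],
                           direction = prep$direction[rownames(imp)]))
}

#' Train a logistic-regression classifier
#'
#' Additive-logit counterpart of [train_rf()] under the identical
#' split protocol. Importance is the magnitude of the coefficient z
#' statistic; direction is the coefficient sign.
#'
#' @inheritParams train_rf
#' @return A `"splice_classifier"` object.
#' @export
train_lr <- function(features, labels, seed = 1L, positive = "upper",
                     holdout = 1 / 3) {
  prep <- prep_training(features, labels, positive, seed, holdout)
  d <- as.data.frame(prep$x_train)
  d$.y <- as.integer(prep$y_train == "pos")
  fit <- glm(.y ~ ., data = d, family = binomial())
  co <- summary(fit)$coefficients
  co <- co[setdiff(rownames(co), "(Intercept)"), , drop = FALSE]
  prob <- predict(fit, newdata = as.data.frame(prep$x_test), type = "response")
  finish_classifier("lr", fit, prep, prob,
                    tibble(feature = rownames(co),
                           importance = abs(co[, "z value"]),
                           direction = sign(co[, "Estimate"])))
}

prep_training <- function(features, labels, positive, seed, holdout) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) abort("training data contains a single class")
  if (length(classes) > 2) abort("exactly two classes required")
  if (!positive %in% classes) {
    abort(sprintf("positive class '%s' absent from labels", positive))
  }
  x <- select(as_tibble(features), -dplyr::any_of(c("gene_id", "label")))
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  y <- factor(ifelse(labels == positive, "pos", "neg"), levels = c("neg", "pos"))
  set.seed(substream_seed(seed, "split"))
  n <- nrow(x)
  test_idx <- sort(sample.int(n, round(holdout * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  direction <- vapply(x, function(v) {
    sign(mean(v[y == "pos"]) - mean(v[y == "neg"]))
  }, double(1))
  list(
    x_train = x[train_idx, ], y_train = y[train_idx],
    x_test = x[test_idx, ], y_test = y[test_idx],
    gene_id_test = features$gene_id[test_idx] %||% as.character(test_idx),
    feature_names = names(x), positive = positive, direction = direction,
    n_train = length(train_idx), n_test = length(test_idx)
  )
}

finish_classifier <- function(method, fit, prep, prob, importance) {
  roc <- roc_points(prob, prep$y_test == "pos")
  structure(
    list(
      method = method, model = fit,
      feature_names = prep$feature_names, positive = prep$positive,
      importance = arrange(importance, desc(.data$importance)),
      roc = roc, auc = roc_auc(roc),
      predictions = tibble(gene_id = prep$gene_id_test, prob = unname(prob),
                           truth = prep$y_test == "pos"),
      n_train = prep$n_train, n_test = prep$n_test
    ),
    class = "splice_classifier"
  )
}

#' ROC curve points and AUC
#'
#' `roc_points()` sweeps the unique score thresholds (ties share one
#' point, so tied scores receive half credit, matching the
#' rank-statistic AUC). `roc_auc()` integrates by trapezoid;
#' `auc_rank()` computes the equivalent Mann-Whitney rank statistic
#' directly.
#'
#' @param score Numeric classifier scores (higher = more positive).
#' @param truth Logical vector of true positives.
#' @return `roc_points()`: tibble with `threshold`, `fpr`, `tpr`,
#'   monotone non-decreasing; the others a scalar in \[0, 1\].
#' @export
roc_points <- function(score, truth) {
  stopifnot(length(score) == length(truth), any(truth), any(!truth))
  o <- order(score, decreasing = TRUE)
  s <- score[o]; t <- as.logical(truth)[o]
  grp_last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(t)[grp_last]
  fp <- cumsum(!t)[grp_last]
  tibble(
    threshold = c(Inf, s[grp_last]),
    fpr = c(0, fp / sum(!truth)),
    tpr = c(0, tp / sum(truth))
  )
}

#' @rdname roc_points
#' @param roc A tibble from `roc_points()`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' @rdname roc_points
#' @export
auc_rank <- function(score, truth) {
  truth <- as.logical(truth)
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Retrain without one feature
#'
#' Repeats the identical training protocol minus one column and
#' returns the holdout AUC, quantifying that feature's marginal
#' contribution.
#'
#' @inheritParams train_rf
#' @param feature_name Column to drop.
#' @param method `"rf"` or `"lr"`.
#' @return Scalar holdout AUC.
#' @export
drop_feature_retrain <- function(features, labels, feature_name, seed = 1L,
                                 positive = "upper", method = c("rf", "lr")) {
  method <- match.arg(method)
  if (!feature_name %in% names(features)) {
    abort(sprintf("feature '%s' not present", feature_name))
  }
  reduced <- select(features, -all_of(feature_name))
  fit <- if (method == "rf") {
    train_rf(reduced, labels, seed = seed, positive = positive)
  } else {
    train_lr(reduced, labels, seed = seed, positive = positive)
  }
  fit$auc
}

#' Predict SSM-prone genes genome-wide
#'
#' Applies a trained classifier to unlabeled genes and returns every
#' gene's probability together with the thresholded SSM-prone call
#' (probability strictly above `prob_threshold`, default 0.6).
#'
#' @param fit A `"splice_classifier"`.
#' @param features Tibble with `gene_id` and the same feature columns
#'   used in training (extra columns ignored).
#' @param prob_threshold Probability cutoff.
#' @return Tibble: `gene_id`, `prob`, `predicted_prone`.
#' @export
predict_genomewide <- function(fit, features, prob_threshold = 0.6) {
  stopifnot(inherits(fit, "splice_classifier"))
  miss <- setdiff(fit$feature_names, names(features))
  if (length(miss) > 0) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(select(as_tibble(features), all_of(fit$feature_names)))
  prob <- if (fit$method == "rf") {
    predict(fit$model, newdata = x, type = "prob")[, "pos"]
  } else {
    predict(fit$model, newdata = x, type = "response")
  }
  tibble(
    gene_id = features$gene_id %||% as.character(seq_len(nrow(x))),
    prob = unname(prob),
    predicted_prone = unname(prob) > prob_threshold
  )
}

#' @export
print.splice_classifier <- function(x, ...) {
  cat(sprintf("<splice_classifier %s: %d features, holdout AUC %.3f (n=%d/%d)>\n",
              x$method, length(x$feature_names), x$auc, x$n_train, x$n_test))
  cat("top features:", paste(head(x$importance$feature, 5), collapse = ", "), "\n")
  invisible(x)
}
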