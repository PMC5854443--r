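test_that("ROC construction agrees with the rank-statistic AUC", {
  set.seed(2)
  for (i in 1:10) {
    score <- round(rnorm(80), 1)  # rounding forces ties
    truth <- runif(80) < 0.4
    if (!any(truth) || all(truth)) next
    roc <- roc_points(score, truth)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(roc_auc(roc), auc_rank(score, truth), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  score <- round(rnorm(120), 1)
  truth <- runif(120) < 0.35
  ours <- roc_auc(roc_points(score, truth))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("classifiers separate planted signal and not permuted labels", {
  ft <- gen_feature_table(c(rep("upper", 80), rep("expected", 520)),
                          effect_profile = 1.5, seed = 31)
  fit <- train_rf(ft, ft$label, seed = 31)
  expect_gte(fit$auc, 0.95)
  expect_equal(nrow(fit$importance), 19)
  expect_true(all(fit$predictions$prob >= 0 & fit$predictions$prob <= 1))
  # reproducible under the same seed
  fit2 <- train_rf(ft, ft$label, seed = 31)
  expect_identical(fit$auc, fit2$auc)
  expect_identical(fit$importance, fit2$importance)

  set.seed(99)
  perm_auc <- vapply(1:3, function(i) {
    train_rf(ft, sample(ft$label), seed = 100 + i)$auc
  }, double(1))
  expect_true(all(perm_auc > 0.3 & perm_auc < 0.7))
  expect_error(train_rf(ft, rep("upper", nrow(ft)), seed = 1), "single class")
})

test_that("logistic regression handles trivially separable data", {
  n <- 120
  feat <- tibble::tibble(
    gene_id = as.character(1:n),
    flag = rep(c(1, 0), each = n / 2),
    noise = rnorm(n)
  )
  labels <- rep(c("upper", "expected"), each = n / 2)
  fit <- suppressWarnings(train_lr(feat, labels, seed = 3))
  expect_equal(fit$auc, 1.0)
  perm <- suppressWarnings(train_lr(feat, sample(labels), seed = 3))
  expect_lt(abs(perm$auc - 0.5), 0.25)
})

test_that("random forests beat additive logits on interaction-driven signal", {
  set.seed(7)
  n <- 500
  x1 <- sample(c(0, 1), n, TRUE); x2 <- sample(c(0, 1), n, TRUE)
  labels <- ifelse(xor(x1, x2), "upper", "expected")
  feat <- tibble::tibble(gene_id = as.character(1:n),
                         x1 = x1 + rnorm(n, 0, 0.1),
                         x2 = x2 + rnorm(n, 0, 0.1))
  rf <- train_rf(feat, labels, seed = 7)
  lr <- suppressWarnings(train_lr(feat, labels, seed = 7))
  expect_gt(rf$auc, lr$auc)
  expect_gt(rf$auc, 0.9)
})

test_that("dropping features changes AUC according to their information", {
  ft <- gen_feature_table(c(rep("upper", 80), rep("expected", 520)),
                          effect_profile = 1.5, seed = 41)
  full <- train_rf(ft, ft$label, seed = 41)$auc
  # pure-noise column: negligible change
  no_noise <- drop_feature_retrain(ft, ft$label, "gene_snp_density", seed = 41)
  expect_lt(abs(no_noise - full), 0.02)
  # one of several informative columns: still predictive
  no_intron <- drop_feature_retrain(ft, ft$label, "intron_count", seed = 41)
  expect_gt(no_intron, 0.7)
  expect_lte(no_intron, full + 0.02)

  # sole informative column: back to chance
  set.seed(8)
  n <- 400
  labels <- rep(c("upper", "expected"), each = n / 2)
  feat <- tibble::tibble(
    gene_id = as.character(1:n),
    signal = ifelse(labels == "upper", 2, 0) + rnorm(n, 0, 0.5),
    junk1 = rnorm(n), junk2 = rnorm(n)
  )
  expect_gt(train_rf(feat, labels, seed = 8)$auc, 0.95)
  expect_lt(abs(drop_feature_retrain(feat, labels, "signal", seed = 8) - 0.5), 0.15)
  expect_error(drop_feature_retrain(feat, labels, "nope", seed = 8), "not present")
})

test_that("genome-wide prediction respects thresholds and feature contracts", {
  ft <- gen_feature_table(c(rep("upper", 80), rep("expected", 520)), seed = 51)
  fit <- suppressWarnings(train_lr(ft, ft$label, seed = 51))
  fresh <- gen_feature_table(400, seed = 52)
  pred <- predict_genomewide(fit, fresh, prob_threshold = 0.6)
  expect_equal(nrow(pred), 400)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_equal(sum(predict_genomewide(fit, fresh, 1)$predicted_prone), 0)
  expect_equal(sum(predict_genomewide(fit, fresh, 0)$predicted_prone), 400)
  expect_error(predict_genomewide(fit, fresh[, 1:5]), "missing feature")

  # 5% planted prone genes at training effect sizes: both recall and
  # precision clear 0.5 at the published 0.6 cutoff
  rf <- train_rf(ft, ft$label, seed = 51)
  unl <- gen_feature_table(c(rep("upper", 20), rep("expected", 380)), seed = 53)
  p <- predict_genomewide(rf, unl, prob_threshold = 0.6)
  truth <- unl$label == "upper"
  recall <- sum(p$predicted_prone & truth) / sum(truth)
  precision <- sum(p$predicted_prone & truth) / max(1, sum(p$predicted_prone))
  expect_gte(recall, 0.5)
  expect_gte(precision, 0.5)
})

test_that("importance ranking surfaces the planted dominant feature", {
  hits <- vapply(1:5, function(s) {
    ft <- gen_feature_table(c(rep("upper", 60), rep("expected", 340)), seed = s)
    fit <- train_rf(ft, ft$label, seed = s)
    fit$importance$feature[1] == "intron_count"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # direction signs match the planted directions for the signal features
  ft <- gen_feature_table(c(rep("upper", 100), rep("expected", 500)), seed = 60)
  fit <- train_rf(ft, ft$label, seed = 60)
  sig <- feature_signal_directions()
  joined <- dplyr::inner_join(fit$importance, sig, by = "feature")
  strong <- joined[joined$strength > 0, ]
  expect_true(all(strong$direction.x == strong$direction.y))
})
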