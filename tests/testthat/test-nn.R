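test_that("half splits are stratified and deterministic", {
  labels <- make_labels(5, 5)
  sp <- split_half(labels, seed = 1)
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)
  expect_gte(min(table(labels[sp$train])), 2)
  expect_gte(min(table(labels[sp$test])), 2)
  expect_identical(sp, split_half(labels, seed = 1))

  odd <- make_labels(5, 6)
  sp2 <- split_half(odd, seed = 2)
  expect_equal(sort(unname(lengths(sp2))), c(5L, 6L))
  tr_tab <- table(odd[sp2$train])
  expect_equal(unname(tr_tab[["control"]]), 2)
  expect_equal(unname(tr_tab[["case"]]), 3)
})

test_that("training on separable data reaches the linear-oracle accuracy", {
  withr::with_seed(5, {
    n <- 40
    labels <- sample_labels(sprintf("s%02d", 1:n),
                            rep(c("case", "control"), each = n / 2))
    y <- as.numeric(labels == "case")
    feats <- rbind(f1 = y * 4 - 2 + rnorm(n, 0, 0.3),
                   f2 = -y * 3 + 1.5 + rnorm(n, 0, 0.3))
    colnames(feats) <- names(labels)
    # independent linear oracle: logistic regression is perfect here
    oracle <- suppressWarnings(glm(y ~ t(feats), family = binomial))
    expect_equal(mean((fitted(oracle) >= 0.5) == y), 1.0)
    model <- train_nn(feats, labels, nn_config("sigmoid", 10, 0.5,
                                               epochs = 1500, seed = 1))
    expect_equal(model$train_accuracy, 1.0)
    expect_lt(tail(model$loss_history, 1), model$loss_history[1])
  })
})

test_that("training is deterministic and rejects degenerate input", {
  fix <- make_ga_features(n_noise = 2, n_inf = 1, n = 30, seed = 3)
  cfg <- nn_config("tanh", c(6, 3), 0.1, epochs = 200, seed = 9)
  m1 <- train_nn(fix$features, fix$labels, cfg)
  m2 <- train_nn(fix$features, fix$labels, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_error(train_nn(fix$features[0, , drop = FALSE], fix$labels, cfg),
               "no features")
})

test_that("grid search returns the best config, first on ties", {
  fix <- make_ga_features(n_noise = 0, n_inf = 2, n = 40, seed = 6)
  single <- grid_search(fix$features, fix$labels, activations = "relu",
                        hidden_grid = list(5), learning_rates = 0.1,
                        epochs = 100, seed = 1)
  expect_equal(single$activation, "relu")
  expect_equal(single$hidden_sizes, 5L)

  best <- grid_search(fix$features, fix$labels,
                      activations = c("sigmoid", "relu"),
                      hidden_grid = list(4), learning_rates = c(0.05, 0.3),
                      epochs = 400, folds = 4, seed = 2)
  grid <- attr(best, "grid")
  expect_equal(attr(best, "cv_accuracy"), max(grid$cv_accuracy))
  expect_equal(which(grid$cv_accuracy == max(grid$cv_accuracy))[1],
               which(grid$activation == best$activation &
                       grid$learning_rate == best$learning_rate)[1])

  # all-zero features: every config predicts a constant -> tie -> first
  zero <- matrix(0, 2, 40, dimnames = list(c("a", "b"), names(fix$labels)))
  tied <- grid_search(zero, fix$labels, activations = c("sigmoid", "relu"),
                      hidden_grid = list(3), learning_rates = c(0.01, 0.1),
                      epochs = 20, folds = 4, seed = 1)
  expect_equal(tied$activation, "sigmoid")
  expect_equal(tied$learning_rate, 0.01)
})

test_that("ROC handles perfect, reversed, and tied scores", {
  labels <- make_labels(3, 3)
  scores <- setNames(c(0.1, 0.2, 0.3, 0.8, 0.9, 0.7), names(labels))
  roc <- roc_auc(scores, labels)
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(tail(roc$points$tpr, 1), 1)
  expect_equal(roc_auc(setNames(rev(scores), names(labels)), labels)$auc, 0)
  expect_equal(roc_auc(setNames(rep(0.5, 6), names(labels)), labels)$auc, 0.5)
  expect_error(roc_auc(scores[1:3], make_labels(3, 0)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney U normalization", {
  withr::with_seed(8, {
    for (rep in 1:100) {
      n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
      labels <- make_labels(n0, n1)
      scores <- setNames(sample(seq(0, 1, 0.1), n0 + n1, replace = TRUE),
                         names(labels))
      auc <- roc_auc(scores, labels)$auc
      case_s <- scores[labels == "case"]; ctrl_s <- scores[labels == "control"]
      u <- sum(outer(case_s, ctrl_s, ">")) + 0.5 * sum(outer(case_s, ctrl_s, "=="))
      expect_equal(auc, u / (n1 * n0), tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    labels <- make_labels(20, 20)
    scores <- setNames(rnorm(40) + as.numeric(labels == "case"), names(labels))
    mine <- roc_auc(scores, labels)$auc
    ref <- pROC::auc(pROC::roc(as.numeric(labels == "case"), scores,
                               quiet = TRUE, direction = "<"))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-9)
  })
})
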