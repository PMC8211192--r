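#' Neural-network configuration
#'
#' @param activation Hidden-layer activation: `"sigmoid"`, `"relu"` or
#'   `"tanh"`. The default initial setting is a sigmoid network with one
#'   hidden layer of 10 units and learning rate 0.01.
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param learning_rate Positive step size for full-batch gradient descent.
#' @param epochs Number of full-batch epochs (default 2000).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(activation = c("sigmoid", "relu", "tanh"),
                      hidden_sizes = 10, learning_rate = 0.01,
                      epochs = 2000, seed = 1) {
  activation <- match.arg(activation)
  hidden_sizes <- vapply(hidden_sizes, check_count, integer(1),
                         name = "hidden_sizes", min = 1)
  if (!length(hidden_sizes)) stopf("'hidden_sizes' must be non-empty")
  lr <- check_scalar(learning_rate, "learning_rate")
  if (lr <= 0) stopf("'learning_rate' must be > 0")
  structure(list(activation = activation, hidden_sizes = hidden_sizes,
                 learning_rate = lr,
                 epochs = check_count(epochs, "epochs", min = 1),
                 seed = check_count(abs(seed), "seed")),
            class = "nn_config")
}

activation_fns <- list(
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df = function(a) a * (1 - a)),
  relu = list(f = function(x) pmax(x, 0),
              df = function(a) (a > 0) * 1),
  tanh = list(f = tanh,
              df = function(a) 1 - a^2))

#' Stratified random half split
#'
#' Shuffles samples under the seed and splits them in half, preserving
#' class proportions within one sample: each class contributes at least
#' `floor(n_class / 2)` training samples, and remaining slots up to
#' `floor(n / 2)` are filled one per class.
#'
#' @param labels [sample_labels()].
#' @param seed Integer seed.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_half <- function(labels, seed = 1) {
  if (any(table(labels) < 2)) stopf("need >= 2 samples per class")
  take <- table(labels) %/% 2
  short <- length(labels) %/% 2 - sum(take)
  if (short > 0) {
    odd <- names(which(table(labels) %% 2 == 1))
    take[odd[seq_len(short)]] <- take[odd[seq_len(short)]] + 1
  }
  train <- character(0)
  withr::with_seed(seed, {
    for (cls in levels(labels)) {
      ids <- sample(names(labels)[labels == cls])
      train <- c(train, ids[seq_len(take[[cls]])])
    }
  })
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

#' Train a feedforward classifier by full-batch gradient descent
#'
#' Fully-connected network: input (one unit per feature) -> hidden layers
#' with the configured activation -> a single sigmoid output unit, trained
#' on mean binary cross-entropy with full-batch gradient descent. Weights
#' initialize from a seeded uniform distribution scaled by
#' `1/sqrt(fan_in)`, so training is deterministic given the config.
#'
#' @param features Numeric matrix, features x samples.
#' @param labels [sample_labels()] aligned to feature columns.
#' @param config An [nn_config()].
#' @return A list of class `nn_model`: `weights` (list of weight matrices,
#'   last row of each = bias), `config`, `loss_history`,
#'   `train_accuracy`.
#' @export
train_nn <- function(features, labels, config = nn_config()) {
  if (is.null(nrow(features)) || nrow(features) < 1) stopf("no features")
  labels <- labels[colnames(features)]
  if (length(unique(labels)) < 2) stopf("both classes required for training")
  y <- matrix(as.numeric(labels == "case"), ncol = 1)
  X <- t(features)                                  # samples x features
  sizes <- c(ncol(X), config$hidden_sizes, 1L)
  act <- activation_fns[[config$activation]]
  L <- length(sizes) - 1

  weights <- withr::with_seed(config$seed, lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]
    matrix(stats::runif((fan_in + 1) * sizes[l + 1], -1, 1) / sqrt(fan_in),
           fan_in + 1, sizes[l + 1])                # last row = bias
  }))

  n <- nrow(X)
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    # forward
    acts <- vector("list", L + 1)
    acts[[1]] <- X
    for (l in seq_len(L)) {
      z <- cbind(acts[[l]], 1) %*% weights[[l]]
      acts[[l + 1]] <- if (l < L) act$f(z) else 1 / (1 + exp(-z))
    }
    p <- acts[[L + 1]]
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    if (!is.finite(loss)) stopf("non-finite loss at epoch %d", epoch)
    loss_history[epoch] <- loss
    # backward: delta at output for sigmoid + cross-entropy is (p - y)
    delta <- (p - y) / n
    for (l in rev(seq_len(L))) {
      grad <- crossprod(cbind(acts[[l]], 1), delta)
      if (l > 1) {
        back <- delta %*% t(weights[[l]][-nrow(weights[[l]]), , drop = FALSE])
        delta <- back * act$df(acts[[l]])
      }
      weights[[l]] <- weights[[l]] - config$learning_rate * grad
    }
  }
  scores <- nn_forward(weights, X, act)
  structure(list(weights = weights, config = config,
                 loss_history = loss_history,
                 train_accuracy = mean((scores >= 0.5) == y)),
            class = "nn_model")
}

nn_forward <- function(weights, X, act) {
  L <- length(weights)
  a <- X
  for (l in seq_len(L)) {
    z <- cbind(a, 1) %*% weights[[l]]
    a <- if (l < L) act$f(z) else 1 / (1 + exp(-z))
  }
  a
}

#' Predict class scores from a trained network
#'
#' @param model An `nn_model` from [train_nn()].
#' @param features Numeric matrix, features x samples.
#' @return Numeric vector of sigmoid output scores in (0, 1), named by
#'   sample.
#' @export
predict_nn <- function(model, features) {
  act <- activation_fns[[model$config$activation]]
  s <- nn_forward(model$weights, t(features), act)
  stats::setNames(as.numeric(s), colnames(features))
}

#' Grid search over network configurations by cross-validated accuracy
#'
#' Evaluates every lattice point (enumerated activation-outermost, then
#' hidden sizes, then learning rate) by stratified k-fold cross-validation
#' on the supplied (training) data and returns the configuration with the
#' highest mean accuracy; ties keep the first point in enumeration order.
#'
#' @param features Numeric matrix, features x samples (training half only,
#'   to avoid test leakage).
#' @param labels [sample_labels()] aligned to feature columns.
#' @param activations Character vector of activations to try.
#' @param hidden_grid List of hidden-size vectors.
#' @param learning_rates Numeric vector of learning rates.
#' @param epochs Training epochs per evaluation (default 800; a shorter
#'   budget than the final fit since only the ranking matters).
#' @param folds CV folds (default 5).
#' @param seed Integer seed (folds and weight init).
#' @return The winning [nn_config()], with attributes `cv_accuracy` and
#'   `grid` (data frame of all evaluated points).
#' @export
grid_search <- function(features, labels,
                        activations = c("sigmoid", "relu"),
                        hidden_grid = list(10, c(10, 5)),
                        learning_rates = c(0.01, 0.1),
                        epochs = 800, folds = 5, seed = 1) {
  labels <- labels[colnames(features)]
  fold <- stratified_folds(labels, folds, seed)
  results <- list()
  for (a in activations) for (h in hidden_grid) for (lr in learning_rates) {
    cfg <- nn_config(a, h, lr, epochs = epochs, seed = seed)
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      model <- train_nn(features[, tr, drop = FALSE], labels[tr], cfg)
      sc <- predict_nn(model, features[, !tr, drop = FALSE])
      mean((sc >= 0.5) == (labels[!tr] == "case"))
    }, numeric(1))
    results[[length(results) + 1]] <- list(config = cfg, acc = mean(acc))
  }
  accs <- vapply(results, `[[`, numeric(1), "acc")
  best <- results[[which.max(accs)]]$config      # first max in order
  attr(best, "cv_accuracy") <- max(accs)
  attr(best, "grid") <- data.frame(
    activation = vapply(results, function(r) r$config$activation, character(1)),
    hidden = vapply(results, function(r)
      paste(r$config$hidden_sizes, collapse = "-"), character(1)),
    learning_rate = vapply(results, function(r)
      r$config$learning_rate, numeric(1)),
    cv_accuracy = accs)
  best
}

#' ROC curve and AUC from classification scores
#'
#' Sweeps all score thresholds (equal scores grouped into one step) to
#' trace the ROC curve from (0, 0) to (1, 1) and integrates the area by
#' the trapezoid rule, which equals the normalized Mann-Whitney U
#' statistic with ties counted half.
#'
#' @param scores Numeric vector of classifier scores (larger = more
#'   case-like).
#' @param labels [sample_labels()] aligned to `scores` (by name when both
#'   are named, else by position).
#' @return A list of class `roc_result`: `points` (data frame `fpr`,
#'   `tpr`), `auc`, and `accuracy` at the 0.5 score cutoff.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels)))
    labels <- labels[names(scores)]
  y <- labels == "case"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy); fp <- cumsum(!yy)
  last <- !duplicated(s, fromLast = TRUE)                    # end of each group
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 accuracy = mean((scores >= 0.5) == y)),
            class = "roc_result")
}
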