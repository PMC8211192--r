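#' Pair-difference feature matrix
#'
#' One row per candidate pair, one column per sample, value
#' `expr(gene_low) - expr(gene_high)` — the within-sample relative
#' expression of the pair. Because both genes live in the same sample, any
#' per-sample additive term (array scaling on the log2 scale, batch shift)
#' cancels exactly, which is what makes pair features portable across
#' platforms without batch correction.
#'
#' @param matrix An [expression_matrix()] (calibrated in the standard
#'   pipeline).
#' @param pairs Data frame with columns `gene_low`, `gene_high`.
#' @return Numeric matrix |pairs| x |samples| with rownames
#'   `"low|high"`.
#' @export
pair_feature_values <- function(matrix, pairs) {
  if (!nrow(pairs)) stopf("no candidate pairs")
  if (any(pairs$gene_low == pairs$gene_high))
    stopf("a pair of a gene with itself is not allowed")
  missing <- setdiff(unique(c(pairs$gene_low, pairs$gene_high)),
                     rownames(matrix))
  if (length(missing))
    stopf("pair genes absent from matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  feats <- matrix[pairs$gene_low, , drop = FALSE] -
    matrix[pairs$gene_high, , drop = FALSE]
  rownames(feats) <- paste(pairs$gene_low, pairs$gene_high, sep = "|")
  feats
}

# Deterministic stratified fold assignment: samples of each class are
# shuffled under the seed and dealt round-robin into folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in levels(labels)) {
      ix <- which(labels == cls)
      if (length(ix) < k)
        stopf("class '%s' has %d samples, fewer than %d folds",
              cls, length(ix), k)
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

# Ridge-regularized least-squares classifier on {0,1} labels; returns
# predicted class for X_new. Deterministic, closed form: the cheap inner
# learner of the GA.
ridge_predict <- function(X_tr, y_tr, X_new, lambda = 1e-3) {
  X_tr <- cbind(1, X_tr)
  X_new <- cbind(1, X_new)
  p <- ncol(X_tr)
  pen <- diag(lambda, p); pen[1, 1] <- 0     # do not penalize the intercept
  w <- solve(crossprod(X_tr) + pen, crossprod(X_tr, y_tr))
  as.integer(X_new %*% w >= 0.5)
}

#' Cross-validated accuracy of a feature chain
#'
#' The GA fitness: mean accuracy of a ridge-regularized linear classifier
#' over stratified k-fold cross-validation, using only the feature rows the
#' chain selects. Deterministic given the seed (which fixes the folds).
#'
#' @param chain Logical/0-1 vector over feature rows, or integer row
#'   indices; must select at least one row.
#' @param features Matrix from [pair_feature_values()].
#' @param labels [sample_labels()] aligned to the feature columns.
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Accuracy in [0, 1].
#' @export
evaluate_fitness <- function(chain, features, labels, cv_folds = 5, seed = 1,
                             lambda = 1e-3) {
  rows <- if (is.logical(chain) || all(chain %in% c(0, 1)) &&
              length(chain) == nrow(features)) which(as.logical(chain))
          else as.integer(chain)
  if (!length(rows)) stopf("empty feature chain")
  labels <- labels[colnames(features)]
  y <- as.integer(labels == "case")
  X <- t(features[rows, , drop = FALSE])
  fold <- stratified_folds(labels, cv_folds, seed)
  correct <- 0L
  for (f in seq_len(cv_folds)) {
    te <- fold == f
    pred <- ridge_predict(X[!te, , drop = FALSE], y[!te],
                          X[te, , drop = FALSE], lambda)
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Genetic-algorithm configuration
#'
#' @param population_size Chains per generation (default 50).
#' @param crossover_rate Probability a child is produced by uniform
#'   crossover rather than copied (default 0.9).
#' @param mutation_rate Per-bit flip probability (default 0.01).
#' @param elite_fraction Fraction of top chains copied unchanged (default
#'   0.1).
#' @param max_generations Generation cap per chain length (default 100).
#' @param patience Generations without best-fitness improvement before a
#'   length run stops (default 20).
#' @param length_schedule Chain lengths as fractions of the candidate
#'   count, annealed from long to short (default `c(0.5, 0.25, 0.1)`; the
#'   first entry is the conventional half-length initialization).
#' @param cv_folds Folds for the fitness cross-validation (default 5).
#' @param fitness_cutoff Pairs with single-pair fitness above this value
#'   are selected (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.9,
                      mutation_rate = 0.01, elite_fraction = 0.1,
                      max_generations = 100, patience = 20,
                      length_schedule = c(0.5, 0.25, 0.1), cv_folds = 5,
                      fitness_cutoff = 0.5, seed = 1) {
  cfg <- list(population_size = check_count(population_size, "population_size", min = 2),
              crossover_rate = check_scalar(crossover_rate, "crossover_rate", 0, 1),
              mutation_rate = check_scalar(mutation_rate, "mutation_rate", 0, 1),
              elite_fraction = check_scalar(elite_fraction, "elite_fraction", 0, 1),
              max_generations = check_count(max_generations, "max_generations", min = 1),
              patience = check_count(patience, "patience", min = 1),
              length_schedule = as.numeric(length_schedule),
              cv_folds = check_count(cv_folds, "cv_folds", min = 2),
              fitness_cutoff = check_scalar(fitness_cutoff, "fitness_cutoff", 0, 1),
              seed = check_count(abs(seed), "seed"))
  if (!length(cfg$length_schedule) || any(cfg$length_schedule <= 0 |
                                          cfg$length_schedule > 1))
    stopf("'length_schedule' entries must be fractions in (0, 1]")
  class(cfg) <- "ga_config"
  cfg
}

# Keep chain cardinality within +/-20% of the target length (at least 1 bit)
repair_cardinality <- function(bits, target) {
  lo <- max(1L, as.integer(ceiling(0.8 * target)))
  hi <- max(lo, as.integer(floor(1.2 * target)))
  k <- sum(bits)
  if (k < lo) {
    zeros <- which(!bits)
    bits[zeros[sample.int(length(zeros), lo - k)]] <- TRUE
  } else if (k > hi) {
    ones <- which(bits)
    bits[ones[sample.int(length(ones), k - hi)]] <- FALSE
  }
  bits
}

#' Genetic-algorithm selection of gene-pair features
#'
#' Evolves binary "feature chains" over the candidate pairs. For each entry
#' of the length schedule (longest first), a population of chains with that
#' many bits set is initialized at random and iterated through elitist
#' selection, fitness-proportional parent sampling, uniform crossover,
#' per-bit mutation and cardinality repair, with fitness the
#' cross-validated accuracy from [evaluate_fitness()]. A length run stops
#' at `max_generations` or after `patience` generations without
#' improvement. Elitism makes the best fitness non-decreasing within each
#' run. Finally every candidate pair is scored alone (single-pair
#' cross-validated accuracy, the per-pair fitness of the results table)
#' and pairs above `fitness_cutoff` are selected. All candidates are
#' scored, not only best-chain members: once a chain reaches perfect
#' accuracy the GA has no pressure to include every informative pair, so
#' best-chain membership alone under-reports individually strong pairs.
#'
#' @param features Matrix from [pair_feature_values()].
#' @param labels [sample_labels()] aligned to feature columns.
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `best_by_length` (per schedule
#'   entry: target length, best chain indices, best fitness, fitness
#'   history), `pair_fitness` (named numeric over scored pairs),
#'   `selected_pairs` (data frame `gene_low`, `gene_high`, `fitness`
#'   sorted by fitness descending) and `config`.
#' @export
run_ga <- function(features, labels, config = ga_config()) {
  n_pairs <- nrow(features)
  if (is.null(n_pairs) || n_pairs < 1) stopf("no candidate pairs")
  labels <- labels[colnames(features)]
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- evaluate_fitness(bits, features, labels, config$cv_folds,
                            seed = config$seed)
    cache[[key]] <- val
    val
  }

  run_length <- function(target) {
    pop_n <- config$population_size
    pop <- replicate(pop_n, {
      b <- logical(n_pairs)
      b[sample.int(n_pairs, target)] <- TRUE
      b
    }, simplify = FALSE)
    fit <- vapply(pop, fitness_of, numeric(1))
    best_hist <- numeric(0)
    mean_hist <- numeric(0)
    stale <- 0L
    n_elite <- max(1L, as.integer(ceiling(config$elite_fraction * pop_n)))
    for (gen in seq_len(config$max_generations)) {
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord]; fit <- fit[ord]
      best_hist <- c(best_hist, fit[1])
      mean_hist <- c(mean_hist, mean(fit))
      if (gen > 1 && best_hist[gen] <= best_hist[gen - 1] + 1e-12)
        stale <- stale + 1L else stale <- 0L
      if (stale >= config$patience) break
      if (gen == config$max_generations) break
      w <- fit - min(fit) + 1e-9           # fitness-proportional weights
      children <- vector("list", pop_n - n_elite)
      for (ci in seq_along(children)) {
        par <- sample.int(pop_n, 2, prob = w)
        child <- if (stats::runif(1) < config$crossover_rate) {
          take_a <- stats::runif(n_pairs) < 0.5
          ifelse(take_a, pop[[par[1]]], pop[[par[2]]])
        } else pop[[par[1]]]
        flip <- stats::runif(n_pairs) < config$mutation_rate
        child <- xor(child, flip)
        children[[ci]] <- repair_cardinality(child, target)
      }
      pop <- c(pop[seq_len(n_elite)], children)
      fit <- c(fit[seq_len(n_elite)],
               vapply(children, fitness_of, numeric(1)))
    }
    ord <- order(fit, decreasing = TRUE)
    list(target_length = target, best_chain = which(pop[[ord[1]]]),
         best_fitness = fit[ord[1]], best_history = best_hist,
         mean_history = mean_hist)
  }

  targets <- unique(pmax(1L, as.integer(round(config$length_schedule * n_pairs))))
  best_by_length <- withr::with_seed(config$seed,
                                     lapply(targets, run_length))
  names(best_by_length) <- as.character(targets)

  scored <- seq_len(n_pairs)
  pair_fitness <- vapply(scored, function(i)
    evaluate_fitness(i, features, labels, config$cv_folds,
                     seed = config$seed), numeric(1))
  names(pair_fitness) <- rownames(features)[scored]
  sel <- pair_fitness > config$fitness_cutoff
  split_ids <- strsplit(names(pair_fitness)[sel], "|", fixed = TRUE)
  selected <- data.frame(
    gene_low = vapply(split_ids, `[[`, character(1), 1),
    gene_high = vapply(split_ids, `[[`, character(1), 2),
    fitness = unname(pair_fitness[sel]), stringsAsFactors = FALSE)
  selected <- selected[order(-selected$fitness, selected$gene_low), , drop = FALSE]
  rownames(selected) <- NULL
  structure(list(best_by_length = best_by_length,
                 pair_fitness = pair_fitness,
                 selected_pairs = selected, config = config),
            class = "ga_result")
}
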