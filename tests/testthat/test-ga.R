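test_that("pair features are within-sample differences", {
  labels <- make_labels(1, 1)
  m <- expression_matrix(rbind(gLow = c(1, 2), gHigh = c(0, 1)),
                         sample_ids = names(labels))
  feats <- pair_feature_values(m, data.frame(gene_low = "gLow",
                                             gene_high = "gHigh"))
  expect_equal(unname(feats[1, ]), c(1, 1))
  expect_error(pair_feature_values(m, data.frame(gene_low = "gLow",
                                                 gene_high = "gLow")),
               "itself")
  expect_error(pair_feature_values(m, data.frame(gene_low = "gLow",
                                                 gene_high = "gMissing")),
               "absent")
})

test_that("per-sample constants cancel bit-identically in pair features", {
  fix <- make_group_matrix(n_genes = 6, n_control = 4, n_case = 4, seed = 2)
  q <- function(x) round(x * 2^20) / 2^20       # exact-addition fixture
  m <- expression_matrix(q(unclass(fix$matrix)), rownames(fix$matrix),
                         colnames(fix$matrix))
  pairs <- data.frame(gene_low = c("g001", "g003"),
                      gene_high = c("g002", "g004"))
  f1 <- pair_feature_values(m, pairs)
  shift <- q(seq(-3, 4, length.out = ncol(m)))
  shifted <- expression_matrix(unclass(m) + rep(shift, each = nrow(m)),
                               rownames(m), colnames(m))
  f2 <- pair_feature_values(shifted, pairs)
  expect_identical(f1, f2)
})

test_that("fitness is CV accuracy: perfect, null, and duplicate features", {
  withr::with_seed(10, {
    n <- 200
    labels <- sample_labels(sprintf("s%03d", 1:n),
                            rep(c("case", "control"), each = n / 2))
    y <- as.numeric(labels == "case")
    feats <- rbind(perfect = y * 2 - 1, noise = rnorm(n))
    colnames(feats) <- names(labels)
    expect_equal(evaluate_fitness(1, feats, labels, seed = 1), 1.0)
    f_null <- evaluate_fitness(2, feats, labels, seed = 1)
    expect_gte(f_null, 0.4); expect_lte(f_null, 0.6)
    dup <- rbind(feats, perfect2 = feats["perfect", ])
    colnames(dup) <- names(labels)
    expect_equal(evaluate_fitness(c(1, 3), dup, labels, seed = 1),
                 evaluate_fitness(1, feats, labels, seed = 1))
  })
  expect_error(evaluate_fitness(integer(0), matrix(1, 1, 4),
                                make_labels(2, 2)), "empty")
})

test_that("a single candidate degenerates to its own accuracy", {
  fix <- make_ga_features(n_noise = 0, n_inf = 1, n = 40, seed = 4)
  ga <- run_ga(fix$features, fix$labels,
               ga_config(population_size = 4, max_generations = 5, seed = 1))
  expect_equal(names(ga$pair_fitness), rownames(fix$features))
  expect_equal(nrow(ga$selected_pairs),
               as.integer(ga$pair_fitness > 0.5))
})

test_that("elitism makes best fitness non-decreasing and runs reproduce", {
  fix <- make_ga_features(n_noise = 6, n_inf = 2, n = 40, seed = 7)
  cfg <- ga_config(population_size = 12, max_generations = 25,
                   patience = 8, seed = 3)
  ga1 <- run_ga(fix$features, fix$labels, cfg)
  ga2 <- run_ga(fix$features, fix$labels, cfg)
  for (run in ga1$best_by_length)
    expect_false(is.unsorted(run$best_history))
  expect_identical(ga1$best_by_length, ga2$best_by_length)
  expect_identical(ga1$pair_fitness, ga2$pair_fitness)
})

test_that("planted informative pairs out-rank noise pairs", {
  fix <- make_ga_features(n_noise = 10, n_inf = 2, n = 80, seed = 5)
  ga <- run_ga(fix$features, fix$labels,
               ga_config(population_size = 20, max_generations = 30,
                         patience = 10, seed = 2))
  inf_names <- rownames(fix$features)[fix$informative]
  noise_names <- setdiff(rownames(fix$features), inf_names)
  expect_true(all(ga$pair_fitness[inf_names] >
                    median(ga$pair_fitness[noise_names])))
  expect_true(all(inf_names %in%
                    paste(ga$selected_pairs$gene_low,
                          ga$selected_pairs$gene_high, sep = "|")))
})

test_that("cardinality repair respects the 20 percent band", {
  withr::with_seed(1, {
    bits <- rep(FALSE, 30)
    fixed <- pairwave:::repair_cardinality(bits, 10)
    expect_equal(sum(fixed), 8)               # raised to ceiling(0.8 * 10)
    over <- rep(TRUE, 30)
    fixed2 <- pairwave:::repair_cardinality(over, 10)
    expect_equal(sum(fixed2), 12)             # cut to floor(1.2 * 10)
    one <- rep(FALSE, 5)
    expect_equal(sum(pairwave:::repair_cardinality(one, 1)), 1)
  })
})
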