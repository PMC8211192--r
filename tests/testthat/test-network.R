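test_that("exact linear relations give r = +/-1 with the right sign", {
  x <- c(1, 2, 3, 4, 5)
  m <- expression_matrix(rbind(gx = x, gy = 2 * x + 1, gz = -x),
                         sample_ids = sprintf("s%d", 1:5))
  edges <- pairwise_correlations(m)
  xy <- edges[edges$gene_a == "gx" & edges$gene_b == "gy", ]
  xz <- edges[edges$gene_a == "gx" & edges$gene_b == "gz", ]
  expect_equal(xy$r, 1)
  expect_equal(xy$sign, "positive")
  expect_equal(xy$p_value, 0)
  expect_equal(xz$r, -1)
  expect_equal(xz$sign, "negative")
})

test_that("r and p match direct-formula and cor.test oracles", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 4, 8)
  m <- expression_matrix(rbind(gx = x, gy = y), sample_ids = sprintf("s%d", 1:4))
  edges <- pairwise_correlations(m)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(edges$r, r_direct, tolerance = 1e-10)
  ct <- cor.test(x, y)
  expect_equal(edges$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("constant genes are excluded with a warning", {
  m <- expression_matrix(rbind(g1 = c(1, 2, 3, 4), gflat = rep(2, 4),
                               g3 = c(2, 1, 4, 3)),
                         sample_ids = sprintf("s%d", 1:4))
  expect_warning(edges <- pairwise_correlations(m), "constant gene")
  expect_false("gflat" %in% c(edges$gene_a, edges$gene_b))
  expect_equal(nrow(edges), 1)
})

test_that("edges are invariant under sample reordering", {
  fix <- make_group_matrix(n_genes = 8, n_control = 5, n_case = 5, seed = 12)
  e1 <- pairwise_correlations(fix$matrix)
  perm <- sample(ncol(fix$matrix))
  m2 <- expression_matrix(unclass(fix$matrix)[, perm],
                          rownames(fix$matrix), colnames(fix$matrix)[perm])
  e2 <- pairwise_correlations(m2)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("network thresholding is strict and drops isolated genes", {
  edges <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
                      r = c(0.9, 0.3, 0.5), p_value = c(0.01, 0.01, 0.01),
                      sign = c("positive", "positive", "positive"))
  net <- build_network(edges, r_min = 0.5, p_max = 0.05)
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)

  # r exactly at the threshold is excluded
  net2 <- build_network(data.frame(gene_a = "A", gene_b = "B", r = 0.8,
                                   p_value = 0.001, sign = "positive"),
                        r_min = 0.8)
  expect_equal(length(net2$nodes), 0)
  expect_equal(nrow(net2$edges), 0)
  expect_error(build_network(edges, r_min = 1.2), "r_min")
})

test_that("degrees satisfy the handshake lemma and fill the gene universe", {
  triangle <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                         r = 0.9, p_value = 0.001, sign = "positive")
  net <- build_network(triangle, 0.5)
  expect_equal(unname(node_degrees(net)), c(2L, 2L, 2L))

  star <- data.frame(gene_a = c("X", "X", "X", "X"),
                     gene_b = c("L1", "L2", "L3", "L4"),
                     r = 0.9, p_value = 0.001, sign = "positive")
  snet <- build_network(star, 0.5)
  deg <- node_degrees(snet)
  expect_equal(deg[["X"]], 4L)
  expect_true(all(deg[c("L1", "L2", "L3", "L4")] == 1L))
  expect_equal(sum(deg), 2 * nrow(snet$edges))

  full <- gene_degrees(snet, c("X", "L1", "Z1", "Z2"))
  expect_equal(unname(full), c(4L, 1L, 0L, 0L))

  # handshake on a random thresholded network
  fix <- make_group_matrix(n_genes = 12, n_control = 6, n_case = 6, seed = 5)
  rnet <- build_network(pairwise_correlations(fix$matrix), r_min = 0.3,
                        p_max = 0.5)
  expect_equal(sum(node_degrees(rnet)), 2 * nrow(rnet$edges))
})

test_that("within-cluster correlations exceed between-cluster on synthetic data", {
  d <- generate_dataset(synthetic_config(n_case = 40, n_control = 40,
                                         n_genes = 120, n_clusters = 3,
                                         n_de_genes = 0, n_planted_pairs = 0,
                                         seed = 21))
  genes <- sample(rownames(d$matrix), 40)
  edges <- pairwise_correlations(d$matrix, genes)
  cl <- d$truth$cluster_of
  same <- cl[edges$gene_a] == cl[edges$gene_b]
  expect_gt(mean(edges$r[same]), mean(edges$r[!same]))
})
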