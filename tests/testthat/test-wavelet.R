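test_that("tracks order by cluster, then degree, then gene id", {
  degs <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     direction = c("up", "up", "up", "down"),
                     stringsAsFactors = FALSE)
  cluster_of <- c(g1 = 1L, g2 = 1L, g3 = 2L, g4 = 1L)
  degrees <- c(g1 = 5L, g2 = 2L, g3 = 7L, g4 = 0L)
  tracks <- build_tracks(degs, cluster_of, degrees)
  expect_equal(tracks$up$ordered_genes, c("g2", "g1", "g3"))
  expect_equal(tracks$up$boundary_after, 2L)
  expect_equal(tracks$down$ordered_genes, "g4")

  # equal cluster and degree -> lexicographic
  degs2 <- data.frame(gene_id = c("gB", "gA"), direction = "up",
                      stringsAsFactors = FALSE)
  t2 <- suppressWarnings(
    build_tracks(degs2, c(gA = 1L, gB = 1L), c(gA = 3L, gB = 3L)))
  expect_equal(t2$up$ordered_genes, c("gA", "gB"))
  expect_warning(
    t3 <- build_tracks(degs2, c(gA = 1L, gB = 1L), c(gA = 1L, gB = 1L)),
    "no down-regulated")
  expect_null(t3$down)
})

test_that("group mean signals average the right samples", {
  labels <- make_labels(2, 2)
  m <- expression_matrix(rbind(g1 = c(1, 3, 3, 3),
                               g2 = c(0, 0, 2, 6),
                               g3 = c(5, 5, 5, 5)),
                         sample_ids = names(labels))
  track <- structure(list(direction = "up",
                          ordered_genes = c("g2", "g1", "g3"),
                          boundary_after = integer(0)),
                     class = "gene_track")
  case_sig <- group_mean_signal(m, labels, track, "case")
  ctrl_sig <- group_mean_signal(m, labels, track, "control")
  expect_equal(unname(case_sig), c(4, 3, 5))
  expect_equal(unname(ctrl_sig), c(0, 2, 5))
})

test_that("difference and moving average obey their contracts", {
  expect_equal(adjacent_difference(c(3, 1, 4)), c(-2, 3))
  expect_equal(adjacent_difference(rep(2, 5)), rep(0, 4))
  s <- c(0.3, -1, 2, 5, -0.5)
  expect_equal(cumsum(c(s[1], adjacent_difference(s))), s)
  expect_error(adjacent_difference(1), "length >= 2")

  expect_equal(as.numeric(moving_average(1:5, 3)), c(2, 3, 4))
  expect_equal(attr(moving_average(1:5, 3), "offset"), 1L)
  expect_equal(as.numeric(moving_average(s, 1)), s)
  expect_equal(as.numeric(moving_average(rep(7, 6), 3)), rep(7, 4))
  expect_error(moving_average(1:5, 2), "odd")
  expect_error(moving_average(1:3, 5), "exceeds")
})

test_that("the Ricker CWT is linear and matches brute-force convolution", {
  expect_equal(cwt_transform(numeric(10), 1:2),
               matrix(0, 2, 10, dimnames = list(c("1", "2"), NULL)))
  set.seed(3)
  sig <- rnorm(32)
  co1 <- cwt_transform(sig, c(1, 2, 4))
  co2 <- cwt_transform(3 * sig, c(1, 2, 4))
  expect_equal(co2, 3 * co1, tolerance = 1e-10)

  impulse <- c(rep(0, 16), 1, rep(0, 15))
  co <- cwt_transform(impulse, 2)
  oracle <- cwt_oracle(impulse, 2)
  expect_lt(max(abs(co - oracle)), 1e-8)
  expect_error(cwt_transform(1:3, 1), "length >= 4")
})

test_that("peak detection applies the threshold rule and plateau tie-break", {
  pk <- detect_peaks(c(0, 0.5, 0.2), threshold = 0.3)
  expect_equal(pk$peaks, 2L)
  expect_equal(detect_peaks(c(0.1, 0.2, 0.1), threshold = 0.5)$peaks,
               integer(0))
  expect_equal(detect_peaks(c(0, 1, 1, 0), threshold = 0.5)$peaks, 2L)
  # mean + 2SD rule
  scores <- c(rep(0.1, 20), 2)
  pk2 <- detect_peaks(scores)
  expect_equal(pk2$threshold, mean(scores) + 2 * sd(scores))
  expect_equal(pk2$peaks, 21L)
  # numerically-zero signals yield no peaks
  expect_equal(detect_peaks(rep(1e-16, 10) * c(1, 2), threshold = NULL)$peaks,
               integer(0))
})

test_that("peaks map to adjacent pairs with the moving-average offset", {
  track <- structure(list(direction = "up",
                          ordered_genes = c("a", "b", "c", "d"),
                          boundary_after = integer(0)),
                     class = "gene_track")
  pairs <- peaks_to_pairs(1L, track, ma_offset = 1)
  expect_equal(pairs$gene_low, "b")
  expect_equal(pairs$gene_high, "c")

  # pair on a cluster boundary is dropped
  track$boundary_after <- 2L
  expect_equal(nrow(peaks_to_pairs(1L, track, ma_offset = 1)), 0)
  expect_error(peaks_to_pairs(5L, track, ma_offset = 1), "out of range")
})

test_that("candidates deduplicate across tracks keeping the largest peak", {
  labels <- make_labels(6, 6)
  set.seed(2)
  n <- 12
  base <- matrix(rnorm(9 * n, 0, 0.05), 9, n)
  # up-regulated genes with a sharp contrast between g4 and g5 in cases
  shift <- c(2, 2, 2, 3.2, 1.2, 2, 2, 2, 2)
  base <- base + outer(shift, as.numeric(labels == "case"))
  m <- expression_matrix(base, sprintf("g%d", 1:9), names(labels))
  degs <- data.frame(gene_id = sprintf("g%d", 1:9), direction = "up",
                     stringsAsFactors = FALSE)
  tracks <- suppressWarnings(build_tracks(
    degs, setNames(rep(1L, 9), sprintf("g%d", 1:9)),
    setNames(1:9, sprintf("g%d", 1:9))))
  cand <- wavelet_candidate_pairs(m, labels, tracks, window = 1)
  expect_true(nrow(cand) >= 1)
  expect_equal(cand$gene_low[1], "g4")
  expect_equal(cand$gene_high[1], "g5")
  key <- paste(cand$gene_low, cand$gene_high)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("candidate detection is invariant to order-preserving relabeling", {
  d <- generate_dataset(synthetic_config(n_case = 50, n_control = 50,
                                         n_genes = 400, n_de_genes = 60,
                                         n_planted_pairs = 2, seed = 31))
  cal <- zscore_calibrate(d$matrix, d$labels)
  degs <- filter_degs(differential_expression(cal$matrix, d$labels,
                                              raw = d$matrix))
  cl <- d$truth$cluster_of
  net <- build_network(pairwise_correlations(cal$matrix, degs$gene_id), 0.8)
  dv <- gene_degrees(net, degs$gene_id)
  tracks <- suppressWarnings(build_tracks(degs, cl, dv))
  cand1 <- wavelet_candidate_pairs(cal$matrix, d$labels, tracks)

  relabel <- function(x) sub("^g", "h", x)      # preserves lexicographic order
  m2 <- expression_matrix(unclass(cal$matrix), relabel(rownames(cal$matrix)),
                          colnames(cal$matrix), calibrated = TRUE)
  degs2 <- degs; degs2$gene_id <- relabel(degs$gene_id)
  cl2 <- setNames(cl, relabel(names(cl)))
  dv2 <- setNames(dv, relabel(names(dv)))
  tracks2 <- suppressWarnings(build_tracks(degs2, cl2, dv2))
  cand2 <- wavelet_candidate_pairs(m2, d$labels, tracks2)
  expect_equal(relabel(cand1$gene_low), cand2$gene_low)
  expect_equal(relabel(cand1$gene_high), cand2$gene_high)
  expect_equal(cand1$peak_magnitude, cand2$peak_magnitude, tolerance = 1e-12)
})
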