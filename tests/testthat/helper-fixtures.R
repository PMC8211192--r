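# Shared fixture builders. Everything is generated in code; no binary data.

tiny_matrix <- function() {
  expression_matrix(matrix(c(1, 2, 3,
                             4, 5, 6), nrow = 2, byrow = TRUE),
                    gene_ids = c("gA", "gB"),
                    sample_ids = c("s1", "s2", "s3"))
}

# labels with n_control controls then n_case cases, ids c1.., k1..
make_labels <- function(n_control, n_case) {
  sample_labels(c(sprintf("c%02d", seq_len(n_control)),
                  sprintf("k%02d", seq_len(n_case))),
                rep(c("control", "case"), c(n_control, n_case)))
}

# small two-group matrix: n_genes x (n_control + n_case), seeded
make_group_matrix <- function(n_genes = 10, n_control = 4, n_case = 4,
                              case_shift = 0, seed = 1) {
  labels <- make_labels(n_control, n_case)
  m <- withr::with_seed(seed, {
    base <- matrix(rnorm(n_genes * length(labels)), n_genes)
    base + outer(rep(case_shift, n_genes), as.numeric(labels == "case"))
  })
  list(matrix = expression_matrix(m, sprintf("g%03d", seq_len(n_genes)),
                                  names(labels)),
       labels = labels)
}

# write a minimal GEO-style series matrix file; returns the path
write_series_fixture <- function(path, with_end = TRUE) {
  lines <- c(
    "!Series_title\t\"synthetic two-sample fixture\"",
    "!Sample_title\t\"s1\"\t\"s2\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"s1\"\t\"s2\"",
    "\"gA\"\t1.5\t2.5",
    "\"gB\"\t3\t4")
  if (with_end) lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

# brute-force Ricker CWT oracle: direct double loop over positions/taps
cwt_oracle <- function(signal, scales) {
  n <- length(signal)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    psi <- ricker_kernel(scales[si])
    hw <- attr(psi, "half_width")
    for (t in seq_len(n)) {
      acc <- 0
      for (u in seq_len(n)) {
        k <- u - t
        if (abs(k) <= hw) acc <- acc + signal[u] * psi[hw + 1 + k]
      }
      out[si, t] <- acc
    }
  }
  out
}

# exhaustive best subset fitness over all non-empty chains (<= 15 pairs)
exhaustive_best_fitness <- function(features, labels, cv_folds, seed) {
  n <- nrow(features)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    f <- evaluate_fitness(rows, features, labels, cv_folds, seed = seed)
    if (f > best) best <- f
  }
  best
}

# feature matrix with a known number of informative rows
make_ga_features <- function(n_noise = 8, n_inf = 2, n = 60, seed = 1) {
  withr::with_seed(seed, {
    labels <- sample_labels(sprintf("s%02d", seq_len(n)),
                            rep(c("case", "control"), each = n / 2))
    y <- as.numeric(labels == "case")
    eff <- seq(1.5, 1.0, length.out = n_inf)
    feats <- rbind(
      matrix(rnorm(n_noise * n), n_noise, n),
      t(vapply(eff, function(e) y * e + rnorm(n, 0, 0.9), numeric(n))))
    rownames(feats) <- paste0("gA", seq_len(n_noise + n_inf), "|",
                              "gB", seq_len(n_noise + n_inf))
    colnames(feats) <- names(labels)
    list(features = feats, labels = labels,
         informative = n_noise + seq_len(n_inf))
  })
}
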