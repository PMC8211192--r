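#' Configuration for the synthetic cohort generator
#'
#' Defines a two-group (case/control) log2-expression cohort with the
#' statistical structure the downstream analysis assumes: co-expression
#' clusters driven by latent per-cluster factors, differentially expressed
#' genes, planted gene pairs whose within-sample expression difference
#' separates the groups, per-gene noise and a per-sample additive nuisance
#' shift (the log2-scale equivalent of multiplicative array scaling).
#'
#' Defaults mirror a cohort of 112 cases and 114 controls. Effect sizes are
#' on the log2 scale: `de_effect = 3` is a strong microarray effect,
#' `pair_effect = 2` with `pair_noise_sd = 0.3` gives a pair-difference
#' signal that cleanly separates groups while each member gene alone stays
#' noisy through its shared latent variance.
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_genes Total number of genes (pair genes and DE genes included).
#' @param n_clusters Number of co-expression clusters (0 = independent genes).
#' @param cluster_factor_sd SD of per-gene factor loadings around 1.
#' @param cluster_factor_means Per-cluster mean of the latent factor,
#'   recycled to `n_clusters` (default 0; distinct values separate clusters
#'   in uncalibrated profile space).
#' @param n_de_genes Number of planted differentially expressed genes
#'   (half up-, half down-regulated).
#' @param de_effect Mean case-group shift of planted DE genes (log2 units).
#' @param de_effect_sd Gene-to-gene SD of the DE effect size around
#'   `de_effect` (effect sizes in real cohorts are heterogeneous); effects
#'   are truncated below at `de_effect / 2` so every planted DE gene stays
#'   clearly regulated in its direction.
#' @param n_planted_pairs Number of planted gene pairs.
#' @param pair_effect Case-group mean shift of the within-pair expression
#'   difference (log2 units).
#' @param pair_noise_sd SD of the pair difference around its group mean.
#' @param pair_factor_sd SD of the pair-private latent factor shared by the
#'   two genes of a planted pair; it makes each gene individually noisy
#'   (and mutually correlated) without touching the pair difference.
#' @param noise_sd SD of per-gene iid noise.
#' @param sample_shift_sd SD of the per-sample additive nuisance shift.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 112, n_control = 114,
                             n_genes = 1500, n_clusters = 7,
                             cluster_factor_sd = 0.2,
                             cluster_factor_means = 0,
                             n_de_genes = 200, de_effect = 3,
                             de_effect_sd = 0,
                             n_planted_pairs = 5, pair_effect = 2,
                             pair_noise_sd = 0.3, pair_factor_sd = 1.5,
                             noise_sd = 1,
                             sample_shift_sd = 0.5, seed = 1) {
  cfg <- list(
    n_case = check_count(n_case, "n_case"),
    n_control = check_count(n_control, "n_control"),
    n_genes = check_count(n_genes, "n_genes"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    cluster_factor_sd = check_scalar(cluster_factor_sd, "cluster_factor_sd", min = 0),
    cluster_factor_means = as.numeric(cluster_factor_means),
    n_de_genes = check_count(n_de_genes, "n_de_genes"),
    de_effect = check_scalar(de_effect, "de_effect"),
    de_effect_sd = check_scalar(de_effect_sd, "de_effect_sd", min = 0),
    n_planted_pairs = check_count(n_planted_pairs, "n_planted_pairs"),
    pair_effect = check_scalar(pair_effect, "pair_effect"),
    pair_noise_sd = check_scalar(pair_noise_sd, "pair_noise_sd", min = 0),
    pair_factor_sd = check_scalar(pair_factor_sd, "pair_factor_sd", min = 0),
    noise_sd = check_scalar(noise_sd, "noise_sd", min = 0),
    sample_shift_sd = check_scalar(sample_shift_sd, "sample_shift_sd", min = 0),
    seed = check_count(abs(seed), "seed"))
  if (cfg$n_planted_pairs * 6 + cfg$n_de_genes > cfg$n_genes)
    stopf(paste("n_genes too small: each planted pair occupies a 6-gene",
                "block (pair + two flanking decoy twin pairs), so",
                "6*n_planted_pairs + n_de_genes must not exceed n_genes"))
  if (cfg$n_clusters > 0)
    cfg$cluster_factor_means <- rep_len(cfg$cluster_factor_means, cfg$n_clusters)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic case/control expression cohort
#'
#' Builds a genes x samples log2-expression matrix from the model
#' `x[g, s] = baseline[g] + loading[g] * factor[cluster(g), s] +
#'  pairfactor + effects + shift[s] + noise`, where:
#' \itemize{
#'   \item each cluster contributes one latent standard-normal factor per
#'     sample, with per-gene loadings `~ N(1, cluster_factor_sd)`;
#'   \item planted DE genes get a `+/- de_effect` shift in case samples;
#'   \item each planted pair (a, b) shares its baseline, loading, cluster
#'     factor and an additional pair-private latent factor (SD 1), so both
#'     genes are individually noisy yet strongly mutually correlated. In
#'     case samples the pair is centred on a `de_effect` shift (keeping both
#'     genes up-regulated, hence in the same track downstream) with gene a
#'     raised by `pair_effect/2` and gene b lowered by `pair_effect/2`;
#'     each gene carries private noise of SD `pair_noise_sd/sqrt(2)` so the
#'     difference `a - b` has SD `pair_noise_sd` exactly, mean
#'     `pair_effect` in cases and 0 in controls. The per-sample shift and
#'     all shared terms cancel exactly in the difference.
#' }
#'
#' @param config A [synthetic_config()].
#' @return A list with components `matrix` (an [expression_matrix()]),
#'   `labels` (a [sample_labels()] factor, controls then cases) and `truth`,
#'   a list with `planted_pairs` (data frame `gene_a`, `gene_b`; the track
#'   convention puts `gene_a` first), `de_genes` (data frame `gene_id`,
#'   `direction`) and `cluster_of` (named integer vector, 0 when
#'   `n_clusters = 0`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  if (config$n_case < 2 || config$n_control < 2)
    stopf("need at least 2 samples per group")
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_s <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("ctrl_%03d", seq_len(cfg$n_control)),
                  sprintf("case_%03d", seq_len(cfg$n_case)))
  labels <- sample_labels(sample_ids,
                          rep(c("control", "case"),
                              c(cfg$n_control, cfg$n_case)))
  is_case <- as.numeric(labels == "case")

  width <- max(4, nchar(cfg$n_genes))
  gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))

  # Each planted pair occupies a 6-gene block of consecutive ids:
  # a flanking decoy twin pair, the planted pair, a second decoy twin pair,
  # all in one cluster. Decoys are co-expressed twin genes with the same
  # marginal construction as planted-pair genes but no internal contrast:
  # they enrich the correlation structure beyond pure cluster blocks and
  # give every planted pair neighbours at the typical calibrated DE level.
  P <- cfg$n_planted_pairs
  n_block <- 6L * P
  pair_idx <- if (P > 0) as.vector(vapply(seq_len(P), function(p)
    6L * (p - 1L) + c(3L, 4L), integer(2))) else integer(0)
  twin_idx <- seq_len(n_block)                       # pairs + decoys
  de_idx <- seq_len(cfg$n_de_genes) + n_block        # next block: DE genes

  # cluster membership: each pair block wholly in one cluster, rest round-robin
  cluster_of <- integer(cfg$n_genes)
  if (cfg$n_clusters > 0) {
    rest <- setdiff(seq_len(cfg$n_genes), twin_idx)
    cluster_of[rest] <- rep_len(seq_len(cfg$n_clusters), length(rest))
    if (P > 0) {
      block_cluster <- rep_len(seq_len(cfg$n_clusters), P)
      cluster_of[twin_idx] <- rep(block_cluster, each = 6)
    }
  }

  baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
  loading <- stats::rnorm(cfg$n_genes, mean = 1, sd = cfg$cluster_factor_sd)
  if (P > 0) {
    # Twin partners share baseline and loading so shared terms cancel in
    # a - b. Twin genes follow their cluster factor at half strength: the
    # pair-private factor is their dominant co-expression driver, while the
    # residual cluster coupling keeps each block embedded in its cluster.
    a_idx <- twin_idx[twin_idx %% 2 == 1]
    baseline[a_idx + 1L] <- baseline[a_idx]
    loading[twin_idx] <- loading[twin_idx] / 2
    loading[a_idx + 1L] <- loading[a_idx]
  }
  x <- matrix(0, cfg$n_genes, n_s, dimnames = list(gene_ids, sample_ids))

  if (cfg$n_clusters > 0) {
    factors <- matrix(stats::rnorm(cfg$n_clusters * n_s), cfg$n_clusters, n_s) +
      cfg$cluster_factor_means
    x <- x + loading * factors[pmax(cluster_of, 1L), , drop = FALSE] *
      (cluster_of > 0)
  }

  # planted DE genes: alternating up/down shifts in case samples
  de_dir <- character(0)
  if (cfg$n_de_genes > 0) {
    de_dir <- rep_len(c("up", "down"), cfg$n_de_genes)
    de_sign <- ifelse(de_dir == "up", 1, -1)
    de_size <- pmax(cfg$de_effect / 2,
                    stats::rnorm(cfg$n_de_genes, cfg$de_effect,
                                 cfg$de_effect_sd))
    x[de_idx, ] <- x[de_idx, , drop = FALSE] +
      outer(de_sign * de_size, is_case)
  }

  # Planted pairs: a shared pair-private factor (SD pair_factor_sd) makes
  # the two genes strongly mutually correlated while diluting their
  # correlation with the rest of the cohort, and opposed half-effects
  # +/- pair_effect/2 ride on a common case shift. That shift is centred
  # so that, after control-group calibration, the two genes straddle the
  # level of ordinary DE genes symmetrically: pair genes have marginal SD
  # ~ sqrt(1 + pair_factor_sd^2 + eps^2) versus sqrt(2) for a DE gene, so
  # the common shift is de_effect rescaled by that ratio. Both genes stay
  # clearly up-regulated for any pair_effect < 2 * de_effect.
  if (P > 0) {
    eps_sd <- cfg$pair_noise_sd / sqrt(2)
    has_cluster <- as.numeric(cfg$n_clusters > 0)
    # centre the twin genes' case shift so that, in control-calibrated
    # units, they straddle the level of ordinary DE genes symmetrically
    sd_twin <- sqrt(has_cluster / 4 + cfg$pair_factor_sd^2 + eps_sd^2 +
                      cfg$sample_shift_sd^2)
    sd_bg <- sqrt(has_cluster + cfg$noise_sd^2 + cfg$sample_shift_sd^2)
    base <- cfg$de_effect * sd_twin / sd_bg
    add_twin <- function(a, contrast, shift) {   # genes a, a+1; case shift +/- contrast/2
      shared <- stats::rnorm(n_s, sd = cfg$pair_factor_sd)
      x[a, ] <<- x[a, ] + shared + is_case * (shift + contrast / 2) +
        stats::rnorm(n_s, sd = eps_sd)
      x[a + 1L, ] <<- x[a + 1L, ] + shared + is_case * (shift - contrast / 2) +
        stats::rnorm(n_s, sd = eps_sd)
    }
    for (p in seq_len(P)) {
      o <- 6L * (p - 1L)
      add_twin(o + 1L, 0, base)                 # left decoy
      add_twin(o + 3L, cfg$pair_effect, base)   # the planted pair
      add_twin(o + 5L, 0, base)                 # right decoy
    }
  }

  # iid noise for non-twin genes, baseline, per-sample nuisance shift
  non_pair <- setdiff(seq_len(cfg$n_genes), twin_idx)
  if (length(non_pair) > 0 && cfg$noise_sd > 0)
    x[non_pair, ] <- x[non_pair, , drop = FALSE] +
      matrix(stats::rnorm(length(non_pair) * n_s, sd = cfg$noise_sd),
             length(non_pair), n_s)
  shift <- stats::rnorm(n_s, sd = cfg$sample_shift_sd)
  x <- x + baseline + rep(shift, each = cfg$n_genes)

  truth <- list(
    planted_pairs = data.frame(
      gene_a = gene_ids[pair_idx[seq_len(P) * 2 - 1]],
      gene_b = gene_ids[pair_idx[seq_len(P) * 2]],
      stringsAsFactors = FALSE),
    de_genes = data.frame(gene_id = gene_ids[de_idx], direction = de_dir,
                          stringsAsFactors = FALSE),
    cluster_of = stats::setNames(cluster_of, gene_ids))

  list(matrix = expression_matrix(x, gene_ids, sample_ids),
       labels = labels, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard matrix TSV, labels TSV and the ground truth as JSON.
#'
#' @param dataset A list from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(dataset$matrix, file.path(dir, "expression.tsv"))
  write_labels_tsv(dataset$labels, file.path(dir, "labels.tsv"))
  truth <- dataset$truth
  truth$cluster_of <- as.list(truth$cluster_of)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
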