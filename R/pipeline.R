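#' Pipeline configuration
#'
#' One object holding every stage's parameters with the conventional
#' defaults: DE filter p < 0.01 and |logFC| > 1, three principal
#' components for gene clustering, network threshold |r| > 0.8 with
#' p < 0.05, moving-average window 3, Ricker scales {1, 2, 4}, peak rule
#' mean + 2 SD, GA and NN defaults from [ga_config()] and the standard
#' grid. Input is either a synthetic config or paths to matrix/label TSVs.
#'
#' @param synthetic A [synthetic_config()] (default) — or `NULL` when
#'   `matrix_path`/`labels_path` are given.
#' @param matrix_path,labels_path Paths to an expression TSV and labels
#'   TSV, used when `synthetic` is `NULL`.
#' @param deg_p,deg_lfc DE filter thresholds.
#' @param d0 Moderated-t prior degrees of freedom.
#' @param n_components Principal components used for gene clustering.
#' @param k_range Candidate cluster counts for the mixture model.
#' @param r_min,cor_p Network thresholds.
#' @param ma_window,scales,peak_c_sd,peak_mode Wavelet stage parameters.
#' @param ga A [ga_config()] (its seed is overridden by the pipeline seed).
#' @param nn_activations,nn_hidden_grid,nn_learning_rates,nn_grid_epochs
#'   Grid-search lattice and its per-point epoch budget.
#' @param nn_epochs Epochs of the final fit.
#' @param seed Global seed; each stage derives its own via [stage_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            matrix_path = NULL, labels_path = NULL,
                            deg_p = 0.01, deg_lfc = 1, d0 = 4,
                            n_components = 3, k_range = 1:7,
                            r_min = 0.8, cor_p = 0.05,
                            ma_window = 1, scales = c(1, 2, 4),
                            peak_c_sd = 2, peak_mode = "any",
                            ga = ga_config(),
                            nn_activations = c("sigmoid", "relu"),
                            nn_hidden_grid = list(10, c(10, 5)),
                            nn_learning_rates = c(0.01, 0.1),
                            nn_grid_epochs = 800, nn_epochs = 2000,
                            seed = 1) {
  if (is.null(synthetic) && (is.null(matrix_path) || is.null(labels_path)))
    stopf("either a synthetic config or matrix/label paths are required")
  structure(list(synthetic = synthetic, matrix_path = matrix_path,
                 labels_path = labels_path, deg_p = deg_p,
                 deg_lfc = deg_lfc, d0 = d0, n_components = n_components,
                 k_range = k_range, r_min = r_min, cor_p = cor_p,
                 ma_window = ma_window, scales = scales,
                 peak_c_sd = peak_c_sd, peak_mode = peak_mode, ga = ga,
                 nn_activations = nn_activations,
                 nn_hidden_grid = nn_hidden_grid,
                 nn_learning_rates = nn_learning_rates,
                 nn_grid_epochs = nn_grid_epochs, nn_epochs = nn_epochs,
                 seed = check_count(abs(seed), "seed")),
            class = "pipeline_config")
}

#' Run the full gene-pair discovery pipeline
#'
#' Executes calibration, differential expression, PCA + mixture gene
#' clustering, co-expression network construction, wavelet candidate-pair
#' detection, genetic-algorithm pair selection and the final neural
#' classifier with a stratified half split, ROC and AUC. Fully
#' deterministic given the config. When `out_dir` is given, stage
#' artifacts (TSV tables) and the machine-readable `report.json` are
#' written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result` with all stage objects and a
#'   `report` list of summary counts and metrics.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  # --- input -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- stage_seed(config$seed, 1)
    data <- generate_dataset(syn)
    matrix <- data$matrix; labels <- data$labels; truth <- data$truth
  } else {
    matrix <- read_expression_tsv(config$matrix_path)
    labels <- read_labels_tsv(config$labels_path)
    truth <- NULL
  }

  # --- preprocess + differential expression ------------------------------
  cal <- zscore_calibrate(matrix, labels)
  de <- differential_expression(cal$matrix, labels, raw = matrix,
                                d0 = config$d0)
  degs <- filter_degs(de, config$deg_p, config$deg_lfc)
  if (nrow(degs) < 5)
    stopf("only %d DEGs pass the filter; nothing to analyze", nrow(degs))

  # --- gene clustering on principal component scores ---------------------
  deg_mat <- cal$matrix[degs$gene_id, , drop = FALSE]
  pca <- pca_scree(deg_mat)
  m <- min(config$n_components, ncol(pca$scores))
  k_range <- config$k_range[config$k_range < nrow(deg_mat)]
  clusters <- gmm_cluster_bic(pca$scores[, seq_len(m), drop = FALSE],
                              k_range)

  # --- co-expression network and degrees ---------------------------------
  cors <- pairwise_correlations(cal$matrix, degs$gene_id)
  network <- build_network(cors, config$r_min, config$cor_p)
  degrees <- gene_degrees(network, degs$gene_id)

  # --- wavelet candidate pairs -------------------------------------------
  tracks <- suppressWarnings(
    build_tracks(degs, clusters$cluster_of, degrees))
  candidates <- wavelet_candidate_pairs(cal$matrix, labels, tracks,
                                        window = config$ma_window,
                                        scales = config$scales,
                                        c_sd = config$peak_c_sd,
                                        mode = config$peak_mode)
  if (nrow(candidates) < 2)
    stopf("only %d candidate pairs from the wavelet stage", nrow(candidates))

  # --- genetic-algorithm selection ---------------------------------------
  features <- pair_feature_values(cal$matrix, candidates)
  ga_cfg <- config$ga
  ga_cfg$seed <- stage_seed(config$seed, 6)
  ga <- run_ga(features, labels, ga_cfg)
  if (!nrow(ga$selected_pairs))
    stopf("GA selected no pairs above the fitness cutoff")

  # --- final classifier ---------------------------------------------------
  sel_features <- pair_feature_values(cal$matrix, ga$selected_pairs)
  split <- split_half(labels, stage_seed(config$seed, 7))
  train_f <- sel_features[, split$train, drop = FALSE]
  test_f <- sel_features[, split$test, drop = FALSE]
  best_cfg <- grid_search(train_f, labels[split$train],
                          activations = config$nn_activations,
                          hidden_grid = config$nn_hidden_grid,
                          learning_rates = config$nn_learning_rates,
                          epochs = config$nn_grid_epochs,
                          seed = stage_seed(config$seed, 8))
  final_cfg <- nn_config(best_cfg$activation, best_cfg$hidden_sizes,
                         best_cfg$learning_rate, epochs = config$nn_epochs,
                         seed = stage_seed(config$seed, 9))
  model <- train_nn(train_f, labels[split$train], final_cfg)
  roc_train <- roc_auc(predict_nn(model, train_f), labels[split$train])
  roc_test <- roc_auc(predict_nn(model, test_f), labels[split$test])

  report <- list(
    seed = config$seed,
    n_samples = ncol(matrix), n_genes = nrow(matrix),
    n_genes_calibrated = nrow(cal$matrix),
    n_degs = nrow(degs),
    n_degs_up = sum(degs$direction == "up"),
    n_degs_down = sum(degs$direction == "down"),
    pca_elbow_k = pca$elbow_k,
    chosen_k = clusters$chosen_k,
    network_nodes = length(network$nodes),
    network_edges = nrow(network$edges),
    n_candidate_pairs = nrow(candidates),
    n_selected_pairs = nrow(ga$selected_pairs),
    selected_pairs = ga$selected_pairs,
    best_nn = list(activation = final_cfg$activation,
                   hidden_sizes = final_cfg$hidden_sizes,
                   learning_rate = final_cfg$learning_rate),
    train_accuracy = roc_train$accuracy, train_auc = roc_train$auc,
    test_accuracy = roc_test$accuracy, test_auc = roc_test$auc)

  result <- structure(
    list(matrix = matrix, labels = labels, truth = truth,
         calibrated = cal, de = de, degs = degs, pca = pca,
         clusters = clusters, network = network, degrees = degrees,
         tracks = tracks, candidates = candidates, ga = ga,
         split = split, model = model, roc_train = roc_train,
         roc_test = roc_test, report = report),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_deg_tsv(degs, file.path(out_dir, "degs.tsv"))
    write_cluster_tsv(clusters, file.path(out_dir, "gene_clusters.tsv"))
    write_network_tsv(network, file.path(out_dir, "network_edges.tsv"))
    utils::write.table(candidates, file.path(out_dir, "candidate_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ga$selected_pairs,
                       file.path(out_dir, "selected_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pairwave pipeline result\n")
  cat(sprintf("  samples: %d   genes: %d (calibrated %d)\n",
              r$n_samples, r$n_genes, r$n_genes_calibrated))
  cat(sprintf("  DEGs: %d (%d up / %d down)\n",
              r$n_degs, r$n_degs_up, r$n_degs_down))
  cat(sprintf("  gene clusters: %d (scree elbow at %s)\n",
              r$chosen_k, r$pca_elbow_k))
  cat(sprintf("  network: %d nodes / %d edges (|r| > %.2f)\n",
              r$network_nodes, r$network_edges, x$network$r_min))
  cat(sprintf("  candidate pairs: %d   selected: %d\n",
              r$n_candidate_pairs, r$n_selected_pairs))
  cat(sprintf("  NN (%s, %s, lr %.3g): train acc %.3f / AUC %.3f, test acc %.3f / AUC %.3f\n",
              r$best_nn$activation,
              paste(r$best_nn$hidden_sizes, collapse = "-"),
              r$best_nn$learning_rate,
              r$train_accuracy, r$train_auc, r$test_accuracy, r$test_auc))
  invisible(x)
}
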