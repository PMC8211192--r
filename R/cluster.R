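#' Hierarchical clustering of samples by correlation distance
#'
#' Clusters samples with average linkage on the distance
#' `d(s, t) = 1 - cor(s, t)` computed over a gene subset (Pearson). Samples
#' with zero variance over the subset have undefined correlation and are
#' excluded with a warning.
#'
#' @param matrix An [expression_matrix()].
#' @param genes Gene ids defining the profile (default: all genes).
#' @return An [stats::hclust] tree over the (retained) samples; cut with
#'   [stats::cutree()].
#' @export
hierarchical_cluster_samples <- function(matrix, genes = rownames(matrix)) {
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stopf("genes absent from matrix: %s", paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < 2) stopf("need >= 2 genes")
  sub <- matrix[genes, , drop = FALSE]
  v <- apply(sub, 2, stats::var)
  if (any(v == 0)) {
    warnf("excluding %d constant-profile sample(s): %s", sum(v == 0),
          paste(utils::head(colnames(sub)[v == 0], 5), collapse = ", "))
    sub <- sub[, v > 0, drop = FALSE]
  }
  if (ncol(sub) < 2) stopf("need >= 2 samples with non-constant profiles")
  d <- stats::as.dist(1 - stats::cor(sub))
  stats::hclust(d, method = "average")
}

#' PCA of genes over samples
#'
#' Treats genes as observations and samples as variables: the covariance of
#' the column-centred matrix is eigen-decomposed and genes are projected
#' onto the components. Eigenvalues are the component variances
#' (non-negative, non-increasing) and sum to the total variance.
#'
#' @param matrix An [expression_matrix()] (rows = genes = observations).
#' @return A list of class `pca_result` with `eigenvalues`, `scores`
#'   (genes x components), `rotation`, and `elbow_k` from [select_elbow()]
#'   (NA when fewer than 3 components).
#' @export
pca_scree <- function(matrix) {
  if (nrow(matrix) < 2) stopf("need >= 2 observations (genes)")
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, scores = pc$x, rotation = pc$rotation,
                 elbow_k = if (length(ev) >= 3) select_elbow(ev) else NA_integer_),
            class = "pca_result")
}

#' Scree elbow by maximum second difference
#'
#' Picks the component index where the decay rate of the eigenvalue curve
#' changes most sharply: the `k` (2 <= k <= length - 1) maximizing the
#' discrete second difference `ev[k-1] - 2*ev[k] + ev[k+1]`. Ties take the
#' smallest `k`.
#'
#' @param eigenvalues Numeric vector sorted non-increasing, length >= 3.
#' @return The elbow index (integer).
#' @export
select_elbow <- function(eigenvalues) {
  if (length(eigenvalues) < 3) stopf("need >= 3 eigenvalues")
  n <- length(eigenvalues)
  k <- 2:(n - 1)
  d2 <- eigenvalues[k - 1] - 2 * eigenvalues[k] + eigenvalues[k + 1]
  k[which.max(d2)]   # which.max takes the first (smallest k) on ties
}

#' Gaussian-mixture clustering of component scores with BIC selection
#'
#' Fits Gaussian mixtures with full (ellipsoidal, varying) covariance per
#' component over a range of cluster counts, scores each by
#' `BIC = 2*loglik - n_params*log(n)` (larger is better), selects the
#' arg-max `k`, and assigns each gene to its maximum-posterior component.
#' Model fitting is delegated to the `mclust` EM implementation
#' (model `"VVV"`; one-dimensional scores use `"V"`), whose
#' hierarchical-agglomeration initialization makes the fit deterministic.
#'
#' @param scores Numeric matrix (genes x components) or vector.
#' @param k_range Candidate cluster counts (default `1:9`).
#' @return A list of class `cluster_assignment` with `cluster_of` (named
#'   integer vector), `chosen_k`, and `bic_by_k` (named numeric; `NA` where
#'   the fit failed).
#' @export
gmm_cluster_bic <- function(scores, k_range = 1:9) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1,
                                             dimnames = list(names(scores), NULL))
  if (!length(k_range)) stopf("'k_range' must be non-empty")
  if (nrow(scores) <= max(k_range))
    stopf("need more observations than max(k_range)")
  model <- if (ncol(scores) == 1) "V" else "VVV"
  fit <- mclust::Mclust(scores, G = k_range, modelNames = model,
                        verbose = FALSE)
  if (is.null(fit)) stopf("EM failed for every candidate k")
  bic <- fit$BIC[, 1]
  names(bic) <- rownames(fit$BIC)
  cluster_of <- stats::setNames(as.integer(fit$classification),
                                rownames(scores))
  structure(list(cluster_of = cluster_of, chosen_k = fit$G,
                 bic_by_k = bic),
            class = "cluster_assignment")
}

#' Write a gene cluster table to TSV
#' @param assignment A `cluster_assignment` from [gmm_cluster_bic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(assignment, path) {
  utils::write.table(
    data.frame(gene_id = names(assignment$cluster_of),
               cluster = unname(assignment$cluster_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
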