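#' All-pairs Pearson correlations over a gene subset
#'
#' Computes Pearson r and the two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom for
#' every unordered gene pair. Genes with zero variance across samples have
#' undefined correlation and are excluded with a warning. No filtering and
#' no multiple-testing correction is applied here.
#'
#' @param matrix An [expression_matrix()].
#' @param genes Gene ids to correlate (default: all genes).
#' @return A data frame `gene_a`, `gene_b` (with `gene_a < gene_b`), `r`,
#'   `p_value`, `sign` (`"positive"`/`"negative"`).
#' @export
pairwise_correlations <- function(matrix, genes = rownames(matrix)) {
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stopf("genes absent from matrix: %s", paste(utils::head(missing, 5), collapse = ", "))
  if (ncol(matrix) < 3) stopf("need >= 3 samples for correlation p-values")
  sub <- t(matrix[genes, , drop = FALSE])
  v <- apply(sub, 2, stats::var)
  if (any(v == 0)) {
    warnf("excluding %d constant gene(s): %s", sum(v == 0),
          paste(utils::head(colnames(sub)[v == 0], 5), collapse = ", "))
    sub <- sub[, v > 0, drop = FALSE]
  }
  if (ncol(sub) < 2) stopf("need >= 2 non-constant genes")
  cm <- stats::cor(sub)
  n <- nrow(sub)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  a <- colnames(sub)[idx[, 1]]
  b <- colnames(sub)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r <- cm[idx]
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(r) == 1] <- 0
  out <- data.frame(gene_a = a, gene_b = b, r = r, p_value = p,
                    sign = ifelse(r > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Threshold correlation edges into a co-expression network
#'
#' Keeps edges with `|r| > r_min` (strict) and `p_value < p_max`; network
#' nodes are the genes incident to at least one kept edge. The default
#' `r_min = 0.8` is the strict hub-defining threshold; `0.5` is the
#' conventional screening value.
#'
#' @param edges Data frame from [pairwise_correlations()].
#' @param r_min Absolute-correlation threshold in (0, 1).
#' @param p_max Significance threshold (default 0.05).
#' @return A list of class `coexpr_network` with `nodes`, `edges`,
#'   `r_min`, `p_max`.
#' @export
build_network <- function(edges, r_min = 0.8, p_max = 0.05) {
  r_min <- check_scalar(r_min, "r_min")
  if (r_min <= 0 || r_min >= 1) stopf("'r_min' must be in (0, 1)")
  keep <- abs(edges$r) > r_min & edges$p_value < p_max
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(nodes = sort(unique(c(kept$gene_a, kept$gene_b))),
                 edges = kept, r_min = r_min, p_max = p_max),
            class = "coexpr_network")
}

#' Node degrees of a co-expression network
#'
#' @param network A `coexpr_network` from [build_network()].
#' @return Named integer vector of degrees (nodes only; genes absent from
#'   the network implicitly have degree 0 — see [gene_degrees()]).
#' @export
node_degrees <- function(network) {
  tab <- table(c(network$edges$gene_a, network$edges$gene_b))
  stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
}

#' Degrees for an explicit gene universe
#'
#' Degrees from [node_degrees()] extended with 0 for listed genes that are
#' absent from the network; this is the ordering key for track building.
#'
#' @param network A `coexpr_network`.
#' @param genes Gene universe.
#' @return Named integer vector over `genes`.
#' @export
gene_degrees <- function(network, genes) {
  deg <- stats::setNames(integer(length(genes)), genes)
  nd <- node_degrees(network)
  hit <- intersect(names(nd), genes)
  deg[hit] <- nd[hit]
  deg
}

#' Summary of the log2 degree distribution
#'
#' @param network A `coexpr_network`.
#' @return Data frame `degree`, `log2_degree`, `count` over observed
#'   degrees.
#' @export
degree_distribution <- function(network) {
  deg <- node_degrees(network)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)),
             log2_degree = log2(as.integer(names(tab))),
             count = as.integer(tab))
}

#' Write a network edge list to TSV
#' @param network A `coexpr_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
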