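#' Moderated two-group differential expression test
#'
#' For every gene, computes the case-minus-control mean difference (logFC on
#' log2-scale input) and a two-sided moderated t-test. The per-gene pooled
#' variance `s^2` (pooled over both groups, `df = n1 + n2 - 2`) is shrunk
#' toward the across-gene average variance `s0^2` with a fixed prior weight
#' of `d0` pseudo-degrees of freedom:
#' `s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df)`,
#' and the statistic `t = logFC / (s_tilde * sqrt(1/n1 + 1/n0))` is referred
#' to a t distribution with `df + d0` degrees of freedom. `d0 = 0` gives the
#' ordinary pooled-variance two-sample t-test. A zero statistic (e.g. a gene
#' identical in both groups) gets `p = 1` by convention.
#'
#' When `raw` is supplied (the uncalibrated matrix), logFC is additionally
#' recomputed on those values and reported as `logFC_raw`; downstream
#' filtering conventionally uses the raw-scale fold change, since a log2
#' fold-change threshold is an expression-scale quantity while the test runs
#' on the calibrated values.
#'
#' @param matrix An [expression_matrix()] (typically calibrated).
#' @param labels [sample_labels()] for all samples.
#' @param raw Optional uncalibrated matrix with the same genes, used only to
#'   report `logFC_raw`.
#' @param d0 Prior degrees of freedom for variance shrinkage (default 4).
#' @return A data frame with one row per gene: `gene_id`, `logFC`,
#'   `logFC_raw` (NA when `raw` is absent), `t`, `p_value`, `direction`
#'   (all `"none"` until filtered).
#' @export
differential_expression <- function(matrix, labels, raw = NULL, d0 = 4) {
  labels <- align_labels(matrix, labels)
  case <- names(labels)[labels == "case"]
  ctrl <- names(labels)[labels == "control"]
  if (length(case) < 2 || length(ctrl) < 2)
    stopf("need >= 2 samples per group (case %d, control %d)",
          length(case), length(ctrl))
  d0 <- check_scalar(d0, "d0", min = 0)
  n1 <- length(case); n0 <- length(ctrl)
  m1 <- rowMeans(matrix[, case, drop = FALSE])
  m0 <- rowMeans(matrix[, ctrl, drop = FALSE])
  v1 <- apply(matrix[, case, drop = FALSE], 1, stats::var)
  v0 <- apply(matrix[, ctrl, drop = FALSE], 1, stats::var)
  df <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  s0_sq <- mean(s2)
  s_tilde <- sqrt((d0 * s0_sq + df * s2) / (d0 + df))
  logfc <- m1 - m0
  se <- s_tilde * sqrt(1 / n1 + 1 / n0)
  t_stat <- ifelse(logfc == 0, 0, logfc / se)
  p <- ifelse(t_stat == 0, 1, 2 * stats::pt(-abs(t_stat), df = df + d0))
  logfc_raw <- rep(NA_real_, nrow(matrix))
  if (!is.null(raw)) {
    missing <- setdiff(rownames(matrix), rownames(raw))
    if (length(missing))
      stopf("genes absent from 'raw': %s", paste(utils::head(missing, 5), collapse = ", "))
    raw <- raw[rownames(matrix), , drop = FALSE]
    logfc_raw <- rowMeans(raw[, case, drop = FALSE]) -
      rowMeans(raw[, ctrl, drop = FALSE])
  }
  data.frame(gene_id = rownames(matrix), logFC = unname(logfc),
             logFC_raw = unname(logfc_raw), t = unname(t_stat),
             p_value = unname(p), direction = "none",
             stringsAsFactors = FALSE)
}

#' Filter differential-expression records
#'
#' Keeps genes with `p_value < p_max` and `|logFC| > lfc_min` (both strict),
#' sets `direction` from the sign of the fold change, and sorts by p
#' ascending, ties by |logFC| descending, then gene id. When `logFC_raw` is
#' available it is the filtered quantity (see
#' [differential_expression()]); otherwise the calibrated-scale `logFC` is
#' used.
#'
#' @param records Data frame from [differential_expression()].
#' @param p_max Significance threshold (default 0.01).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @return The filtered, sorted data frame with `direction` set to
#'   `"up"`/`"down"`.
#' @export
filter_degs <- function(records, p_max = 0.01, lfc_min = 1) {
  p_max <- check_scalar(p_max, "p_max", min = 0)
  lfc_min <- check_scalar(lfc_min, "lfc_min", min = 0)
  if (p_max <= 0 || lfc_min <= 0) stopf("thresholds must be > 0")
  lfc <- if ("logFC_raw" %in% names(records) && !all(is.na(records$logFC_raw)))
    records$logFC_raw else records$logFC
  keep <- records$p_value < p_max & abs(lfc) > lfc_min
  out <- records[keep, , drop = FALSE]
  lfc <- lfc[keep]
  out$direction <- ifelse(lfc > 0, "up", "down")
  ord <- order(out$p_value, -abs(lfc), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a DEG table to TSV
#' @param records DEG data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
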