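#' Construct a validated expression matrix
#'
#' The central container of the package: a numeric genes x samples matrix of
#' log2-scale expression values with unique gene and sample identifiers.
#' Represented as a plain numeric matrix with `rownames` (genes),
#' `colnames` (samples) and a `calibrated` attribute recording whether
#' values have been standardized against the control group.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: existing rownames).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: existing colnames).
#' @param calibrated Logical flag, `TRUE` once values are control-group
#'   z-scores.
#' @return A numeric matrix with dimnames and a `calibrated` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              calibrated = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stopf("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stopf("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stopf("duplicated gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stopf("duplicated sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stopf("expression values must all be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "calibrated") <- isTRUE(calibrated)
  values
}

#' Is the matrix calibrated?
#' @param matrix An expression matrix.
#' @return Logical.
#' @export
is_calibrated <- function(matrix) isTRUE(attr(matrix, "calibrated"))

#' Construct sample group labels
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param group Character/factor vector with values `"case"` or `"control"`.
#' @return A factor with levels `control`, `case`, named by sample id.
#' @export
sample_labels <- function(sample_ids, group) {
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (length(sample_ids) != length(group))
    stopf("'sample_ids' and 'group' must have equal length")
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids in labels")
  if (!all(group %in% c("case", "control")))
    stopf("groups must be 'case' or 'control'")
  structure(factor(group, levels = c("control", "case")),
            names = sample_ids)
}

# Labels restricted and ordered to the matrix columns; errors on missing.
align_labels <- function(matrix, labels) {
  ids <- colnames(matrix)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stopf("samples missing from labels: %s", paste(missing, collapse = ", "))
  labels[ids]
}

#' Read an expression matrix from TSV
#'
#' Expected layout: a header row of sample ids, first column `gene_id`,
#' numeric body. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stopf("'%s': need a header and at least one gene row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1]])
  widths <- lengths(fields)
  if (any(widths != ncol_expected))
    stopf("'%s': ragged rows (line %d has %d fields, expected %d)",
          path, which(widths != ncol_expected)[1],
          widths[widths != ncol_expected][1], ncol_expected)
  sample_ids <- fields[[1]][-1]
  gene_ids <- vapply(fields[-1], `[[`, character(1), 1)
  body <- vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stopf("'%s': non-numeric cell in row '%s'", path, f[[1]])
    v
  }, numeric(length(sample_ids)))
  values <- if (is.matrix(body)) t(body) else matrix(body, ncol = 1)
  expression_matrix(values, gene_ids, sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]; `read(write(x))` reproduces `x`
#' up to numeric printing precision (15 significant digits are written).
#'
#' @param matrix An expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  header <- paste(c("gene_id", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            formatC(matrix[i, ], format = "g", digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read sample labels from TSV
#'
#' Columns `sample_id` and `group` (values `case`/`control`).
#'
#' @param path Path to a tab-separated file.
#' @return A [sample_labels()] factor.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stopf("'%s': expected columns sample_id, group", path)
  sample_labels(df$sample_id, df$group)
}

#' Write sample labels to TSV
#' @param labels A [sample_labels()] factor.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Convenience reader for the Series Matrix dialect: metadata lines start
#' with `!` and the expression table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Only the
#' table block is parsed; fields may be quoted.
#'
#' @param path Path to a series matrix text file (uncompressed).
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stopf("'%s': series matrix table delimiters absent or empty", path)
  block <- lines[(begin + 1):(end - 1)]
  strip <- function(x) gsub('^"|"$', "", x)
  fields <- lapply(strsplit(block, "\t", fixed = TRUE),
                   function(f) strip(f))
  sample_ids <- fields[[1]][-1]
  gene_ids <- vapply(fields[-1], `[[`, character(1), 1)
  body <- vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stopf("'%s': non-numeric cell in row '%s'", path, f[[1]])
    v
  }, numeric(length(sample_ids)))
  values <- if (is.matrix(body)) t(body) else matrix(body, ncol = 1)
  expression_matrix(values, gene_ids, sample_ids)
}

#' Calibrate expression values against the control group
#'
#' Standardizes every gene by the mean and standard deviation of its
#' expression in the control samples only, so that all genes live on a
#' common distributional scale anchored at the control population:
#' `z = (x - mu_ctrl) / sd_ctrl`. The SD uses the sample (n-1) denominator.
#' Genes whose control values are constant have an undefined z-score and
#' are dropped with a warning.
#'
#' @param matrix An uncalibrated [expression_matrix()].
#' @param labels [sample_labels()] covering all samples.
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{the calibrated expression matrix (`calibrated = TRUE`)}
#'     \item{params}{data frame `gene_id`, `mu`, `sd` of the control-group
#'       parameters for the retained genes}
#'     \item{dropped}{character vector of gene ids dropped for zero control
#'       variance}
#'   }
#' @export
zscore_calibrate <- function(matrix, labels) {
  if (is_calibrated(matrix)) stopf("matrix is already calibrated")
  labels <- align_labels(matrix, labels)
  ctrl <- names(labels)[labels == "control"]
  if (length(ctrl) < 2)
    stopf("need >= 2 control samples to calibrate (got %d)", length(ctrl))
  ctrl_vals <- matrix[, ctrl, drop = FALSE]
  mu <- rowMeans(ctrl_vals)
  sd <- apply(ctrl_vals, 1, stats::sd)
  keep <- sd > 0
  dropped <- rownames(matrix)[!keep]
  if (length(dropped))
    warnf("dropping %d gene(s) with zero control variance: %s",
          length(dropped), paste(utils::head(dropped, 5), collapse = ", "))
  z <- (matrix[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  out <- expression_matrix(z, rownames(matrix)[keep], colnames(matrix),
                           calibrated = TRUE)
  list(matrix = out,
       params = data.frame(gene_id = rownames(matrix)[keep],
                           mu = unname(mu[keep]), sd = unname(sd[keep]),
                           stringsAsFactors = FALSE),
       dropped = dropped)
}
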