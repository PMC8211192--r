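#' Build ordered gene tracks for wavelet analysis
#'
#' Splits filtered DEGs by direction (up/down) and orders each track so
#' that neighbouring genes are comparable: genes are grouped contiguously
#' by cluster index (ascending), within a cluster sorted by co-expression
#' network degree ascending, ties broken lexicographically by gene id.
#' Adjacent genes then have similar regulatory importance, so a sharp
#' change in the group-mean signal flags a biologically interesting pair.
#'
#' @param deg_records Filtered DEG data frame (see [filter_degs()]).
#' @param cluster_of Named integer vector mapping gene id to cluster.
#' @param degrees Named integer vector of network degrees (0 for genes
#'   absent from the network), covering all DEGs.
#' @return A list with elements `up` and `down`, each a list of class
#'   `gene_track` with `direction`, `ordered_genes` and `boundary_after`
#'   (positions i such that genes i and i+1 belong to different clusters);
#'   a direction with no genes yields `NULL` with a warning.
#' @export
build_tracks <- function(deg_records, cluster_of, degrees) {
  make_track <- function(genes, direction) {
    if (!length(genes)) {
      warnf("no %s-regulated genes; track skipped", direction)
      return(NULL)
    }
    missing <- setdiff(genes, names(cluster_of))
    if (length(missing))
      stopf("genes without cluster assignment: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    cl <- cluster_of[genes]
    dg <- degrees[genes]
    dg[is.na(dg)] <- 0L
    ord <- order(cl, dg, genes)
    genes <- genes[ord]
    cl <- cl[ord]
    structure(list(direction = direction, ordered_genes = unname(genes),
                   boundary_after = unname(which(diff(cl) != 0))),
              class = "gene_track")
  }
  list(up = make_track(deg_records$gene_id[deg_records$direction == "up"], "up"),
       down = make_track(deg_records$gene_id[deg_records$direction == "down"], "down"))
}

#' Per-gene group-mean signal along a track
#'
#' @param matrix A calibrated [expression_matrix()].
#' @param labels [sample_labels()].
#' @param track A `gene_track` from [build_tracks()].
#' @param group `"case"` or `"control"`.
#' @return Numeric vector aligned to `track$ordered_genes`.
#' @export
group_mean_signal <- function(matrix, labels, track, group = c("case", "control")) {
  group <- match.arg(group)
  labels <- align_labels(matrix, labels)
  missing <- setdiff(track$ordered_genes, rownames(matrix))
  if (length(missing))
    stopf("track genes absent from matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  cols <- names(labels)[labels == group]
  rowMeans(matrix[track$ordered_genes, cols, drop = FALSE])
}

#' First difference of a signal
#'
#' `out[i] = signal[i + 1] - signal[i]`; position i of the output indexes
#' the adjacent pair (gene i, gene i+1) of the originating track.
#'
#' @param signal Numeric vector, length >= 2.
#' @return Numeric vector of length `length(signal) - 1`.
#' @export
adjacent_difference <- function(signal) {
  if (length(signal) < 2) stopf("need a signal of length >= 2")
  diff(signal)
}

#' Centred moving average (valid mode)
#'
#' Output position j is the mean of input positions `j .. j + window - 1`;
#' the centre of that window is `j + (window - 1) / 2`, the offset needed
#' to map smoothed positions back to input positions.
#'
#' @param signal Numeric vector.
#' @param window Odd window size, `1 <= window <= length(signal)`.
#' @return Numeric vector of length `length(signal) - window + 1` with
#'   attribute `offset = (window - 1) / 2`.
#' @export
moving_average <- function(signal, window = 3) {
  window <- check_count(window, "window", min = 1)
  if (window %% 2 == 0) stopf("'window' must be odd")
  if (window > length(signal)) stopf("'window' exceeds signal length")
  n_out <- length(signal) - window + 1
  out <- as.numeric(stats::filter(signal, rep(1 / window, window),
                                  sides = 2))[(window - 1) / 2 + seq_len(n_out)]
  attr(out, "offset") <- (window - 1L) %/% 2L
  out
}

#' Sampled Ricker (Mexican-hat) wavelet
#'
#' `psi(t) = 2 / (sqrt(3a) * pi^(1/4)) * (1 - (t/a)^2) * exp(-t^2 / (2a^2))`
#' sampled at integer offsets `-floor(5a) .. floor(5a)` (the kernel is
#' negligible beyond five scale widths).
#'
#' @param scale Positive scale `a`.
#' @return Numeric kernel with attribute `half_width`.
#' @export
ricker_kernel <- function(scale) {
  scale <- check_scalar(scale, "scale")
  if (scale <= 0) stopf("'scale' must be > 0")
  hw <- max(1L, as.integer(floor(5 * scale)))
  t <- seq(-hw, hw)
  a <- 2 / (sqrt(3 * scale) * pi^0.25)
  psi <- a * (1 - (t / scale)^2) * exp(-t^2 / (2 * scale^2))
  attr(psi, "half_width") <- hw
  psi
}

#' Continuous wavelet transform with the Ricker mother wavelet
#'
#' `coefficients[s, t] = sum_u signal[u] * psi_s(u - t)` with zero-padded
#' boundaries: the correlation of the signal with the scaled wavelet
#' centred at each position (the wavelet is symmetric, so correlation and
#' convolution coincide).
#'
#' @param signal Numeric vector, length >= 4.
#' @param scales Positive scales (default `c(1, 2, 4)`).
#' @return A scales x positions numeric matrix, rownames = scales.
#' @export
cwt_transform <- function(signal, scales = c(1, 2, 4)) {
  if (length(signal) < 4) stopf("need a signal of length >= 4")
  if (!length(scales)) stopf("'scales' must be non-empty")
  n <- length(signal)
  out <- matrix(0, length(scales), n,
                dimnames = list(as.character(scales), NULL))
  for (i in seq_along(scales)) {
    psi <- ricker_kernel(scales[i])
    hw <- attr(psi, "half_width")
    padded <- c(numeric(hw), signal, numeric(hw))
    # filter() computes sum_k padded[t + k] * psi[hw + 1 + k]: correlation
    conv <- stats::filter(padded, psi, method = "convolution", sides = 2)
    out[i, ] <- as.numeric(conv[hw + seq_len(n)])
  }
  out
}

#' Detect significant peaks in wavelet coefficients
#'
#' Collapses the coefficient matrix to the per-position score
#' `max over scales of |coefficient|`, sets the threshold to
#' `mean(score) + c_sd * sd(score)` (or an absolute value when supplied),
#' and returns local maxima strictly above the threshold. A plateau
#' contributes its leftmost position.
#'
#' @param coefficients Matrix from [cwt_transform()] (or a numeric vector
#'   of ready-made scores).
#' @param c_sd Multiplier of the score SD in the threshold rule (default 2).
#' @param threshold Absolute threshold overriding the mean + c_sd * SD rule.
#' @param min_threshold Numerical floor of the threshold (default 1e-8):
#'   a signal that is zero up to floating-point residue (e.g. the
#'   control-group track of a control-calibrated matrix) yields no peaks.
#' @return A list with `threshold`, `scores`, and `peaks` (increasing
#'   integer positions).
#' @export
detect_peaks <- function(coefficients, c_sd = 2, threshold = NULL,
                         min_threshold = 1e-8) {
  scores <- if (is.matrix(coefficients))
    apply(abs(coefficients), 2, max) else abs(coefficients)
  if (!length(scores)) stopf("empty coefficients")
  if (is.null(threshold))
    threshold <- max(mean(scores) + c_sd * stats::sd(scores), min_threshold)
  n <- length(scores)
  ext <- c(-Inf, scores, -Inf)
  peaks <- integer(0)
  i <- 2
  while (i <= n + 1) {
    j <- i
    while (j < n + 1 && ext[j + 1] == ext[i]) j <- j + 1   # plateau run
    if (ext[i] > ext[i - 1] && ext[i] > ext[j + 1] && ext[i] > threshold)
      peaks <- c(peaks, i - 1L)                            # leftmost of run
    i <- j + 1
  }
  list(threshold = threshold, scores = unname(scores), peaks = peaks)
}

#' Map smoothed-signal peaks to adjacent gene pairs
#'
#' A peak at smoothed position j sits at difference-signal position
#' `j + ma_offset`, which names the adjacent pair (gene at that position,
#' its successor) of the track. Pairs spanning a cluster boundary are
#' artifacts of track concatenation and are dropped.
#'
#' @param peaks Integer positions from [detect_peaks()].
#' @param track The `gene_track` the signal came from.
#' @param ma_offset Offset recorded by [moving_average()] (0 if the
#'   difference signal was not smoothed).
#' @param scores Optional per-position scores used to report peak
#'   magnitudes.
#' @return Data frame `gene_low`, `gene_high`, `pair_index`,
#'   `peak_magnitude`.
#' @export
peaks_to_pairs <- function(peaks, track, ma_offset = 0, scores = NULL) {
  pos <- peaks + ma_offset
  n_pairs <- length(track$ordered_genes) - 1
  if (any(pos < 1 | pos > n_pairs)) stopf("peak position out of range")
  keep <- !(pos %in% track$boundary_after)
  data.frame(gene_low = track$ordered_genes[pos[keep]],
             gene_high = track$ordered_genes[pos[keep] + 1],
             pair_index = pos[keep],
             peak_magnitude = if (is.null(scores)) rep(NA_real_, sum(keep))
                              else scores[peaks[keep]],
             stringsAsFactors = FALSE)
}

#' Candidate gene pairs from the four track/group wavelet analyses
#'
#' Runs the full per-track procedure — group-mean signal, first difference,
#' moving average, Ricker CWT, peak detection — for every combination of
#' direction track (up/down) and sample group (case/control), and pools
#' the adjacent pairs under the significant peaks. A pair flagged in any
#' of the four analyses is a candidate (`mode = "any"`); `mode = "all"`
#' requires every available track/group analysis containing the pair's
#' track to flag it. Duplicates keep the largest peak magnitude.
#'
#' The default window of 1 applies no smoothing: an adjacent gene pair is a
#' single-position spike in the difference signal, and the scale-1 Ricker
#' kernel is then close to a matched filter for it, whereas a centred
#' moving average cancels the spike's centre exactly (the window-3 average
#' of the difference pattern `(+u, -(u+w), +w)` is zero at the pair
#' position). Wider windows remain available for tracks with correlated
#' position-to-position noise.
#'
#' @param matrix Calibrated [expression_matrix()].
#' @param labels [sample_labels()].
#' @param tracks List from [build_tracks()].
#' @param window Moving-average window (odd, default 1 = no smoothing).
#' @param scales CWT scales (default `c(1, 2, 4)`).
#' @param c_sd Peak threshold multiplier (default 2).
#' @param mode `"any"` (default) or `"all"`.
#' @return Data frame `gene_low`, `gene_high`, `track_direction`,
#'   `track_group`, `peak_magnitude`, sorted by magnitude descending, with
#'   attribute `analyses` holding the per-track signals, coefficients and
#'   thresholds.
#' @export
wavelet_candidate_pairs <- function(matrix, labels, tracks, window = 1,
                                    scales = c(1, 2, 4), c_sd = 2,
                                    mode = c("any", "all")) {
  mode <- match.arg(mode)
  found <- list()
  analyses <- list()
  n_groups_by_dir <- c(up = 0L, down = 0L)
  for (direction in c("up", "down")) {
    track <- tracks[[direction]]
    if (is.null(track) || length(track$ordered_genes) < window + 4) next
    for (group in c("case", "control")) {
      sig <- group_mean_signal(matrix, labels, track, group)
      d <- adjacent_difference(sig)
      sm <- moving_average(d, window)
      coef <- cwt_transform(sm, scales)
      pk <- detect_peaks(coef, c_sd)
      pairs <- peaks_to_pairs(pk$peaks, track, attr(sm, "offset"), pk$scores)
      if (nrow(pairs)) {
        pairs$track_direction <- direction
        pairs$track_group <- group
        found[[paste(direction, group)]] <- pairs
      }
      n_groups_by_dir[direction] <- n_groups_by_dir[direction] + 1L
      analyses[[paste(direction, group, sep = "_")]] <-
        list(signal = sig, difference = d, smoothed = sm,
             coefficients = coef, threshold = pk$threshold,
             peaks = pk$peaks)
    }
  }
  if (!length(found)) {
    out <- data.frame(gene_low = character(0), gene_high = character(0),
                      track_direction = character(0),
                      track_group = character(0),
                      peak_magnitude = numeric(0), stringsAsFactors = FALSE)
    attr(out, "analyses") <- analyses
    return(out)
  }
  all_pairs <- do.call(rbind, found)
  key <- paste(all_pairs$gene_low, all_pairs$gene_high)
  if (mode == "all") {
    need <- n_groups_by_dir[all_pairs$track_direction]
    ok_keys <- names(which(tapply(seq_along(key), key, length) >=
                             tapply(need, key, max)))
    all_pairs <- all_pairs[key %in% ok_keys, , drop = FALSE]
    key <- paste(all_pairs$gene_low, all_pairs$gene_high)
  }
  best <- tapply(seq_len(nrow(all_pairs)), key,
                 function(ix) ix[which.max(all_pairs$peak_magnitude[ix])])
  out <- all_pairs[unlist(best), c("gene_low", "gene_high",
                                   "track_direction", "track_group",
                                   "peak_magnitude")]
  out <- out[order(-out$peak_magnitude, out$gene_low), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "analyses") <- analyses
  out
}
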