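#' Per-block cross-correlograms for all neuron pairs
#'
#' Computes, for every ordered neuron pair and every block, the Pearson
#' cross-correlogram at integer frame shifts of the per-block
#' mean-subtracted, variance-normalized traces. Entry `[i, j, l]` is the
#' correlation of `x_i(t)` with `x_j(t + lag_l)`, so positive peak lags
#' mean neuron i leads neuron j. Blocks in which a neuron has zero variance
#' contribute `NA` for its pairs.
#'
#' @param dff a `dff_traces` object.
#' @param schedule a `stim_schedule`; defaults to the one in `dff`.
#' @param max_lag_s half-width of the lag search window in seconds (wider
#'   than the edge cutoff so that out-of-window peaks can be detected and
#'   discarded).
#' @return a `block_xcorr` object: list with `lags` (frame shifts),
#'   `frame_rate_hz`, and `blocks` — one `(n, n, n_lags)` array per block.
#' @export
block_correlograms <- function(dff, schedule = dff$schedule,
                               max_lag_s = 1.5) {
  fs <- schedule$frame_rate_hz
  k <- floor(max_lag_s * fs)
  lags <- -k:k
  n <- nrow(dff$dff)

  arr_list <- vector("list", schedule$n_blocks)
  for (b in seq_len(schedule$n_blocks)) {
    x <- dff$dff[, block_frames(schedule, b), drop = FALSE]
    xs <- row_standardize(x)
    zv <- attr(xs, "zero_variance")
    tt <- ncol(xs)
    arr <- array(NA_real_, c(n, n, length(lags)))
    for (tau in 0:k) {
      cpos <- tcrossprod(xs[, seq_len(tt - tau), drop = FALSE],
                         xs[, (1 + tau):tt, drop = FALSE]) / (tt - tau - 1)
      arr[, , k + 1 + tau] <- cpos
      if (tau > 0) arr[, , k + 1 - tau] <- t(cpos)
    }
    if (any(zv)) { arr[zv, , ] <- NA_real_; arr[, zv, ] <- NA_real_ }
    arr_list[[b]] <- arr
  }
  structure(list(lags = lags, frame_rate_hz = fs, blocks = arr_list),
            class = "block_xcorr")
}

#' Edge lag and direction from block-averaged cross-correlograms
#'
#' Averages per-block correlograms (over `blocks`), finds the global peak
#' lag `t_max` for each pair, and classifies: `t_max = 0` is bidirectional,
#' `0 < |t_max| <= cutoff` frames is a directed edge from the leading to
#' the lagging neuron, and `|t_max| > cutoff` removes the edge. Ties in the
#' peak are broken toward the smaller `|lag|`, then the positive lag.
#'
#' @param xcorr a `block_xcorr` object.
#' @param blocks optional integer subset of blocks to average over.
#' @param cutoff_s maximum edge lag in seconds.
#' @return an `edge_lags` object: list of `t_max` (n x n matrix, entry
#'   `[i, j]` the peak lag of `corr(x_i(t), x_j(t + lag))`; antisymmetric),
#'   `status` (n x n character: `"bidirectional"`, `"directed"`, `"none"`),
#'   `cutoff_frames` and `frame_rate_hz`.
#' @export
edge_lag <- function(xcorr, blocks = NULL, cutoff_s = 0.5) {
  lags <- xcorr$lags
  fs <- xcorr$frame_rate_hz
  cutoff <- floor(cutoff_s * fs + 1e-9)
  if (max(lags) < cutoff) abort("search window narrower than the cutoff")
  if (is.null(blocks)) blocks <- seq_along(xcorr$blocks)

  mean_arr <- Reduce(`+`, lapply(xcorr$blocks[blocks], function(a) {
    a[is.na(a)] <- 0; a
  }))
  cnt <- Reduce(`+`, lapply(xcorr$blocks[blocks], function(a) !is.na(a)))
  mean_arr <- ifelse(cnt > 0, mean_arr / pmax(cnt, 1), NA_real_)

  n <- dim(mean_arr)[1]
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  I <- pr[, 1]; J <- pr[, 2]
  np <- length(I)
  # candidate ordering: |lag| ascending, positive before negative
  ord <- order(abs(lags), -sign(lags))
  m <- matrix(NA_real_, np, length(lags))
  for (li in seq_along(ord)) {
    m[, li] <- mean_arr[cbind(I, J, ord[li])]
  }
  all_na <- rowSums(!is.na(m)) == 0
  m[is.na(m)] <- -Inf
  best <- max.col(m, ties.method = "first")
  t_best <- lags[ord][best]
  t_best[all_na] <- NA_integer_

  status_pair <- ifelse(is.na(t_best), "none",
                 ifelse(t_best == 0, "bidirectional",
                 ifelse(abs(t_best) <= cutoff, "directed", "none")))

  t_max <- matrix(0L, n, n)
  t_max[cbind(I, J)] <- ifelse(is.na(t_best), 0L, as.integer(t_best))
  t_max[cbind(J, I)] <- -t_max[cbind(I, J)]
  status <- matrix("none", n, n)
  status[cbind(I, J)] <- status_pair
  status[cbind(J, I)] <- status_pair

  structure(list(t_max = t_max, status = status,
                 cutoff_frames = cutoff, frame_rate_hz = fs),
            class = "edge_lags")
}
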