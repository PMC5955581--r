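#' Assemble the directed functional graph
#'
#' Combines the blocked partial-correlation matrix with cross-correlogram
#' lag/direction decisions into a signed directed weight matrix: pairs with
#' peak lag beyond the cutoff get no edge (weight zero), zero-lag pairs get
#' a symmetric bidirectional edge, and otherwise a single directed edge
#' from the leading to the lagging neuron.
#'
#' @param partial_matrix symmetric matrix from [block_partial_matrix()].
#' @param lags an `edge_lags` object from [edge_lag()].
#' @param weight_floor edges with `|weight| <= weight_floor` are dropped.
#' @param positions_um optional neuron x 2 coordinates (microns).
#' @param classes optional per-neuron class labels (e.g. tuned/untuned).
#' @param frame_rate_hz imaging frame rate; defaults to the one in `lags`.
#' @param condition which frames the weights were computed on.
#' @return a `functional_graph`: list with `W` (`W[i, j]` = weight of edge
#'   i -> j), `lag_frames`, `frame_rate_hz`, `positions_um`, `classes`,
#'   `condition`.
#' @export
build_graph <- function(partial_matrix, lags, weight_floor = 0,
                        positions_um = NULL, classes = NULL,
                        frame_rate_hz = lags$frame_rate_hz,
                        condition = c("all", "grating_only", "grey_only")) {
  condition <- match.arg(condition)
  n <- nrow(partial_matrix)
  if (!all(dim(lags$t_max) == c(n, n))) abort("matrix/lag shape mismatch")

  w <- matrix(0, n, n)
  lagm <- matrix(0L, n, n)
  pr <- which(upper.tri(partial_matrix), arr.ind = TRUE)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    pc <- partial_matrix[i, j]
    st <- lags$status[i, j]
    if (is.na(pc) || st == "none" || abs(pc) <= weight_floor) next
    tm <- lags$t_max[i, j]
    if (st == "bidirectional") {
      w[i, j] <- pc; w[j, i] <- pc
    } else if (tm > 0) {                    # i leads -> edge i -> j
      w[i, j] <- pc; lagm[i, j] <- tm
    } else {                                # j leads
      w[j, i] <- pc; lagm[j, i] <- -tm
    }
  }
  structure(list(W = w, lag_frames = lagm, frame_rate_hz = frame_rate_hz,
                 positions_um = positions_um, classes = classes,
                 condition = condition),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  n <- nrow(x$W)
  npair <- n * (n - 1) / 2
  con <- connected_pairs(x$W)
  cat(sprintf("<functional_graph> %d neurons, %s frames\n", n, x$condition))
  cat(sprintf("  %d/%d pairs connected (%.1f%%), %.1f%% of those bidirectional\n",
              sum(con$any), npair, 100 * mean(con$any),
              100 * mean(con$bidir[con$any])))
  invisible(x)
}

# pair-level connectivity bookkeeping on a weight matrix
connected_pairs <- function(w) {
  ut <- upper.tri(w)
  fwd <- w[ut] != 0
  bwd <- t(w)[ut] != 0
  list(any = fwd | bwd, bidir = fwd & bwd, fwd = fwd, bwd = bwd)
}

#' @describeIn build_graph edge-list tibble (source, target, weight,
#'   lag_frames, bidirectional).
#' @param x a `functional_graph`.
#' @param ... unused.
#' @export
tidy.functional_graph <- function(x, ...) {
  idx <- which(x$W != 0, arr.ind = TRUE)
  bidir <- x$W[idx] != 0 & x$W[cbind(idx[, 2], idx[, 1])] != 0
  out <- tibble(source = idx[, 1], target = idx[, 2],
                weight = x$W[idx],
                lag_frames = x$lag_frames[idx],
                bidirectional = bidir)
  if (!is.null(x$classes)) {
    out$source_class <- x$classes[out$source]
    out$target_class <- x$classes[out$target]
  }
  arrange(out, .data$source, .data$target)
}

#' @describeIn build_graph one-row summary: density, bidirectional
#'   fraction, mean |weight|, mean |lag|.
#' @export
glance.functional_graph <- function(x, ...) {
  n <- nrow(x$W)
  con <- connected_pairs(x$W)
  e <- tidy(x)
  tibble(n_neurons = n,
         n_pairs_connected = sum(con$any),
         pair_density = mean(con$any),
         zero_edge_fraction = 1 - mean(con$any),
         ordered_density = sum(x$W != 0) / (n * (n - 1)),
         bidir_fraction = if (any(con$any)) mean(con$bidir[con$any]) else NA,
         mean_abs_weight = mean(abs(e$weight)),
         mean_abs_lag_s = mean(abs(e$lag_frames)) / x$frame_rate_hz)
}

#' Export a functional graph to GraphML
#'
#' @param g a `functional_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(g, path) {
  e <- tidy(g)
  ig <- igraph::graph_from_data_frame(
    e[, c("source", "target", "weight", "lag_frames", "bidirectional")],
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(g$W))))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

# label an unordered pair of classes, e.g. "tuned-untuned" (sorted)
pair_class <- function(ci, cj) {
  paste(pmin(ci, cj), pmax(ci, cj), sep = "-")
}

#' Graph-level spatial and threshold statistics
#'
#' Computes, over a grid of absolute-weight thresholds: connection
#' probability overall and per class pair; and over equal-width distance
#' bins: connection probability and mean |lag|, with a propagation speed
#' fitted as the inverse slope of the least-squares line of mean lag
#' (seconds) against distance (mm). Bidirectional-edge prevalence per
#' threshold is normalized by the independent-placement expectation `q^2`,
#' where `q` is the directed-edge density among ordered pairs at that
#' threshold.
#'
#' @param g a `functional_graph` with `positions_um`.
#' @param thresholds absolute-weight thresholds.
#' @param n_dist_bins number of equal-width distance bins.
#' @return list of tibbles: `density_by_threshold`, `connection_by_distance`,
#'   `lag_by_distance`, `bidir_by_threshold`, and scalar `speed_mm_s`.
#' @export
graph_stats <- function(g, thresholds = seq(0, 0.3, by = 0.05),
                        n_dist_bins = 8) {
  if (is.null(g$positions_um)) abort("graph has no positions")
  n <- nrow(g$W)
  d_um <- as.matrix(stats::dist(g$positions_um))
  ut <- upper.tri(g$W)
  dist_pair <- d_um[ut]
  wf <- g$W[ut]; wb <- t(g$W)[ut]
  cls <- if (is.null(g$classes)) rep("all", n) else g$classes
  pr <- which(ut, arr.ind = TRUE)
  pcls <- pair_class(cls[pr[, 1]], cls[pr[, 2]])

  dens <- list(); bid <- list()
  for (th in thresholds) {
    f <- abs(wf) > th; b <- abs(wb) > th
    con <- f | b
    dens[[length(dens) + 1]] <- bind_rows(
      tibble(threshold = th, class_pair = "all", p_connect = mean(con)),
      tibble(threshold = th,
             class_pair = tapply(con, pcls, mean) |> names(),
             p_connect = as.numeric(tapply(con, pcls, mean))))
    q <- (sum(f) + sum(b)) / (n * (n - 1))
    p_bidir <- mean(f & b)
    bid[[length(bid) + 1]] <- tibble(
      threshold = th,
      bidir_fraction = if (any(con)) sum(f & b) / sum(con) else NA_real_,
      p_bidir = p_bidir,
      expected_p_bidir = q^2,
      normalized_ratio = if (q > 0) p_bidir / q^2 else NA_real_)
  }

  breaks <- seq(0, max(dist_pair) + 1e-9, length.out = n_dist_bins + 1)
  bin <- cut(dist_pair, breaks, include.lowest = TRUE, labels = FALSE)
  con0 <- wf != 0 | wb != 0
  cbd <- tibble(bin = bin, dist_um = dist_pair, con = con0,
                class_pair = pcls) |>
    group_by(.data$bin, .data$class_pair) |>
    summarise(mid_um = mean(.data$dist_um), p_connect = mean(.data$con),
              n_pairs = n(), .groups = "drop")

  lag_pair_frames <- pmax(abs(g$lag_frames[ut]), abs(t(g$lag_frames)[ut]))
  lbd <- tibble(bin = bin, dist_um = dist_pair,
                lag_s = lag_pair_frames / g$frame_rate_hz,
                con = con0) |>
    filter(.data$con) |>
    group_by(.data$bin) |>
    summarise(mid_mm = mean(.data$dist_um) / 1000,
              mean_lag_s = mean(.data$lag_s), n_edges = n(),
              .groups = "drop")

  speed <- NA_real_
  if (nrow(lbd) >= 2) {
    sl <- coef(lm(mean_lag_s ~ mid_mm, data = lbd))[2]
    if (is.finite(sl) && sl > 0) speed <- 1 / sl
  }
  list(density_by_threshold = bind_rows(dens),
       connection_by_distance = cbd,
       lag_by_distance = lbd,
       bidir_by_threshold = bind_rows(bid),
       speed_mm_s = unname(speed))
}

#' Trial-response correlations per stimulus condition
#'
#' Pearson correlations between neurons' per-trial mean-response vectors,
#' separately for grating and grey trials (signal + noise mixture; no
#' shuffling), with class-pair summaries and, when preferred directions are
#' supplied, mean correlation of tuned pairs against their difference in
#' preferred direction.
#'
#' @param tr a `trial_responses` object.
#' @param classes optional per-neuron class labels.
#' @param theta_p_deg optional per-neuron preferred direction (degrees; NA
#'   for untuned neurons).
#' @param delta_bin_deg bin width for the tuning-difference summary.
#' @return list with `grating_r`, `grey_r` (matrices), `summary` (tibble:
#'   condition, class_pair, mean_r, sd_r), and `by_delta_pref` (tibble) if
#'   `theta_p_deg` given.
#' @export
condition_correlations <- function(tr, classes = NULL, theta_p_deg = NULL,
                                   delta_bin_deg = 30) {
  meta <- tr$meta
  out <- list()
  for (kd in c("grating", "grey")) {
    cols <- which(meta$kind == kd)
    if (length(cols) < 10) abort("need >= 10 trials per condition")
    x <- tr$responses[, cols, drop = FALSE]
    sds <- apply(x, 1, sd)
    r <- suppressWarnings(cor(t(x)))
    r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
    diag(r) <- 1
    out[[paste0(kd, "_r")]] <- r
  }

  n <- nrow(tr$responses)
  cls <- if (is.null(classes)) rep("all", n) else classes
  ut <- upper.tri(out$grating_r)
  pr <- which(ut, arr.ind = TRUE)
  pcls <- pair_class(cls[pr[, 1]], cls[pr[, 2]])
  summ <- bind_rows(lapply(c("grating", "grey"), function(kd) {
    rv <- out[[paste0(kd, "_r")]][ut]
    tibble(condition = kd, class_pair = names(tapply(rv, pcls, mean)),
           mean_r = as.numeric(tapply(rv, pcls, mean, na.rm = TRUE)),
           sd_r = as.numeric(tapply(rv, pcls, sd, na.rm = TRUE)))
  }))
  out$summary <- summ

  if (!is.null(theta_p_deg)) {
    both <- !is.na(theta_p_deg[pr[, 1]]) & !is.na(theta_p_deg[pr[, 2]])
    dp <- abs(wrap_180(theta_p_deg[pr[, 1]] - theta_p_deg[pr[, 2]]))
    bins <- cut(dp, seq(0, 180, by = delta_bin_deg), include.lowest = TRUE)
    out$by_delta_pref <- bind_rows(lapply(c("grating", "grey"), function(kd) {
      rv <- out[[paste0(kd, "_r")]][ut]
      tibble(condition = kd, delta_pref = bins, r = rv, keep = both) |>
        filter(.data$keep) |>
        group_by(.data$condition, .data$delta_pref) |>
        summarise(mean_r = mean(.data$r, na.rm = TRUE), n_pairs = n(),
                  .groups = "drop")
    }))
  }
  out
}
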