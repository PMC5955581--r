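#' Directed triplet-motif clustering coefficients
#'
#' Per-node clustering for each directed triangle motif on a binary
#' adjacency matrix `A` (zero diagonal), with `d_in`, `d_out`,
#' `d_tot = d_in + d_out` and `d_bi = (A^2)_ii` (reciprocated degree):
#' cycle `(A^3)_ii / (d_in d_out - d_bi)`, middleman
#' `(A A' A)_ii / (d_in d_out - d_bi)`, fan-in
#' `(A' A^2)_ii / (d_in (d_in - 1))`, fan-out
#' `(A^2 A')_ii / (d_out (d_out - 1))`, and total
#' `((A + A')^3)_ii / (2 (d_tot (d_tot - 1) - 2 d_bi))`. A coefficient is
#' `NA` exactly when its denominator is zero (too few neighbours of the
#' required kind); `NA` nodes are excluded from all means.
#'
#' @param adj binary directed adjacency matrix with zero diagonal
#'   (`adj[i, j] = 1` for edge i -> j).
#' @return a `clustering_profile` tibble: one row per node with degrees and
#'   the five coefficients.
#' @export
directed_clustering <- function(adj) {
  a <- (as.matrix(adj) != 0) * 1
  if (any(diag(a) != 0)) abort("adjacency must have a zero diagonal")
  at <- t(a)
  a2 <- a %*% a
  d_in <- colSums(a); d_out <- rowSums(a)
  d_tot <- d_in + d_out
  d_bi <- diag(a2)

  num <- list(cycle = diag(a2 %*% a),
              middleman = diag(a %*% at %*% a),
              fan_in = diag(at %*% a2),
              fan_out = diag(a2 %*% at),
              total = diag((a + at) %*% (a + at) %*% (a + at)))
  den <- list(cycle = d_in * d_out - d_bi,
              middleman = d_in * d_out - d_bi,
              fan_in = d_in * (d_in - 1),
              fan_out = d_out * (d_out - 1),
              total = 2 * (d_tot * (d_tot - 1) - 2 * d_bi))
  cc <- lapply(names(num), function(m)
    ifelse(den[[m]] > 0, num[[m]] / den[[m]], NA_real_))
  names(cc) <- names(num)

  out <- tibble(node = seq_len(nrow(a)), d_in = d_in, d_out = d_out,
                d_bi = d_bi,
                cycle = cc$cycle, middleman = cc$middleman,
                fan_in = cc$fan_in, fan_out = cc$fan_out, total = cc$total)
  class(out) <- c("clustering_profile", class(out))
  out
}

motif_names <- c("cycle", "middleman", "fan_in", "fan_out", "total")

#' Erdos-Renyi null ensemble for motif clustering
#'
#' Generates `n_graphs` directed Erdos-Renyi graphs (independent directed
#' edges with probability `p`, no self-loops), computes the node-mean of
#' each motif clustering coefficient per graph (undefined nodes excluded),
#' and summarizes the ensemble.
#'
#' @param n nodes per graph (>= 3).
#' @param p directed edge probability, matched to the data graph's
#'   ordered-pair edge density.
#' @param n_graphs ensemble size.
#' @param seed integer seed.
#' @return tibble: `motif`, `null_mean`, `null_sd` (SD across the
#'   ensemble of graph-level means), `n_graphs`.
#' @export
er_null <- function(n, p, n_graphs = 50, seed = 1) {
  if (n < 3) abort("need n >= 3")
  if (p < 0 || p > 1) abort("p must be in [0, 1]")
  means <- with_seed(seed, {
    vapply(seq_len(n_graphs), function(g) {
      a <- matrix(runif(n * n) < p, n, n) * 1
      diag(a) <- 0
      prof <- directed_clustering(a)
      vapply(motif_names, function(m) mean(prof[[m]], na.rm = TRUE), 0)
    }, numeric(length(motif_names)))
  })
  tibble(motif = motif_names,
         null_mean = rowMeans(means, na.rm = TRUE),
         null_sd = apply(means, 1, sd, na.rm = TRUE),
         n_graphs = n_graphs)
}

#' Motif clustering versus reconstruction performance
#'
#' Z-scores each motif's clustering coefficient across nodes (undefined
#' values excluded; zero-variance motifs dropped with a warning), bins
#' nodes into equal-count bins of reconstruction variance explained, and
#' reports the per-bin mean z-scored coefficient per motif.
#'
#' @param profile a `clustering_profile` from [directed_clustering()].
#' @param ve per-node variance explained (same node order).
#' @param n_bins number of equal-count VE bins.
#' @return tibble: `motif`, `bin`, `mean_ve`, `mean_z`, `n_nodes`.
#' @export
clustering_vs_performance <- function(profile, ve, n_bins = 5) {
  stopifnot(length(ve) == nrow(profile))
  ok_node <- !is.na(ve)
  if (sum(ok_node) < n_bins) abort("fewer usable nodes than bins")
  bin <- rep(NA_integer_, length(ve))
  bin[ok_node] <- ceiling(rank(ve[ok_node], ties.method = "first") /
                            sum(ok_node) * n_bins)
  out <- list()
  for (m in motif_names) {
    x <- profile[[m]]
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warn(sprintf("motif '%s' has zero variance; excluded", m))
      next
    }
    z <- (x - mu) / s
    keep <- ok_node & !is.na(z)
    out[[m]] <- tibble(motif = m, bin = bin[keep], z = z[keep],
                       ve = ve[keep]) |>
      group_by(.data$motif, .data$bin) |>
      summarise(mean_ve = mean(.data$ve), mean_z = mean(.data$z),
                n_nodes = n(), .groups = "drop")
  }
  bind_rows(out)
}
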