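#' Partial correlation of two traces given control traces
#'
#' Computes the partial correlation between `x` and `y` controlling for the
#' columns of `controls` by successive iterations of the first-order
#' formula `r_xy|z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' eliminating one control at a time.
#'
#' @param x,y numeric traces of equal length (>= 10).
#' @param controls matrix (or data frame) whose columns are control traces.
#' @return scalar partial correlation in `[-1, 1]`.
#' @export
partial_corr <- function(x, y, controls) {
  z <- as.matrix(controls)
  if (length(x) != length(y) || nrow(z) != length(x)) {
    abort("all traces must have the same length")
  }
  if (length(x) < 10) abort("traces must have length >= 10")
  vars <- cbind(x = x, y = y, z)
  sds <- apply(vars, 2, sd)
  if (any(sds == 0)) abort("zero-variance input trace")
  r <- cor(vars)
  m <- ncol(r)
  while (m > 2) {
    rz <- r[, m]
    d <- 1 - rz^2
    if (any(d[-m] <= .Machine$double.eps)) {
      abort("degenerate input: a trace is collinear with a control")
    }
    rnew <- (r - tcrossprod(rz)) / sqrt(tcrossprod(d))
    r <- rnew[-m, -m, drop = FALSE]
    diag(r) <- 1
    m <- m - 1
  }
  min(max(r[1, 2], -1), 1)
}

# vectorized elimination of one control from a set of pairwise correlations
# stored as vectors over instances: r is a named list; ctrl the control name;
# keep the names to retain
partial_step <- function(r, vars, ctrl) {
  keep <- setdiff(vars, ctrl)
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  d <- lapply(keep, function(a) 1 - r[[key(a, ctrl)]]^2)
  names(d) <- keep
  out <- list()
  for (ii in seq_along(keep)) for (jj in seq_len(ii - 1)) {
    a <- keep[ii]; b <- keep[jj]
    den <- sqrt(pmax(d[[a]] * d[[b]], 0))
    val <- (r[[key(a, b)]] - r[[key(a, ctrl)]] * r[[key(b, ctrl)]]) / den
    val[den < 1e-12] <- NA_real_
    out[[key(a, b)]] <- val
  }
  out
}

#' Blocked three-control partial-correlation matrix
#'
#' For every neuron pair (i, j) and every stimulus block b, computes the
#' partial correlation of the two within-block traces controlling for three
#' variables: the frame-wise mean of i's trace across all other blocks, the
#' same for j (both capture stimulus-locked response because the direction
#' order is preserved across blocks), and the within-block mean trace of
#' all remaining neurons (population-wide covariability, e.g. running).
#' The entry is the mean partial correlation across blocks.
#'
#' @param dff a `dff_traces` object.
#' @param schedule a `stim_schedule`; defaults to the one in `dff`.
#' @param frame_filter use all frames, only grating frames, or only grey
#'   frames of each block.
#' @param blocks optional integer subset of blocks (>= 2) to use, e.g. the
#'   training blocks of a cross-validation fold.
#' @return symmetric neuron x neuron matrix of mean partial correlations
#'   with a zero diagonal.
#' @export
block_partial_matrix <- function(dff, schedule = dff$schedule,
                                 frame_filter = c("all", "grating_only",
                                                  "grey_only"),
                                 blocks = NULL) {
  frame_filter <- match.arg(frame_filter)
  if (is.null(blocks)) blocks <- seq_len(schedule$n_blocks)
  nb <- length(blocks)
  if (nb < 2) abort("need at least 2 blocks")
  if (schedule$n_frames > ncol(dff$dff)) abort("schedule extends past traces")

  kind <- switch(frame_filter, all = "all", grating_only = "grating",
                 grey_only = "grey")
  rel <- block_relative_frames(schedule, kind)

  n <- nrow(dff$dff)
  if (n < 3) abort("need at least 3 neurons (population control)")
  xb <- lapply(blocks, function(b) dff$dff[, block_frames(schedule, b)[rel],
                                           drop = FALSE])
  sum_x <- Reduce(`+`, xb)

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  I <- pairs[, 1]; J <- pairs[, 2]
  acc <- matrix(0, length(I), nb)

  for (bi in seq_len(nb)) {
    x <- xb[[bi]]
    m <- (sum_x - x) / (nb - 1)
    tt <- ncol(x)
    xc <- x - rowMeans(x); mc <- m - rowMeans(m)
    cxx <- tcrossprod(xc) / (tt - 1)
    cxm <- tcrossprod(xc, mc) / (tt - 1)   # [i, j] = cov(X_i, M_j)
    cmm <- tcrossprod(mc) / (tt - 1)
    dxx <- diag(cxx); dmm <- diag(cmm); dxm <- diag(cxm)
    cs <- rowSums(cxx)                     # cov(X_i, S)
    cms <- colSums(cxm)                    # cov(M_i, S)
    vs <- sum(cxx)                         # var(S)

    ij <- cbind(I, J); ji <- cbind(J, I)
    nm2 <- n - 2
    cov_l <- list(
      "x|y"   = cxx[ij],
      "x|z1"  = dxm[I],
      "x|z2"  = cxm[ij],
      "y|z1"  = cxm[ji],
      "y|z2"  = dxm[J],
      "z1|z2" = cmm[ij],
      "x|z3"  = (cs[I] - dxx[I] - cxx[ij]) / nm2,
      "y|z3"  = (cs[J] - dxx[J] - cxx[ij]) / nm2,
      "z1|z3" = (cms[I] - dxm[I] - cxm[ji]) / nm2,
      "z2|z3" = (cms[J] - cxm[ij] - dxm[J]) / nm2)
    v <- list(x = dxx[I], y = dxx[J], z1 = dmm[I], z2 = dmm[J],
              z3 = (vs + dxx[I] + dxx[J] - 2 * cs[I] - 2 * cs[J] +
                      2 * cxx[ij]) / nm2^2)
    key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
    r <- list()
    for (kk in names(cov_l)) {
      ab <- strsplit(kk, "|", fixed = TRUE)[[1]]
      den <- sqrt(v[[ab[1]]] * v[[ab[2]]])
      rv <- cov_l[[kk]] / den
      rv[den <= 0] <- NA_real_
      r[[key(ab[1], ab[2])]] <- pmin(pmax(rv, -1), 1)
    }
    r <- partial_step(r, c("x", "y", "z1", "z2", "z3"), "z1")
    r <- partial_step(r, c("x", "y", "z2", "z3"), "z2")
    r <- partial_step(r, c("x", "y", "z3"), "z3")
    acc[, bi] <- pmin(pmax(r[["x|y"]], -1), 1)
  }

  pc <- rowMeans(acc, na.rm = TRUE)
  pc[is.nan(pc)] <- NA_real_
  out <- matrix(0, n, n)
  out[cbind(I, J)] <- pc
  out[cbind(J, I)] <- pc
  diag(out) <- 0
  out
}
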