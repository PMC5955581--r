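#' Classify visually responsive neurons (Dunnett-style many-to-one test)
#'
#' A neuron is responsive when its mean trial response to any grating
#' direction significantly exceeds the mean over all grey periods, by a
#' one-sided many-to-one comparison familywise-corrected with a seeded
#' Monte-Carlo null of the maximum Dunnett t statistic (pooled within-group
#' variance across the direction groups and the grey control group).
#'
#' @param tr a `trial_responses` object.
#' @param alpha familywise significance level.
#' @param n_mc Monte-Carlo draws for the max-t null.
#' @param seed integer seed for the Monte-Carlo null.
#' @return tibble with one row per neuron: `neuron`, `responsive`, `p_any`
#'   (adjusted p of the best direction) plus attribute `"p_adj"` — the
#'   neuron x direction matrix of adjusted per-direction p values.
#' @export
classify_responsive <- function(tr, alpha = 0.01, n_mc = 10000, seed = 1) {
  meta <- tr$meta
  dirs <- sort(unique(meta$direction[meta$kind == "grating"]))
  dir_cols <- lapply(dirs, function(d)
    which(meta$kind == "grating" & meta$direction == d))
  grey_cols <- which(meta$kind == "grey")
  sizes <- vapply(dir_cols, length, 1L)
  n0 <- length(grey_cols)
  if (any(sizes < 2) || n0 < 2) abort("need >= 2 trials in every group")

  k <- length(dirs)
  ntot <- sum(sizes) + n0
  df <- ntot - (k + 1)

  ## Monte-Carlo null of the max many-to-one t (depends only on the design)
  null_max <- with_seed(seed, {
    m_d <- matrix(rnorm(n_mc * k), n_mc, k) / rep(sqrt(sizes), each = n_mc)
    m_0 <- rnorm(n_mc) / sqrt(n0)
    s2 <- stats::rchisq(n_mc, df) / df
    tmat <- (m_d - m_0) / sqrt(s2 %o% (1 / sizes + 1 / n0))
    apply(tmat, 1, max)
  })

  resp <- tr$responses
  n_neuron <- nrow(resp)
  p_adj <- matrix(NA_real_, n_neuron, k,
                  dimnames = list(NULL, paste0("dir_", dirs)))
  for (i in seq_len(n_neuron)) {
    y <- resp[i, ]
    gm <- vapply(dir_cols, function(cc) mean(y[cc]), 0)
    g0 <- mean(y[grey_cols])
    ss <- sum(vapply(dir_cols, function(cc) sum((y[cc] - mean(y[cc]))^2), 0)) +
      sum((y[grey_cols] - g0)^2)
    s2 <- ss / df
    if (s2 <= 0) { p_adj[i, ] <- 1; next }
    tstat <- (gm - g0) / sqrt(s2 * (1 / sizes + 1 / n0))
    p_adj[i, ] <- vapply(tstat, function(tt) mean(null_max >= tt), 0)
  }
  out <- tibble(neuron = seq_len(n_neuron),
                p_any = apply(p_adj, 1, min),
                responsive = apply(p_adj, 1, min) < alpha)
  attr(out, "p_adj") <- p_adj
  out
}

#' Permutation tests for direction and orientation tuning
#'
#' Tests each neuron's grating trial responses for significant tuning via
#' the magnitude of the mean trial vector: trials are mapped to unit vectors
#' at the grating angle (direction space) or twice the angle (orientation
#' space), scaled by the trial response; the null is a seeded permutation of
#' direction labels and `p = (1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param tr a `trial_responses` object.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return tibble: `neuron`, `p_dir`, `p_ori`.
#' @export
tuning_significance <- function(tr, n_perm = 1000, seed = 1) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  meta <- tr$meta
  gcols <- which(meta$kind == "grating")
  theta <- meta$direction[gcols] * pi / 180
  resp <- tr$responses[, gcols, drop = FALSE]
  n_neuron <- nrow(resp)
  m <- length(gcols)

  stat <- function(r, ph) Mod(mean(r * exp(1i * ph)))
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(m))
    p_dir <- p_ori <- numeric(n_neuron)
    for (i in seq_len(n_neuron)) {
      r <- resp[i, ]
      for (space in c("dir", "ori")) {
        ph <- if (space == "dir") theta else 2 * theta
        obs <- stat(r, ph)
        nullv <- vapply(seq_len(n_perm),
                        function(b) stat(r, ph[perms[, b]]), 0)
        p <- (1 + sum(nullv >= obs)) / (1 + n_perm)
        if (space == "dir") p_dir[i] <- p else p_ori[i] <- p
      }
    }
    tibble(neuron = seq_len(n_neuron), p_dir = p_dir, p_ori = p_ori)
  })
}

# model: R(theta) = B + A1 exp(-wrap(theta-thp)^2 / 2s^2)
#                 + A2 exp(-wrap(theta-thp-180)^2 / 2s^2)
acg_model <- function(theta, b, a1, a2, sigma, theta_p) {
  b + a1 * exp(-wrap_180(theta - theta_p)^2 / (2 * sigma^2)) +
    a2 * exp(-wrap_180(theta - theta_p - 180)^2 / (2 * sigma^2))
}

#' Fit an asymmetric circular Gaussian tuning curve
#'
#' Fits `R(theta) = B + A1 exp(-wrap(theta - theta_p)^2 / (2 sigma^2)) + A2
#' exp(-wrap(theta - theta_p - 180)^2 / (2 sigma^2))` to per-direction mean
#' responses by least squares from `n_restarts` randomized initial
#' conditions, keeping the parameter set with the lowest mean-squared error.
#'
#' @param direction_means per-direction mean responses.
#' @param directions grating directions in degrees (>= 5 distinct).
#' @param n_restarts number of randomized starts.
#' @param seed integer seed for the starts.
#' @return list with `b`, `a1`, `a2`, `sigma_deg`, `theta_p_deg` (NA when
#'   the fitted curve is flat), `r_squared`, `converged`, `fitted`.
#' @export
fit_tuning_curve <- function(direction_means, directions, n_restarts = 20,
                             seed = 1) {
  stopifnot(length(direction_means) == length(directions))
  if (length(unique(directions)) < 5) abort("need >= 5 distinct directions")
  y <- as.numeric(direction_means); th <- as.numeric(directions)
  rng <- diff(range(y))
  sst <- sum((y - mean(y))^2)

  best <- NULL; best_sse <- Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      st <- list(b = min(y) + runif(1, -0.1, 0.1) * max(rng, 1e-6),
                 a1 = max(rng, 1e-3) * runif(1, 0.5, 1.5),
                 a2 = max(rng, 1e-3) * runif(1, 0, 1),
                 sigma = runif(1, 15, 60),
                 theta_p = if (r == 1) th[which.max(y)] else runif(1, 0, 360))
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ acg_model(th, b, a1, a2, sigma, theta_p),
          start = st,
          lower = c(b = -Inf, a1 = 0, a2 = 0, sigma = 5, theta_p = -360),
          upper = c(b = Inf, a1 = Inf, a2 = Inf, sigma = 180, theta_p = 720),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(residuals(fit)^2)
      if (sse < best_sse) { best_sse <- sse; best <- coef(fit) }
    }
  })
  if (is.null(best)) {
    return(list(b = NA_real_, a1 = NA_real_, a2 = NA_real_,
                sigma_deg = NA_real_, theta_p_deg = NA_real_,
                r_squared = NA_real_, converged = FALSE, fitted = NULL))
  }
  # canonical labelling: the model is invariant under swapping (A1, A2)
  # with a 180-degree rotation of theta_p, so force A1 >= A2
  if (best[["a2"]] > best[["a1"]]) {
    tmp <- best[["a1"]]; best[["a1"]] <- best[["a2"]]; best[["a2"]] <- tmp
    best[["theta_p"]] <- best[["theta_p"]] + 180
  }
  theta_p <- best[["theta_p"]] %% 360
  flat <- (best[["a1"]] + best[["a2"]]) < 1e-6 * max(abs(y), 1e-12) + 1e-12
  list(b = best[["b"]], a1 = best[["a1"]], a2 = best[["a2"]],
       sigma_deg = best[["sigma"]],
       theta_p_deg = if (flat) NA_real_ else theta_p,
       r_squared = if (sst > 0) 1 - best_sse / sst else NA_real_,
       converged = TRUE,
       fitted = acg_model(th, best[["b"]], best[["a1"]], best[["a2"]],
                          best[["sigma"]], theta_p))
}

#' Variance of single-trial responses explained by mean tuning
#'
#' For each neuron, the fraction of cross-trial (grating) response variance
#' explained by its per-direction means: `1 - SS(resp - direction mean) /
#' SS(resp - grand mean)`.
#'
#' @param tr a `trial_responses` object.
#' @return tibble: `neuron`, `tuning_ve` (`NA` when total variance is zero).
#' @export
tuning_variance_explained <- function(tr) {
  meta <- tr$meta
  gcols <- which(meta$kind == "grating")
  dirlab <- meta$direction[gcols]
  resp <- tr$responses[, gcols, drop = FALSE]
  ve <- apply(resp, 1, function(y) {
    tot <- sum((y - mean(y))^2)
    if (tot == 0) return(NA_real_)
    res <- sum((y - stats::ave(y, dirlab))^2)
    1 - res / tot
  })
  tibble(neuron = seq_len(nrow(resp)), tuning_ve = ve)
}

#' Tuning vector in direction or orientation space
#'
#' Sums per-direction mean responses as vectors at the grating angle
#' (direction space) or twice the angle (orientation space):
#' `v = sum_d m_d (cos phi_d, sin phi_d)`.
#'
#' @param direction_means per-direction mean responses.
#' @param directions directions in degrees.
#' @param space `"direction"` or `"orientation"`.
#' @return numeric 2-vector `(x, y)`; zero vector means tuning is undefined.
#' @export
tuning_vector <- function(direction_means, directions,
                          space = c("direction", "orientation")) {
  space <- match.arg(space)
  phi <- directions * pi / 180
  if (space == "orientation") phi <- 2 * phi
  v <- c(x = sum(direction_means * cos(phi)),
         y = sum(direction_means * sin(phi)))
  # exact symmetry cancels to floating-point dust; snap it to zero so the
  # undefined-direction flag triggers downstream
  if (sqrt(sum(v^2)) < 1e-10 * sum(abs(direction_means))) v[] <- 0
  v
}

#' Full per-neuron tuning analysis
#'
#' Runs responsiveness classification, direction/orientation permutation
#' tests, asymmetric circular Gaussian fits (for tuned neurons), tuning
#' variance explained, and tuning vectors, returning one row per neuron.
#' Class precedence: `direction` if `p_dir < alpha_tuning`, else
#' `orientation` if `p_ori < alpha_tuning`, else `untuned`; non-responsive
#' neurons are `untuned`.
#'
#' @param tr a `trial_responses` object.
#' @param alpha_responsive familywise level of the responsiveness test.
#' @param alpha_tuning level of the tuning permutation tests.
#' @param n_perm,n_restarts,seed see the underlying functions.
#' @return a tibble of class `tuning_result`, one row per neuron.
#' @export
tune_neurons <- function(tr, alpha_responsive = 0.01, alpha_tuning = 0.05,
                         n_perm = 1000, n_restarts = 20, seed = 1) {
  resp <- classify_responsive(tr, alpha = alpha_responsive, seed = seed)
  sig <- tuning_significance(tr, n_perm = n_perm, seed = seed + 1)
  ve <- tuning_variance_explained(tr)

  meta <- tr$meta
  gcols <- which(meta$kind == "grating")
  dirs <- sort(unique(meta$direction[gcols]))
  dmeans <- t(apply(tr$responses[, gcols, drop = FALSE], 1, function(y)
    vapply(dirs, function(d) mean(y[meta$direction[gcols] == d]), 0)))

  n <- nrow(tr$responses)
  cls <- rep("untuned", n)
  tuned_sel <- resp$responsive & sig$p_dir < alpha_tuning
  cls[tuned_sel] <- "direction"
  ori_sel <- resp$responsive & !tuned_sel & sig$p_ori < alpha_tuning
  cls[ori_sel] <- "orientation"

  fits <- vector("list", n)
  for (i in seq_len(n)) {
    if (cls[i] == "untuned") next
    fits[[i]] <- fit_tuning_curve(dmeans[i, ], dirs,
                                  n_restarts = n_restarts, seed = seed + i)
  }
  get <- function(fld) vapply(fits, function(f)
    if (is.null(f)) NA_real_ else as.numeric(f[[fld]]), 0)

  vec_dir <- t(apply(dmeans, 1, tuning_vector, directions = dirs,
                     space = "direction"))
  vec_ori <- t(apply(dmeans, 1, tuning_vector, directions = dirs,
                     space = "orientation"))

  out <- tibble(
    neuron = seq_len(n),
    responsive = resp$responsive,
    p_any = resp$p_any,
    p_dir = sig$p_dir, p_ori = sig$p_ori,
    tuning_class = cls,
    b = get("b"), a1 = get("a1"), a2 = get("a2"),
    sigma_deg = get("sigma_deg"), theta_p_deg = get("theta_p_deg"),
    r_squared = get("r_squared"),
    tuning_ve = ve$tuning_ve,
    vec_dir_x = vec_dir[, 1], vec_dir_y = vec_dir[, 2],
    vec_ori_x = vec_ori[, 1], vec_ori_y = vec_ori[, 2])
  attr(out, "direction_means") <- dmeans
  attr(out, "directions") <- dirs
  class(out) <- c("tuning_result", class(out))
  out
}
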