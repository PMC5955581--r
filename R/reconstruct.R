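#' Variance explained by a predicted trace
#'
#' `1 - sum((y - yhat)^2) / sum(y^2)`; note the denominator is the raw
#' (uncentered) sum of squares, so a constant predictor of a nonzero-mean
#' trace has positive variance explained.
#'
#' @param y observed trace.
#' @param yhat predicted trace.
#' @return scalar in `(-Inf, 1]`; `NA` when `y` is all zero.
#' @export
variance_explained <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ss <- sum(y^2)
  if (ss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss
}

#' @describeIn variance_explained population-level version,
#'   `1 - sum_i sum_t (Y - Yhat)^2 / sum_i sum_t Y^2`.
#' @param Y,Yhat observed and predicted neuron x frame matrices.
#' @export
population_ve <- function(Y, Yhat) {
  ss <- sum(Y^2)
  if (ss == 0) return(NA_real_)
  1 - sum((Y - Yhat)^2) / ss
}

# closed-form least squares of y on (yraw, 1) over `frames`
fit_gain_offset <- function(y, yraw, frames = seq_along(y)) {
  yf <- y[frames]; xf <- yraw[frames]
  vx <- var(xf)
  if (!is.finite(vx) || vx == 0) {
    return(list(gain = 0, offset = mean(yf)))
  }
  g <- stats::cov(yf, xf) / vx
  list(gain = g, offset = mean(yf) - g * mean(xf))
}

#' Predict one neuron's trace from its graph in-neighbours
#'
#' The raw prediction is the weighted sum of the in-neighbour traces with
#' the partial-correlation edge weights; a gain and offset are then fit by
#' closed-form least squares (over `fit_frames`) to map it onto the target
#' trace. The gain and offset are frozen: edge-removal analyses reuse them
#' unchanged. A neuron with zero in-degree is predicted by its best
#' constant and flagged.
#'
#' @param g a `functional_graph`.
#' @param dff a `dff_traces` object.
#' @param j target neuron index.
#' @param fit_frames frames used to fit the gain/offset (default all).
#' @return list: `pred` (full-length predicted trace), `gain`, `offset`,
#'   `n_in`, `zero_in_degree`, `mse`, `ve` (both over `fit_frames`).
#' @export
predict_neuron <- function(g, dff, j, fit_frames = NULL) {
  y <- dff$dff[j, ]
  if (is.null(fit_frames)) fit_frames <- seq_along(y)
  w <- g$W[, j]
  inn <- which(w != 0)
  if (length(inn) == 0) {
    b <- mean(y[fit_frames])
    pred <- rep(b, length(y))
    return(list(pred = pred, gain = 0, offset = b, n_in = 0L,
                zero_in_degree = TRUE,
                mse = mean((y[fit_frames] - b)^2),
                ve = variance_explained(y[fit_frames], pred[fit_frames])))
  }
  yraw <- as.numeric(w[inn] %*% dff$dff[inn, , drop = FALSE])
  fo <- fit_gain_offset(y, yraw, fit_frames)
  pred <- fo$gain * yraw + fo$offset
  list(pred = pred, gain = fo$gain, offset = fo$offset,
       n_in = length(inn), zero_in_degree = FALSE,
       mse = mean((y[fit_frames] - pred[fit_frames])^2),
       ve = variance_explained(y[fit_frames], pred[fit_frames]))
}

#' Reconstruct a population from its functional graph
#'
#' Runs [predict_neuron()] for each requested neuron and aggregates
#' per-neuron and population variance explained. When `eval_frames` is
#' given, gain/offset are fit on `fit_frames` and performance is reported
#' on `eval_frames` (used for cross-validation).
#'
#' @param g a `functional_graph`.
#' @param dff a `dff_traces` object.
#' @param neurons neuron indices (default all).
#' @param fit_frames frames for the gain/offset fit (default all).
#' @param eval_frames frames for performance evaluation (default
#'   `fit_frames`).
#' @return a `recon_result`: list with `neurons` (tibble: neuron, n_in,
#'   gain, offset, mse, ve, zero_in_degree), `pred` (matrix over all
#'   frames, rows = `neurons`), `population_ve`.
#' @export
reconstruct_population <- function(g, dff, neurons = NULL,
                                   fit_frames = NULL, eval_frames = NULL) {
  if (is.null(neurons)) neurons <- seq_len(nrow(dff$dff))
  if (is.null(fit_frames)) fit_frames <- seq_len(ncol(dff$dff))
  if (is.null(eval_frames)) eval_frames <- fit_frames

  pred <- matrix(0, length(neurons), ncol(dff$dff))
  rows <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    pn <- predict_neuron(g, dff, j, fit_frames = fit_frames)
    pred[k, ] <- pn$pred
    y <- dff$dff[j, eval_frames]
    yh <- pn$pred[eval_frames]
    rows[[k]] <- tibble(neuron = j, n_in = pn$n_in, gain = pn$gain,
                        offset = pn$offset,
                        zero_in_degree = pn$zero_in_degree,
                        mse = mean((y - yh)^2),
                        ve = variance_explained(y, yh))
  }
  structure(
    list(neurons = bind_rows(rows),
         pred = pred,
         neuron_index = neurons,
         population_ve = population_ve(dff$dff[neurons, eval_frames,
                                               drop = FALSE],
                                       pred[, eval_frames, drop = FALSE])),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d neurons, population VE = %.3f\n",
              nrow(x$neurons), x$population_ve))
  invisible(x)
}

#' @describeIn reconstruct_population per-neuron tibble.
#' @param x a `recon_result`.
#' @param ... unused.
#' @export
tidy.recon_result <- function(x, ...) x$neurons

#' @describeIn reconstruct_population one-row summary.
#' @export
glance.recon_result <- function(x, ...) {
  tibble(n_neurons = nrow(x$neurons),
         mean_ve = mean(x$neurons$ve, na.rm = TRUE),
         median_mse = median(x$neurons$mse, na.rm = TRUE),
         population_ve = x$population_ve)
}

#' Cross-validated reconstruction over stimulus blocks
#'
#' Leave-one-block-out validation of the graph model: for each fold, the
#' partial-correlation matrix and edge directions are rebuilt from the
#' training blocks only, gain/offset are fit on training frames, and
#' variance explained is measured on the held-out block.
#'
#' @param dff a `dff_traces` object.
#' @param schedule a `stim_schedule` (>= 3 blocks).
#' @param xcorr optional precomputed [block_correlograms()] (per-block
#'   correlograms do not depend on the fold split, so they are reused).
#' @param neurons neurons to evaluate (graphs are always built from the
#'   full population).
#' @param weight_floor,cutoff_s,max_lag_s graph-construction parameters.
#' @param frame_filter frames used for the partial correlations.
#' @return list with `neurons` (tibble: neuron, mean held-out `ve` and
#'   `mse` across folds), `folds` (tibble: fold, population_ve),
#'   `population_ve` (pooled over folds).
#' @export
crossval_reconstruction <- function(dff, schedule = dff$schedule,
                                    xcorr = NULL, neurons = NULL,
                                    weight_floor = 0, cutoff_s = 0.5,
                                    max_lag_s = 1.5,
                                    frame_filter = "all") {
  nb <- schedule$n_blocks
  if (nb < 3) abort("need >= 3 blocks for cross-validation")
  if (is.null(neurons)) neurons <- seq_len(nrow(dff$dff))
  if (is.null(xcorr)) xcorr <- block_correlograms(dff, schedule, max_lag_s)

  per_fold <- vector("list", nb)
  acc_num <- 0; acc_den <- 0
  for (b in seq_len(nb)) {
    train <- setdiff(seq_len(nb), b)
    pcm <- block_partial_matrix(dff, schedule, frame_filter = frame_filter,
                                blocks = train)
    lg <- edge_lag(xcorr, blocks = train, cutoff_s = cutoff_s)
    g <- build_graph(pcm, lg, weight_floor = weight_floor,
                     positions_um = dff$positions_um)
    train_frames <- unlist(lapply(train, block_frames, schedule = schedule))
    test_frames <- block_frames(schedule, b)
    rec <- reconstruct_population(g, dff, neurons = neurons,
                                  fit_frames = train_frames,
                                  eval_frames = test_frames)
    per_fold[[b]] <- mutate(rec$neurons, fold = b)
    yt <- dff$dff[neurons, test_frames, drop = FALSE]
    acc_num <- acc_num + sum((yt - rec$pred[, test_frames, drop = FALSE])^2)
    acc_den <- acc_den + sum(yt^2)
  }
  all_folds <- bind_rows(per_fold)
  list(
    neurons = all_folds |>
      group_by(.data$neuron) |>
      summarise(ve = mean(.data$ve, na.rm = TRUE),
                mse = mean(.data$mse, na.rm = TRUE), .groups = "drop"),
    folds = all_folds |>
      group_by(.data$fold) |>
      summarise(mean_ve = mean(.data$ve, na.rm = TRUE), .groups = "drop"),
    population_ve = 1 - acc_num / acc_den)
}

#' Increase in reconstruction error as edges are removed
#'
#' Removes a neuron's in-edges one at a time (strongest-first,
#' weakest-first, or random order averaged over draws) with the gain and
#' offset frozen from the full model, reporting the increase in MSE
#' normalized by the neuron's mean squared fluorescence, against both the
#' number of edges removed and the cumulative |weight| fraction removed.
#'
#' @param g a `functional_graph`.
#' @param dff a `dff_traces` object.
#' @param j target neuron.
#' @param order removal order.
#' @param seed seed for random order.
#' @param n_random random-order draws to average.
#' @return tibble: `n_removed`, `frac_removed`, `cum_weight_frac`,
#'   `dmse_norm`.
#' @export
edge_removal_curves <- function(g, dff, j,
                                order = c("strongest_first", "weakest_first",
                                          "random"),
                                seed = 1, n_random = 20) {
  order <- match.arg(order)
  y <- dff$dff[j, ]
  w <- g$W[, j]
  inn <- which(w != 0)
  pn <- predict_neuron(g, dff, j)
  norm <- sum(y^2) / length(y)
  if (length(inn) == 0) {
    return(tibble(n_removed = 0L, frac_removed = 0, cum_weight_frac = 0,
                  dmse_norm = 0))
  }
  contrib <- dff$dff[inn, , drop = FALSE] * w[inn]   # per-edge contribution
  tot_w <- sum(abs(w[inn]))

  one_curve <- function(ord) {
    e <- y - pn$pred
    dmse <- numeric(length(ord) + 1)
    cw <- numeric(length(ord) + 1)
    mse0 <- mean(e^2)
    for (s in seq_along(ord)) {
      e <- e + pn$gain * contrib[ord[s], ]
      dmse[s + 1] <- mean(e^2) - mse0
      cw[s + 1] <- cw[s] + abs(w[inn][ord[s]])
    }
    list(dmse = dmse, cw = cw / tot_w)
  }

  if (order == "strongest_first") {
    res <- one_curve(order(abs(w[inn]), decreasing = TRUE))
  } else if (order == "weakest_first") {
    res <- one_curve(order(abs(w[inn])))
  } else {
    curves <- with_seed(seed, lapply(seq_len(n_random), function(r)
      one_curve(sample(seq_along(inn)))))
    res <- list(
      dmse = rowMeans(sapply(curves, `[[`, "dmse")),
      cw = rowMeans(sapply(curves, `[[`, "cw")))
  }
  tibble(n_removed = 0:length(inn),
         frac_removed = (0:length(inn)) / length(inn),
         cum_weight_frac = res$cw,
         dmse_norm = res$dmse / norm)
}

#' Ablate within- versus between-class in-edges
#'
#' For each neuron, removes either its within-class or its between-class
#' in-edges (gain/offset frozen from the full model) and reports the MSE
#' increase of each ablation.
#'
#' @param g a `functional_graph`.
#' @param dff a `dff_traces` object.
#' @param classes per-neuron class labels.
#' @param neurons neurons to evaluate (default all).
#' @return tibble: `neuron`, `class`, `n_in_within`, `n_in_between`,
#'   `dmse_within`, `dmse_between` (normalized by mean squared
#'   fluorescence).
#' @export
subpopulation_ablation <- function(g, dff, classes, neurons = NULL) {
  if (is.null(neurons)) neurons <- seq_len(nrow(dff$dff))
  rows <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    y <- dff$dff[j, ]
    w <- g$W[, j]
    inn <- which(w != 0)
    pn <- predict_neuron(g, dff, j)
    norm <- sum(y^2) / length(y)
    e0 <- y - pn$pred
    mse0 <- mean(e0^2)
    same <- inn[classes[inn] == classes[j]]
    diff_ <- setdiff(inn, same)
    dmse_of <- function(rm) {
      if (length(rm) == 0) return(0)
      e <- e0 + pn$gain *
        as.numeric(w[rm] %*% dff$dff[rm, , drop = FALSE])
      (mean(e^2) - mse0) / norm
    }
    rows[[k]] <- tibble(neuron = j, class = classes[j],
                        n_in_within = length(same),
                        n_in_between = length(diff_),
                        dmse_within = dmse_of(same),
                        dmse_between = dmse_of(diff_))
  }
  bind_rows(rows)
}

#' Tuning similarity between data and model
#'
#' Recomputes each tuned neuron's per-direction mean response from the
#' predicted traces exactly as for the data, sums the direction means as a
#' tuning vector (direction space for direction-tuned neurons, orientation
#' space for orientation-tuned), and reports the cosine similarity with
#' the data-derived vector.
#'
#' @param pred predicted neuron x frame matrix (rows follow `neurons`).
#' @param neurons neuron indices corresponding to the rows of `pred`.
#' @param dff a `dff_traces` object (for the data vectors and schedule).
#' @param tuning a `tuning_result` from [tune_neurons()].
#' @return tibble: `neuron`, `tuning_class`, `similarity` (`NA` when the
#'   model vector has zero magnitude).
#' @export
model_tuning_similarity <- function(pred, neurons, dff, tuning) {
  schedule <- dff$schedule
  fake <- structure(list(dff = pred, schedule = schedule,
                         frame_rate_hz = dff$frame_rate_hz),
                    class = "dff_traces")
  tm_model <- trial_means(fake, schedule)
  tm_data <- trial_means(dff, schedule)
  meta <- tm_model$meta
  gcols <- which(meta$kind == "grating")
  dirs <- sort(unique(meta$direction[gcols]))
  dmean <- function(respmat, row) vapply(dirs, function(d)
    mean(respmat[row, gcols[meta$direction[gcols] == d]]), 0)

  rows <- list()
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    cl <- tuning$tuning_class[tuning$neuron == j]
    if (length(cl) != 1 || cl == "untuned") next
    space <- if (cl == "direction") "direction" else "orientation"
    vm <- tuning_vector(dmean(tm_model$responses, k), dirs, space)
    vd <- tuning_vector(dmean(tm_data$responses, j), dirs, space)
    rows[[length(rows) + 1]] <- tibble(
      neuron = j, tuning_class = cl,
      similarity = cosine_similarity(vm, vd))
  }
  bind_rows(rows)
}

#' Population variance explained versus population size
#'
#' For each requested subsample size, draws seeded neuron subsamples, runs
#' the full graph + reconstruction pipeline on the subsample alone (the
#' partial-correlation controls and correlograms are recomputed within the
#' subsample), and reports the population variance explained, together
#' with the Spearman correlation of the per-size mean VE with size.
#'
#' @param dff a `dff_traces` object.
#' @param sizes subsample sizes (each <= number of neurons).
#' @param n_rep subsamples per size.
#' @param seed integer seed.
#' @param schedule a `stim_schedule`.
#' @param weight_floor,cutoff_s,max_lag_s graph parameters.
#' @return list with `samples` (tibble: size, rep, population_ve),
#'   `by_size` (tibble: size, mean_ve), `spearman_rho`.
#' @export
ve_vs_population_size <- function(dff, sizes, n_rep = 2, seed = 1,
                                  schedule = dff$schedule,
                                  weight_floor = 0, cutoff_s = 0.5,
                                  max_lag_s = 1.5) {
  n <- nrow(dff$dff)
  if (any(sizes > n)) abort("sizes exceed the population")
  draws <- with_seed(seed, {
    lapply(seq_along(sizes), function(si)
      lapply(seq_len(n_rep), function(r) sample.int(n, sizes[si])))
  })
  rows <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(n_rep)) {
      sel <- draws[[si]][[r]]
      sub <- structure(
        list(dff = dff$dff[sel, , drop = FALSE],
             frame_rate_hz = dff$frame_rate_hz,
             positions_um = dff$positions_um[sel, , drop = FALSE],
             schedule = schedule),
        class = "dff_traces")
      pv <- if (length(sel) < 3) {
        cst <- reconstruct_population(
          build_graph(matrix(0, length(sel), length(sel)),
                      list(t_max = matrix(0L, length(sel), length(sel)),
                           status = matrix("none", length(sel), length(sel)),
                           frame_rate_hz = dff$frame_rate_hz)),
          sub)
        cst$population_ve
      } else {
        pcm <- block_partial_matrix(sub, schedule)
        xc <- block_correlograms(sub, schedule, max_lag_s)
        lg <- edge_lag(xc, cutoff_s = cutoff_s)
        g <- build_graph(pcm, lg, weight_floor = weight_floor,
                         positions_um = sub$positions_um)
        reconstruct_population(g, sub)$population_ve
      }
      rows[[length(rows) + 1]] <- tibble(size = sizes[si], rep = r,
                                         population_ve = pv)
    }
  }
  samples <- bind_rows(rows)
  by_size <- samples |>
    group_by(.data$size) |>
    summarise(mean_ve = mean(.data$population_ve), .groups = "drop")
  rho <- suppressWarnings(
    cor(by_size$size, by_size$mean_ve, method = "spearman"))
  list(samples = samples, by_size = by_size, spearman_rho = rho)
}
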