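#' One-standard-error rule for a cross-validation profile
#'
#' Returns the largest penalty whose cross-validated MSE does not exceed
#' the minimum MSE plus the standard error at the minimum.
#'
#' @param lambda penalty grid.
#' @param cv_mse cross-validated MSE per penalty.
#' @param cv_se standard error of `cv_mse` per penalty.
#' @return the selected lambda.
#' @export
choose_lambda_1se <- function(lambda, cv_mse, cv_se) {
  stopifnot(length(lambda) == length(cv_mse), length(cv_mse) == length(cv_se))
  i0 <- which.min(cv_mse)
  thr <- cv_mse[i0] + cv_se[i0]
  max(lambda[cv_mse <= thr])
}

# contiguous-chunk or random fold assignment over T frames
make_foldid <- function(T, n_folds, type = c("chunk", "random"), seed = 1) {
  type <- match.arg(type)
  if (type == "chunk") {
    rep(seq_len(n_folds), each = ceiling(T / n_folds))[seq_len(T)]
  } else {
    with_seed(seed, sample(rep(seq_len(n_folds), length.out = T)))
  }
}

#' LASSO-optimal weights for a neuron's inputs
#'
#' Fits the L1-penalized regression `min (1/2N) sum(y - b0 - x'b)^2 +
#' lambda sum|b_j|` over a geometric penalty path from `lambda_max` (the
#' smallest penalty at which all coefficients are zero) down, estimating
#' per-penalty MSE and its standard error by k-fold cross-validation, and
#' selecting the penalty by the one-standard-error rule. Folds are seeded
#' contiguous time chunks by default, respecting temporal autocorrelation;
#' set `fold_type = "random"` for random frames. Predictors are not
#' standardized, so the coefficients live on the fluorescence scale the
#' objective is written in.
#'
#' @param x frame x input matrix of in-neighbour traces.
#' @param y target trace.
#' @param n_folds cross-validation folds.
#' @param seed integer seed (random fold type).
#' @param fold_type `"chunk"` or `"random"`.
#' @param nlambda path length.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param lambda optional explicit penalty grid (descending; may include 0).
#' @return a `lasso_fit`: list with `weights`, `intercept`, `lambda_choice`,
#'   `lambda`, `cv_mse`, `cv_se`, `lambda_min`, `nonzero` (per-penalty
#'   count), `n_folds`, and the underlying `glmnet` path fit.
#' @export
lasso_weights <- function(x, y, n_folds = 5, seed = 1,
                          fold_type = c("chunk", "random"),
                          nlambda = 100, lambda_min_ratio = 1e-4,
                          lambda = NULL) {
  fold_type <- match.arg(fold_type)
  x <- as.matrix(x)
  T <- nrow(x)
  p <- ncol(x)
  if (p < 1) abort("need at least one input")
  if (T <= p) warn("fewer frames than inputs; fit may be unstable")
  if (all(apply(x, 2, sd) == 0)) {
    return(structure(list(failed = TRUE, reason = "all inputs constant"),
                     class = "lasso_fit"))
  }
  if (p == 1) return(lasso_single_input(x, y, n_folds, seed, fold_type,
                                        nlambda, lambda_min_ratio, lambda))

  lambda_max <- max(abs(crossprod(x, y - mean(y)))) / T
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  foldid <- make_foldid(T, n_folds, fold_type, seed)
  cv <- glmnet::cv.glmnet(x, y, lambda = lambda, foldid = foldid,
                          standardize = FALSE, thresh = 1e-10)
  fit <- cv$glmnet.fit
  lam_grid <- cv$lambda
  lam1 <- choose_lambda_1se(lam_grid, cv$cvm, cv$cvsd)
  beta <- as.numeric(predict(fit, s = lam1, type = "coefficients",
                             exact = TRUE, x = x, y = y))
  structure(
    list(weights = beta[-1], intercept = beta[1],
         lambda_choice = lam1,
         lambda = lam_grid, cv_mse = cv$cvm, cv_se = cv$cvsd,
         lambda_min = cv$lambda.min,
         nonzero = fit$df,
         n_folds = n_folds, fold_type = fold_type,
         lambda_max = lambda_max,
         glmnet_fit = fit, failed = FALSE),
    class = "lasso_fit")
}

# closed-form single-predictor soft-threshold path (glmnet needs >= 2
# columns); same objective and 1-SE selection as the multi-input path
lasso_single_input <- function(x, y, n_folds, seed, fold_type,
                               nlambda, lambda_min_ratio, lambda) {
  x <- as.numeric(x); T <- length(x)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  fit1 <- function(xtr, ytr, lam) {
    xm <- mean(xtr); ym <- mean(ytr)
    sxx <- mean((xtr - xm)^2)
    sxy <- mean((xtr - xm) * (ytr - ym))
    b <- if (sxx > 0) soft(sxy, lam) / sxx else 0
    c(b0 = ym - b * xm, b = b)
  }
  lambda_max <- max(abs(sum(x * (y - mean(y))))) / T
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  foldid <- make_foldid(T, n_folds, fold_type, seed)
  cvm <- cvse <- numeric(length(lambda))
  for (li in seq_along(lambda)) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- foldid != f
      cf <- fit1(x[tr], y[tr], lambda[li])
      mean((y[!tr] - cf["b0"] - cf["b"] * x[!tr])^2)
    }, 0)
    cvm[li] <- mean(errs)
    cvse[li] <- sd(errs) / sqrt(n_folds)
  }
  lam1 <- choose_lambda_1se(lambda, cvm, cvse)
  cf <- fit1(x, y, lam1)
  path_b <- vapply(lambda, function(l) fit1(x, y, l)["b"], 0)
  structure(
    list(weights = unname(cf["b"]), intercept = unname(cf["b0"]),
         lambda_choice = lam1, lambda = lambda, cv_mse = cvm, cv_se = cvse,
         lambda_min = lambda[which.min(cvm)],
         nonzero = as.integer(path_b != 0),
         n_folds = n_folds, fold_type = fold_type,
         lambda_max = lambda_max, glmnet_fit = NULL, failed = FALSE),
    class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<lasso_fit> failed:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<lasso_fit> %d inputs, %d nonzero at lambda = %.4g (1-SE rule)\n",
              length(x$weights), sum(x$weights != 0), x$lambda_choice))
  invisible(x)
}

#' @describeIn lasso_weights per-penalty path tibble.
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @export
tidy.lasso_fit <- function(x, ...) {
  if (isTRUE(x$failed)) return(tibble())
  tibble(lambda = x$lambda, cv_mse = x$cv_mse, cv_se = x$cv_se,
         nonzero = as.integer(x$nonzero))
}

#' @describeIn lasso_weights one-row summary of the selected model.
#' @export
glance.lasso_fit <- function(x, ...) {
  if (isTRUE(x$failed)) return(tibble(failed = TRUE))
  tibble(lambda_choice = x$lambda_choice, lambda_min = x$lambda_min,
         n_nonzero = sum(x$weights != 0), n_inputs = length(x$weights),
         n_folds = x$n_folds)
}

#' Benchmark reconstruction with LASSO-optimal weights
#'
#' For each neuron, refits the weights of its graph in-neighbours by
#' [lasso_weights()] (the partial-correlation weights only choose the
#' inputs) and reports in-sample performance of the selected model.
#'
#' @param g a `functional_graph`.
#' @param dff a `dff_traces` object.
#' @param neurons neurons to evaluate (default all).
#' @param n_folds,seed,fold_type,nlambda passed to [lasso_weights()].
#' @return list with `neurons` (tibble: neuron, n_in, n_nonzero, mse, ve),
#'   `pred` matrix, `population_ve`.
#' @export
lasso_reconstruction <- function(g, dff, neurons = NULL, n_folds = 5,
                                 seed = 1, fold_type = "chunk",
                                 nlambda = 100) {
  if (is.null(neurons)) neurons <- seq_len(nrow(dff$dff))
  pred <- matrix(0, length(neurons), ncol(dff$dff))
  rows <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    y <- dff$dff[j, ]
    inn <- which(g$W[, j] != 0)
    if (length(inn) == 0) {
      pred[k, ] <- mean(y)
      rows[[k]] <- tibble(neuron = j, n_in = 0L, n_nonzero = 0L,
                          mse = mean((y - mean(y))^2),
                          ve = variance_explained(y, rep(mean(y), length(y))))
      next
    }
    lf <- lasso_weights(t(dff$dff[inn, , drop = FALSE]), y,
                        n_folds = n_folds, seed = seed,
                        fold_type = fold_type, nlambda = nlambda)
    if (isTRUE(lf$failed)) {
      pred[k, ] <- mean(y)
    } else {
      pred[k, ] <- lf$intercept +
        as.numeric(lf$weights %*% dff$dff[inn, , drop = FALSE])
    }
    rows[[k]] <- tibble(neuron = j, n_in = length(inn),
                        n_nonzero = if (isTRUE(lf$failed)) 0L
                          else sum(lf$weights != 0),
                        mse = mean((y - pred[k, ])^2),
                        ve = variance_explained(y, pred[k, ]))
  }
  list(neurons = bind_rows(rows), pred = pred,
       population_ve = population_ve(dff$dff[neurons, , drop = FALSE], pred))
}
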