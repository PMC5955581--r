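# internal helpers shared across modules

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Wrap angular differences to (-180, 180] degrees
#' @param x angle differences in degrees
#' @return wrapped values in (-180, 180]
#' @keywords internal
wrap_180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar, got %s", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# deterministic seeded evaluation that does not disturb the caller's RNG
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Cosine similarity between two vectors
#'
#' Returns `u . v / (|u| |v|)`, or `NA` when either vector has zero
#' magnitude (the similarity is then undefined).
#'
#' @param u,v numeric vectors of equal length.
#' @return a scalar in `[-1, 1]`, or `NA_real_` for a zero-magnitude input.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

# fast row standardization (mean 0, sd 1 with denominator n-1); zero-variance
# rows come back as all-zero with a flag attribute
row_standardize <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1))
  bad <- s <= 0 | !is.finite(s)
  s[bad] <- 1
  out <- xc / s
  attr(out, "zero_variance") <- bad
  out
}
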