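# build a trial_responses layout with k directions x reps plus grey trials
null_design <- function(n_dir = 12, reps = 24, n_grey = NULL) {
  if (is.null(n_grey)) n_grey <- n_dir * reps
  dirs <- seq(0, 360 - 360 / n_dir, by = 360 / n_dir)
  kind <- c(rep("grating", n_dir * reps), rep("grey", n_grey))
  direction <- c(rep(dirs, each = reps), rep(NA_real_, n_grey))
  list(kind = kind, direction = direction,
       n_trial = length(kind), dirs = dirs)
}

test_that("responsiveness test fires on real effects and not on constants", {
  d <- null_design(n_dir = 6, reps = 30, n_grey = 60)
  const <- fake_tr(matrix(5, 1, d$n_trial), d$kind, d$direction)
  expect_false(classify_responsive(const, seed = 1)$responsive)

  # one direction elevated by 5 pooled SDs
  set.seed(2)
  y <- matrix(rnorm(3 * d$n_trial), 3, d$n_trial)
  y[2, d$kind == "grating" & d$direction == 120] <-
    y[2, d$kind == "grating" & d$direction == 120] + 5
  out <- classify_responsive(fake_tr(y, d$kind, d$direction), seed = 1)
  expect_true(out$responsive[2])
  expect_false(out$responsive[1])
  expect_false(out$responsive[3])
  # the elevated direction is the significant one
  p_adj <- attr(out, "p_adj")
  expect_equal(which.min(p_adj[2, ]), 3L, ignore_attr = TRUE)  # 120 deg

  expect_error(classify_responsive(fake_tr(matrix(1, 1, 8),
                                           c(rep("grating", 4), rep("grey", 4)),
                                           c(0, 90, 180, 270, rep(NA, 4))),
                                   seed = 1))
})

test_that("responsiveness familywise error is calibrated on null data", {
  d <- null_design(n_dir = 12, reps = 10, n_grey = 60)
  n_neuron <- 1000
  set.seed(3)
  y <- matrix(rnorm(n_neuron * d$n_trial), n_neuron, d$n_trial)
  out <- classify_responsive(fake_tr(y, d$kind, d$direction),
                             alpha = 0.01, seed = 4)
  hits <- sum(out$responsive)
  # binomial 95% band around alpha = 0.01
  expect_gte(hits, qbinom(0.025, n_neuron, 0.01))
  expect_lte(hits, qbinom(0.975, n_neuron, 0.01))
})

test_that("Monte-Carlo Dunnett agrees with multcomp's Dunnett adjustment", {
  skip_if_not_installed("multcomp")
  d <- null_design(n_dir = 6, reps = 12, n_grey = 36)
  set.seed(5)
  y <- rnorm(d$n_trial)
  y[d$kind == "grating" & d$direction == 60] <- y[d$kind == "grating" &
                                                    d$direction == 60] + 0.9
  out <- classify_responsive(fake_tr(matrix(y, 1), d$kind, d$direction),
                             n_mc = 40000, seed = 6)
  p_mc <- min(attr(out, "p_adj")[1, ])

  g <- factor(ifelse(d$kind == "grey", "ctrl", paste0("d", d$direction)))
  g <- relevel(g, ref = "ctrl")
  fit <- stats::aov(y ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"),
                       alternative = "greater")
  p_ref <- min(summary(gl)$test$pvalues)
  expect_lt(abs(p_mc - p_ref), 0.02)
})

test_that("tuning permutation test is calibrated and detects tuning", {
  d <- null_design(n_dir = 8, reps = 10, n_grey = 20)
  # calibration under the null
  set.seed(7)
  y <- matrix(rnorm(400 * d$n_trial, mean = 2), 400, d$n_trial)
  sig <- tuning_significance(fake_tr(y, d$kind, d$direction),
                             n_perm = 200, seed = 8)
  for (p in list(sig$p_dir, sig$p_ori)) {
    hits <- sum(p < 0.05)
    expect_gte(hits, qbinom(0.005, 400, 0.05))
    expect_lte(hits, qbinom(0.995, 400, 0.05))
  }

  # noiseless cosine direction tuning -> minimal p_dir
  gcols <- d$kind == "grating"
  y2 <- matrix(1, 2, d$n_trial)
  y2[1, gcols] <- 2 + cos(d$direction[gcols] * pi / 180)
  # two equal peaks 180 deg apart -> orientation-tuned only
  y2[2, gcols] <- 2 + cos(2 * d$direction[gcols] * pi / 180)
  sig2 <- tuning_significance(fake_tr(y2, d$kind, d$direction),
                              n_perm = 500, seed = 9)
  expect_equal(sig2$p_dir[1], 1 / 501)
  expect_equal(sig2$p_ori[2], 1 / 501)
  expect_gt(sig2$p_dir[2], 0.05)   # direction-space vectors cancel

  expect_error(tuning_significance(fake_tr(y2, d$kind, d$direction),
                                   n_perm = 50), "n_perm")
})

test_that("asymmetric circular Gaussian fits recover parameters", {
  dirs <- seq(0, 330, by = 30)
  truth <- list(b = 10, a1 = 80, a2 = 30, sigma = 25, theta_p = 90)
  y <- peernet:::acg_model(dirs, truth$b, truth$a1, truth$a2, truth$sigma,
                           truth$theta_p)
  fit <- fit_tuning_curve(y, dirs, seed = 1)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$theta_p_deg, 90, tolerance = 0.02)
  expect_equal(fit$sigma_deg, 25, tolerance = 0.05)
  expect_equal(fit$a1, 80, tolerance = 0.05)
  expect_equal(fit$a2, 30, tolerance = 0.05)

  flat <- fit_tuning_curve(rep(4, 12), dirs, seed = 2)
  expect_true(flat$converged)
  expect_lt(flat$a1 + flat$a2, 0.01)
  expect_true(is.na(flat$theta_p_deg))

  # noisy recovery: median preferred-direction error < 10 degrees
  errs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    yn <- y + rnorm(length(y), sd = 0.2 * truth$a1)
    f <- fit_tuning_curve(yn, dirs, n_restarts = 10, seed = s)
    abs(peernet:::wrap_180(f$theta_p_deg - truth$theta_p))
  }, 0)
  expect_lt(median(errs), 10)
})

test_that("fit quality degrades monotonically with noise", {
  dirs <- seq(0, 330, by = 30)
  y <- peernet:::acg_model(dirs, 5, 50, 20, 30, 120)
  r2 <- vapply(c(0, 2, 5, 10, 20), function(sdn) {
    median(vapply(1:7, function(s) {
      set.seed(s)
      fit_tuning_curve(y + rnorm(12, sd = sdn), dirs, n_restarts = 8,
                       seed = s)$r_squared
    }, 0))
  }, 0)
  expect_true(all(diff(r2) <= 1e-8))
})

test_that("tuning variance explained behaves as defined", {
  d <- null_design(n_dir = 6, reps = 20, n_grey = 30)
  gcols <- d$kind == "grating"
  # responses exactly equal to their direction means -> VE = 1
  y <- matrix(0, 2, d$n_trial)
  y[1, gcols] <- rep(1:6, each = 20)
  y[2, ] <- rnorm(d$n_trial)
  ve <- tuning_variance_explained(fake_tr(y, d$kind, d$direction))
  expect_equal(ve$tuning_ve[1], 1)
  # direction-independent noise -> VE near 0
  expect_lt(abs(ve$tuning_ve[2]), 2 / sqrt(sum(gcols)) + 5 / (sum(gcols) - 1))

  # adding noise strictly decreases VE
  set.seed(11)
  base_sig <- rep(sin(1:6), each = 20)
  ves <- vapply(c(0.1, 0.3, 1, 3, 10), function(sdn) {
    set.seed(12)
    yy <- matrix(base_sig + rnorm(120, sd = sdn), 1)
    tuning_variance_explained(
      fake_tr(cbind(yy, matrix(0, 1, 30)), d$kind, d$direction))$tuning_ve
  }, 0)
  expect_true(all(diff(ves) < 0))
})

test_that("tuning vectors point at the driven direction", {
  dirs <- seq(0, 330, by = 30)
  m <- rep(0, 12); m[4] <- 2  # only 90 deg driven
  v <- tuning_vector(m, dirs, "direction")
  expect_equal(atan2(v[2], v[1]) * 180 / pi, 90, ignore_attr = TRUE)

  u <- tuning_vector(rep(1, 12), dirs, "direction")
  expect_equal(sqrt(sum(u^2)), 0, tolerance = 1e-12)
  expect_true(is.na(cosine_similarity(u, v)))
  expect_equal(cosine_similarity(v, v), 1)

  # fitted-model vector angle equals theta_p when A1 > A2 > 0, noiseless
  y <- peernet:::acg_model(dirs, 0, 60, 20, 30, 210)
  vv <- tuning_vector(y, dirs, "direction")
  ang <- (atan2(vv[2], vv[1]) * 180 / pi) %% 360
  expect_lt(abs(peernet:::wrap_180(ang - 210)), 1)
})

test_that("tune_neurons assembles classes with the stated precedence", {
  fx <- synth_fixture()
  trm <- trial_means(fx$dff)
  tn <- tune_neurons(trm, n_perm = 300, n_restarts = 8, seed = 5)
  expect_equal(nrow(tn), 24)
  expect_true(all(tn$tuning_class %in% c("direction", "orientation",
                                         "untuned")))
  # untuned neurons carry no fit
  expect_true(all(is.na(tn$theta_p_deg[tn$tuning_class == "untuned"])))
  # class precedence consistent with the p-values
  called_dir <- tn$tuning_class == "direction"
  expect_true(all(tn$p_dir[called_dir] < 0.05))
  expect_true(all(tn$responsive[called_dir]))
})
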