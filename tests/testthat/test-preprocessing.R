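test_that("baseline estimation preserves constants and rejects transients", {
  const <- rep(100, 600)
  expect_equal(estimate_baseline(const), const, tolerance = 1e-10)

  # constant + sparse positive transients: oracle is the known constant
  set.seed(1)
  tr <- rep(100, 2000)
  starts <- sample(100:1900, 30)
  for (s0 in starts) tr[s0:(s0 + 3)] <- tr[s0:(s0 + 3)] + 50
  tr <- tr + rnorm(2000, sd = 0.5)
  b <- estimate_baseline(tr)
  expect_lt(max(abs(b - 100)), 0.05 * 100)

  # slow sinusoidal drift: oracle is the generative drift
  t <- seq_len(3000)
  drift <- 100 * (1 + 0.15 * sin(2 * pi * t / 3000))
  b <- estimate_baseline(drift + rnorm(3000, sd = 0.3))
  core <- 200:2800
  expect_lt(max(abs(b[core] - drift[core]) / drift[core]), 0.05)

  expect_error(estimate_baseline(rep(1, 50)), "shorter")
  expect_error(estimate_baseline(rep(1, 200), sg_window = 80), "odd")
})

test_that("dF/F0 is the percent change from baseline", {
  raw <- matrix(runif(200, 50, 150), 4, 50)
  base <- raw
  d0 <- compute_dff(raw, baseline = base)
  expect_equal(d0$dff, matrix(0, 4, 50))
  d2 <- compute_dff(2 * base, baseline = base)
  expect_equal(d2$dff, matrix(100, 4, 50))
  # scale invariance
  da <- compute_dff(1.7 * raw, baseline = 1.7 * base)
  db <- compute_dff(raw, baseline = base)
  expect_equal(da$dff, db$dff, tolerance = 1e-12)

  bad <- base; bad[2, 7] <- 0
  expect_error(compute_dff(raw, baseline = bad), "neuron 2, frame 7")
})

test_that("baseline + dF/F recovers a known dF/F within 5% of its SD", {
  # sparse-transient trace with a known generative baseline, at the default
  # imaging-noise level (1% of F0)
  kern <- peernet:::calcium_kernel(0.1, 1.5, 20)
  for (s0 in 1:4) {
    set.seed(s0)
    T <- 6000
    b <- 100 * (1 + 0.1 * sin(2 * pi * seq_len(T) / 3000 + s0))
    sp <- rpois(T, 0.1 / 20) * 40
    ca <- peernet:::convolve_calcium(matrix(sp, 1), kern, 1)[1, ]
    raw <- b * (1 + ca / 100) + rnorm(T, sd = 1)
    dff_true <- 100 * (raw - b) / b
    est_b <- estimate_baseline(raw)
    est <- 100 * (raw - est_b) / est_b
    expect_lt(sqrt(mean((est - dff_true)^2)), 0.05 * sd(dff_true))
  }
})

test_that("trial means use the stated windows", {
  sched <- make_schedule(2, 4, 1, 2, 2, 20, seed = 1)
  n_fr <- sched$n_frames
  const <- fake_dff(matrix(3.5, 2, n_fr), sched)
  tm <- trial_means(const)
  expect_true(all(tm$responses == 3.5))

  # indicator trace inside one grating window
  g5 <- sched$trials[sched$trials$kind == "grating", ][3, ]
  step <- matrix(0, 2, n_fr)
  step[1, g5$onset:g5$offset] <- 1
  tm2 <- trial_means(fake_dff(step, sched))
  k <- which(sched$trials$kind == "grating")[3]
  expect_equal(tm2$responses[1, k], 1)
  expect_true(all(tm2$responses[1, -k] == 0))

  # grey window is only the last 1.5 s
  grey1 <- sched$trials[sched$trials$kind == "grey", ][1, ]
  ramp <- matrix(0, 2, n_fr)
  ramp[1, grey1$onset:grey1$offset] <- seq_len(grey1$offset - grey1$onset + 1)
  tm3 <- trial_means(fake_dff(ramp, sched))
  kg <- which(sched$trials$kind == "grey")[1]
  tail_n <- floor(1.5 * 20)
  expected <- mean(tail(seq_len(grey1$offset - grey1$onset + 1), tail_n))
  expect_equal(tm3$responses[1, kg], expected)

  # brute-force oracle on random data
  set.seed(2)
  x <- matrix(rnorm(3 * n_fr), 3, n_fr)
  tm4 <- trial_means(fake_dff(x, sched))
  for (k in seq_len(nrow(sched$trials))) {
    trk <- sched$trials[k, ]
    w <- if (trk$kind == "grating") trk$onset:trk$offset else
      (trk$offset - tail_n + 1):trk$offset
    expect_equal(tm4$responses[, k], rowMeans(x[, w, drop = FALSE]))
  }

  # responses depend only on within-trial frames
  y <- x
  outside <- setdiff(seq_len(n_fr),
                     unlist(lapply(seq_len(nrow(sched$trials)), function(k)
                       sched$trials$onset[k]:sched$trials$offset[k])[1]))
  g1 <- sched$trials[1, ]
  y[, setdiff(seq_len(n_fr), g1$onset:g1$offset)] <- 99
  tm5 <- trial_means(fake_dff(y, sched))
  expect_equal(tm5$responses[, 1], tm4$responses[, 1])
})

test_that("silent-neuron masking matches a brute-force rule", {
  sched <- make_schedule(1, 4, 1, 2, 2, 20, seed = 1)
  n_fr <- sched$n_frames
  z <- fake_dff(matrix(0, 3, n_fr), sched)
  expect_true(all(silent_mask(z, trial = 2)))

  x <- matrix(rnorm(3 * n_fr, sd = 1), 3, n_fr)
  tr2 <- sched$trials[2, ]
  x[2, tr2$onset + 3] <- 10 * sd(x[2, ])
  d <- fake_dff(x, sched)
  expect_false(silent_mask(d, trial = 2)[2])

  # brute force on random data
  sm <- silent_mask(d, trial = 2, sd_factor = 2)
  nsd <- apply(x, 1, sd)
  w <- tr2$onset:tr2$offset
  manual <- vapply(1:3, function(i) all(x[i, w] <= 2 * nsd[i]), TRUE)
  expect_equal(sm, manual)
})

test_that("population summary z-scores and separates classes", {
  fx <- synth_fixture()
  classes <- ifelse(fx$sim$ground_truth$is_tuned, "tuned", "untuned")
  ps <- population_summary(fx$dff, classes)
  expect_setequal(unique(ps$timecourse$class), c("tuned", "untuned"))
  # z-scored single-trial responses have mean 0, sd 1 per neuron
  zt <- ps$responses
  expect_lt(abs(mean(zt$z_response)), 0.5)

  # identical neurons give a zero-width quartile band
  sched <- make_schedule(1, 4, 1, 2, 2, 20, seed = 1)
  tr0 <- rep(0, sched$n_frames)
  tr0[seq(50, sched$n_frames, by = 80)] <- 10   # grating-locked transients
  same <- matrix(rep(tr0, each = 4), 4, byrow = FALSE)
  ps2 <- population_summary(fake_dff(same, sched), rep("a", 4))
  expect_gt(nrow(ps2$timecourse), 0)
  expect_equal(ps2$timecourse$q25, ps2$timecourse$q75, tolerance = 1e-12)

  expect_warning(population_summary(fx$dff, rep(c("tuned", "ghost"),
                                                c(24, 0))), NA)
})

test_that("running probability rises with population activity", {
  sched <- make_schedule(1, 4, 1, 2, 2, 20, seed = 1)
  n_fr <- sched$n_frames
  x <- matrix(rnorm(2 * n_fr), 2, n_fr)
  d0 <- fake_dff(x, sched, speed = rep(0, n_fr))
  expect_true(all(running_by_activity(d0)$p_running == 0))
  d1 <- fake_dff(x, sched, speed = rep(5, n_fr))
  expect_true(all(running_by_activity(d1)$p_running == 1))
  expect_error(running_by_activity(fake_dff(x[, 1:5], sched_short <- sched,
                                            ), speed_cm_s = rep(0, 5),
                                   n_quantiles = 10))

  # generative coupling: speed is driven by the same latent as activity
  sched2 <- make_schedule(2, 8, 2, 3, 2, 20, seed = 2)
  cfg <- sim_config(n_neurons = 30, n_local_latents = 0, latent_gain = 3,
                    latent_tau_s = 4, conn_p0 = 0)
  sim <- simulate_population(cfg, sched2, seed = 21)
  dff <- compute_dff(sim$recording)
  rba <- running_by_activity(dff, n_quantiles = 5)
  expect_gt(cor(rba$quantile, rba$p_running, method = "spearman"), 0)
  expect_gt(rba$p_running[5], rba$p_running[1])
})
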