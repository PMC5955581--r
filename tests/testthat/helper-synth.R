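# shared fixtures, built once per test run

# small but structured recording in the default (coupled, latent-driven)
# regime: 24 neurons, 3 blocks of 8 directions x 2 reps at 20 Hz
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- make_schedule(3, 8, 2, 3, 2, 20, seed = 11)
      sim <- simulate_population(sim_config(n_neurons = 24), sched,
                                 seed = 12)
      dff <- compute_dff(sim$recording)
      pcm <- block_partial_matrix(dff)
      xcorr <- block_correlograms(dff)
      lags <- edge_lag(xcorr)
      g <- build_graph(pcm, lags, positions_um = dff$positions_um)
      cache <<- list(sched = sched, sim = sim, dff = dff, pcm = pcm,
                     xcorr = xcorr, lags = lags, graph = g)
    }
    cache
  }
})

# hand-built trial_responses object
fake_tr <- function(responses, kind, direction, block = 1L) {
  structure(
    list(responses = responses,
         meta = tibble::tibble(trial = seq_along(kind),
                               block = rep(block, length.out = length(kind)),
                               kind = kind, direction = direction)),
    class = "trial_responses")
}

# a bare dff_traces object around a matrix
fake_dff <- function(mat, schedule, speed = NULL, positions = NULL) {
  structure(list(dff = mat, baseline_f0 = matrix(1, nrow(mat), ncol(mat)),
                 frame_rate_hz = schedule$frame_rate_hz,
                 positions_um = positions, speed_cm_s = speed,
                 schedule = schedule),
            class = "dff_traces")
}

# exhaustive triangle-count oracle for directed clustering
enumerate_clustering <- function(a) {
  n <- nrow(a)
  at <- t(a)
  res <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("cycle", "middleman", "fan_in",
                                        "fan_out", "total")))
  s <- a + at
  for (i in seq_len(n)) {
    cyc <- mid <- fin <- fout <- tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i == j || i == k || j == k) next
      cyc <- cyc + a[i, j] * a[j, k] * a[k, i]
      mid <- mid + a[j, i] * a[i, k] * a[j, k]
      fin <- fin + a[j, i] * a[k, i] * a[j, k]
      fout <- fout + a[i, j] * a[i, k] * a[j, k]
      tot <- tot + s[i, j] * s[j, k] * s[k, i]
    }
    din <- sum(a[, i]); dout <- sum(a[i, ]); dbi <- sum(a[i, ] * a[, i])
    dtot <- din + dout
    den <- c(din * dout - dbi, din * dout - dbi, din * (din - 1),
             dout * (dout - 1), 2 * (dtot * (dtot - 1) - 2 * dbi))
    num <- c(cyc, mid, fin, fout, tot)
    res[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  res
}
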