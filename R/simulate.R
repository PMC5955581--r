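#' Generator configuration for synthetic population recordings
#'
#' Parameters of the synthetic two-photon recording generator. Defaults
#' emulate the drifting-grating regime the analysis assumes: an L2/3-sized
#' field of view, a majority-tuned population, distance-dependent coupling,
#' a shared running-like latent, a slow calcium indicator and additive
#' imaging noise.
#'
#' @param n_neurons number of neurons.
#' @param frac_tuned fraction of neurons given a stimulus-tuned drive.
#' @param frac_direction among tuned neurons, fraction that is
#'   direction-selective (strongly asymmetric peaks) rather than
#'   orientation-selective.
#' @param field_diameter_um diameter of the circular field of view (microns).
#' @param conn_p0 coupling probability at zero distance.
#' @param conn_lambda_um length constant (microns) of the exponential decay
#'   of connection probability with distance.
#' @param weight_scale mean magnitude of coupling weights (drive units per
#'   spike).
#' @param frac_positive fraction of coupling weights that are excitatory.
#' @param lag_choices integer frame lags that ground-truth edges draw from
#'   (0 denotes a sub-frame interaction that appears at lag 0 at imaging
#'   resolution).
#' @param baseline_drive mean per-neuron baseline drive; `softplus()` of it
#'   is the baseline firing rate in Hz.
#' @param tuning_amp_range range of the primary tuning amplitude A1 (drive
#'   units).
#' @param sigma_range_deg range of tuning widths (degrees).
#' @param latent_tau_s correlation time of the global (running-like) shared
#'   latent (seconds).
#' @param latent_gain mean per-neuron gain on the rectified global latent;
#'   0 turns the latent (and running) off.
#' @param latent_threshold threshold on the global latent above which the
#'   animal "runs"; sets the running fraction.
#' @param n_local_latents number of spatially local co-fluctuation
#'   processes (0 disables them).
#' @param local_latent_tau_s correlation time of the local latents
#'   (seconds); faster than the baseline-estimation window so local
#'   co-fluctuations survive dF/F0 normalization.
#' @param local_latent_gain drive gain of the local latents.
#' @param local_latent_sigma_um spatial footprint (Gaussian SD, microns) of
#'   each local latent, giving correlations that decay with distance.
#' @param calcium_rise_s,calcium_decay_s indicator kernel time constants
#'   (seconds); defaults in the slow GCaMP6s-class regime.
#' @param spike_amp fractional fluorescence change per spike.
#' @param f0_range range of per-neuron baseline fluorescence (arbitrary
#'   units).
#' @param noise_frac imaging noise SD as a fraction of baseline fluorescence.
#' @param drift_amp,drift_period_s amplitude (fraction of F0) and period of a
#'   slow sinusoidal baseline drift.
#' @param syn_tau_s decay time (seconds) of the synaptic trace through which
#'   spikes exert their coupling drive; one presynaptic spike contributes
#'   roughly `weight * syn_tau_s` expected extra downstream spikes.
#' @param rate_max rate ceiling in Hz keeping the recurrence stable.
#' @param substeps sub-steps per imaging frame in the spiking recurrence.
#' @param coupling_matrix optional explicit ground-truth coupling matrix
#'   (entry `[j, i]` = weight of j -> i); overrides the random draw.
#' @param lag_matrix optional explicit per-edge frame lags (with
#'   `coupling_matrix`).
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 150,
                       frac_tuned = 0.55,
                       frac_direction = 0.2,
                       field_diameter_um = 800,
                       conn_p0 = 0.35,
                       conn_lambda_um = 200,
                       weight_scale = 0.2,
                       frac_positive = 0.8,
                       lag_choices = 0:3,
                       baseline_drive = -1.5,
                       tuning_amp_range = c(4, 9),
                       sigma_range_deg = c(20, 40),
                       latent_tau_s = 8,
                       latent_gain = 1.2,
                       latent_threshold = 1.28,
                       n_local_latents = 12,
                       local_latent_tau_s = 1,
                       local_latent_gain = 4,
                       local_latent_sigma_um = 150,
                       calcium_rise_s = 0.1,
                       calcium_decay_s = 1.5,
                       spike_amp = 0.3,
                       f0_range = c(50, 150),
                       noise_frac = 0.01,
                       drift_amp = 0.03,
                       drift_period_s = 120,
                       syn_tau_s = 0.15,
                       rate_max = 100,
                       substeps = 2,
                       coupling_matrix = NULL,
                       lag_matrix = NULL) {
  if (calcium_rise_s <= 0 || calcium_decay_s <= 0) {
    abort("calcium kernel time constants must be positive")
  }
  if (calcium_decay_s <= calcium_rise_s) {
    abort("calcium_decay_s must exceed calcium_rise_s")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# discrete difference-of-exponentials indicator kernel, peak-normalized
calcium_kernel <- function(rise_s, decay_s, frame_rate_hz) {
  ar <- exp(-1 / (rise_s * frame_rate_hz))
  ad <- exp(-1 / (decay_s * frame_rate_hz))
  tt <- 0:max(200, ceiling(10 * decay_s * frame_rate_hz))
  peak <- max(ad^tt - ar^tt)
  list(ar = ar, ad = ad, peak = peak)
}

# convolve spike counts (rows) with the indicator kernel via two recursive
# exponential filters
convolve_calcium <- function(spikes, kern, amp) {
  f1 <- t(apply(spikes, 1, function(s) stats::filter(s, kern$ad, method = "recursive")))
  f2 <- t(apply(spikes, 1, function(s) stats::filter(s, kern$ar, method = "recursive")))
  amp * (f1 - f2) / kern$peak
}

# evaluate the asymmetric circular Gaussian drive on a direction grid
tuning_drive_values <- function(theta_deg, a1, a2, sigma, theta_p) {
  a1 * exp(-wrap_180(theta_deg - theta_p)^2 / (2 * sigma^2)) +
    a2 * exp(-wrap_180(theta_deg - theta_p - 180)^2 / (2 * sigma^2))
}

#' Simulate a population recording under a stimulus schedule
#'
#' Generates ground truth (positions, tuning, distance-dependent signed
#' coupling with per-edge lags, shared latent) and a fluorescence recording:
#' rates are `softplus(baseline + tuning drive + lagged coupling input +
#' gain x latent)`, spikes are Poisson, fluorescence is the spike train
#' convolved with a slow difference-of-exponentials indicator kernel riding
#' on a per-neuron baseline with slow drift and additive Gaussian noise. A
#' running-speed trace is co-generated from the same latent so frames of
#' high population activity co-occur with running.
#'
#' @param config a [sim_config()] list.
#' @param schedule a [make_schedule()] stimulus schedule.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return a list with elements `ground_truth` and `recording` (class
#'   `ca_recording`, holding `raw_f` (neuron x frame), `frame_rate_hz`,
#'   `positions_um`, `speed_cm_s`, `schedule`, `ground_truth`).
#' @export
simulate_population <- function(config, schedule, seed = 1) {
  stopifnot(inherits(schedule, "stim_schedule"))
  cfg <- config
  n <- cfg$n_neurons
  fs <- schedule$frame_rate_hz
  T <- schedule$n_frames

  out <- with_seed(seed, {
    ## geometry
    rad <- cfg$field_diameter_um / 2
    rr <- rad * sqrt(runif(n)); ang <- runif(n, 0, 2 * pi)
    positions <- cbind(x = rr * cos(ang), y = rr * sin(ang))

    ## tuning assignment
    n_tuned <- round(cfg$frac_tuned * n)
    is_tuned <- seq_len(n) %in% sample.int(n, n_tuned)
    tuning_class <- ifelse(!is_tuned, "untuned",
                           ifelse(runif(n) < cfg$frac_direction,
                                  "direction", "orientation"))
    theta_p <- runif(n, 0, 360)
    sigma <- runif(n, cfg$sigma_range_deg[1], cfg$sigma_range_deg[2])
    a1 <- runif(n, cfg$tuning_amp_range[1], cfg$tuning_amp_range[2])
    a2 <- a1 * ifelse(tuning_class == "direction",
                      runif(n, 0, 0.3), runif(n, 0.7, 1))
    a1[!is_tuned] <- 0; a2[!is_tuned] <- 0

    ## coupling with distance-dependent probability
    d <- as.matrix(stats::dist(positions))
    p_conn <- cfg$conn_p0 * exp(-d / cfg$conn_lambda_um)
    diag(p_conn) <- 0
    adj <- matrix(runif(n * n) < p_conn, n, n)
    diag(adj) <- FALSE
    wmag <- matrix(rexp(n * n, rate = 1 / cfg$weight_scale), n, n)
    wsgn <- matrix(ifelse(runif(n * n) < cfg$frac_positive, 1, -1), n, n)
    coupling <- ifelse(adj, wmag * wsgn, 0)
    lag_frames <- matrix(0L, n, n)
    lag_frames[adj] <- if (length(cfg$lag_choices) == 1) {
      rep(as.integer(cfg$lag_choices), sum(adj))
    } else {
      sample(cfg$lag_choices, sum(adj), replace = TRUE)
    }
    if (!is.null(cfg$coupling_matrix)) {
      coupling <- cfg$coupling_matrix
      adj <- coupling != 0
      lag_frames <- matrix(0L, n, n)
      if (!is.null(cfg$lag_matrix)) {
        lag_frames[adj] <- as.integer(cfg$lag_matrix[adj])
      }
    }

    ## global (running-like) latent: OU at frame resolution, unit SD
    ar_l <- exp(-1 / (cfg$latent_tau_s * fs))
    latent_raw <- as.numeric(stats::filter(
      rnorm(T, sd = sqrt(1 - ar_l^2)), ar_l, method = "recursive"))
    latent_pos <- pmax(latent_raw, 0)
    g_i <- cfg$latent_gain * runif(n, 0.5, 1.5)

    ## spatially local fast co-fluctuations: each latent has a Gaussian
    ## spatial footprint, so shared variability decays with distance and is
    ## not fully captured by the population-mean control
    local_drive <- matrix(0, n, T)
    local_loadings <- NULL
    if (cfg$n_local_latents > 0) {
      ar_f <- exp(-1 / (cfg$local_latent_tau_s * fs))
      centers_r <- rad * sqrt(runif(cfg$n_local_latents))
      centers_a <- runif(cfg$n_local_latents, 0, 2 * pi)
      centers <- cbind(centers_r * cos(centers_a),
                       centers_r * sin(centers_a))
      local_lat <- vapply(seq_len(cfg$n_local_latents), function(k)
        as.numeric(stats::filter(rnorm(T, sd = sqrt(1 - ar_f^2)), ar_f,
                                 method = "recursive")), numeric(T))
      d2 <- outer(positions[, 1], centers[, 1], `-`)^2 +
        outer(positions[, 2], centers[, 2], `-`)^2
      local_loadings <- exp(-d2 / (2 * cfg$local_latent_sigma_um^2))
      local_drive <- cfg$local_latent_gain *
        (local_loadings %*% t(local_lat))
    }

    ## stimulus drive at frame resolution
    dir_of_frame <- rep(NA_real_, T)
    gr <- schedule$trials[schedule$trials$kind == "grating", ]
    for (k in seq_len(nrow(gr))) {
      dir_of_frame[gr$onset[k]:gr$offset[k]] <- gr$direction[k]
    }
    dirs <- sort(unique(gr$direction))
    drive_by_dir <- sapply(dirs, function(th)
      tuning_drive_values(th, a1, a2, sigma, theta_p))   # n x n_dir
    drive <- matrix(0, n, T)
    idx <- match(dir_of_frame, dirs)
    on_stim <- !is.na(idx)
    drive[, on_stim] <- drive_by_dir[, idx[on_stim]]
    b_i <- rnorm(n, cfg$baseline_drive, 0.3)
    drive <- drive + b_i + outer(g_i, latent_pos) + local_drive

    ## spiking recurrence (sub-frame grid; lag 0 -> 1 sub-step)
    lag_sub <- lag_frames * cfg$substeps
    lag_sub[adj & lag_frames == 0L] <- 1L
    max_lag <- max(1L, max(lag_sub))
    w_by_lag <- lapply(seq_len(max_lag), function(l) {
      w <- coupling
      w[lag_sub != l | !adj] <- 0
      Matrix::Matrix(w, sparse = TRUE)
    })
    spikes <- sim_spikes_cpp(drive, w_by_lag, 1 / fs, cfg$substeps,
                             cfg$rate_max, cfg$syn_tau_s)

    ## fluorescence
    kern <- calcium_kernel(cfg$calcium_rise_s, cfg$calcium_decay_s, fs)
    ca <- convolve_calcium(spikes, kern, cfg$spike_amp)
    f0 <- runif(n, cfg$f0_range[1], cfg$f0_range[2])
    phase <- runif(n, 0, 2 * pi)
    drift <- cfg$drift_amp *
      sin(outer(phase, 2 * pi * seq_len(T) / (cfg$drift_period_s * fs), `+`))
    noise <- matrix(rnorm(n * T, sd = 1), n, T) * (cfg$noise_frac * f0)
    raw_f <- pmax(f0 * (1 + ca + drift) + noise, 0)

    ## running speed from the same latent
    run_excess <- pmax(latent_raw - cfg$latent_threshold, 0)
    speed <- pmax(20 * run_excess + rnorm(T, sd = 0.02), 0)
    if (cfg$latent_gain == 0) speed <- pmax(rnorm(T, sd = 0.02), 0)

    gt <- list(positions_um = positions,
               is_tuned = is_tuned,
               tuning_class = tuning_class,
               tuning_params = tibble(
                 neuron = seq_len(n), tuned = is_tuned,
                 class = tuning_class, baseline_drive = b_i,
                 a1 = a1, a2 = a2, sigma_deg = sigma,
                 theta_p_deg = theta_p),
               coupling = coupling,
               lag_frames = lag_frames,
               latent_gain = latent_pos,
               neuron_gain = g_i,
               local_loadings = local_loadings,
               spikes = spikes)

    rec <- structure(
      list(raw_f = raw_f,
           frame_rate_hz = fs,
           positions_um = positions,
           speed_cm_s = speed,
           schedule = schedule,
           ground_truth = gt),
      class = "ca_recording")
    list(ground_truth = gt, recording = rec)
  })
  out
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d neurons x %d frames @ %.5g Hz\n",
              nrow(x$raw_f), ncol(x$raw_f), x$frame_rate_hz))
  invisible(x)
}
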