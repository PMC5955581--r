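#' Estimate a time-varying fluorescence baseline
#'
#' Estimates the slow baseline F0 of a raw fluorescence trace by masking
#' spike-induced transients and smoothing with a Savitzky-Golay filter.
#' Transients are frames exceeding a running median by `transient_sd` robust
#' standard deviations (1.4826 x MAD of the residual from the running
#' median); masked runs are linearly interpolated before smoothing.
#'
#' @param raw_trace numeric vector, one neuron's raw fluorescence.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window length in frames (odd).
#' @param transient_sd threshold, in robust SDs, above the current baseline
#'   at which frames are treated as transients.
#' @param n_iter masking/smoothing refinement iterations; the noise SD is
#'   re-estimated from the sub-baseline residuals (which transients cannot
#'   contaminate) after each pass.
#' @return numeric vector of the same length: the estimated baseline.
#' @export
estimate_baseline <- function(raw_trace, sg_order = 4, sg_window = 81,
                              transient_sd = 2.5, n_iter = 3) {
  n <- length(raw_trace)
  if (sg_window %% 2 != 1) abort("`sg_window` must be odd")
  if (n <= sg_window) abort("trace shorter than the smoothing window")

  center <- stats::runmed(raw_trace, k = sg_window, endrule = "median")
  for (it in seq_len(n_iter)) {
    resid <- raw_trace - center
    neg <- resid[resid <= 0]
    rsd <- 1.4826 * median(abs(neg))
    if (!is.finite(rsd) || rsd == 0) rsd <- sd(resid)
    masked <- raw_trace
    is_tr <- is.finite(rsd) & rsd > 0 & resid > transient_sd * rsd
    if (any(is_tr)) {
      # dilate the mask so transient flanks (indicator rise/decay) are
      # excluded along with the suprathreshold peak
      pad_b <- max(2L, round(sg_window / 8))
      pad_f <- max(4L, round(sg_window / 2))   # slow indicator decay
      idx <- which(is_tr)
      ext <- unique(unlist(lapply(idx, function(k)
        max(1L, k - pad_b):min(n, k + pad_f))))
      is_tr[ext] <- TRUE
    }
    if (any(is_tr)) {
      keep <- which(!is_tr)
      if (length(keep) < 2) break
      # masked frames take an anchor curve interpolated through local
      # medians of the clean samples (robust to endpoint noise, follows
      # slow drift through masked stretches)
      cells <- split(keep, ceiling(keep / 40))
      gx <- vapply(cells, mean, 0)
      gy <- vapply(cells, function(g) median(raw_trace[g]), 0)
      if (length(gx) >= 2) {
        curve <- approx(gx, gy, xout = seq_len(n), rule = 2)$y
      } else {
        curve <- rep(median(raw_trace[keep]), n)
      }
      masked[is_tr] <- curve[is_tr]
    }
    center <- as.numeric(signal::sgolayfilt(masked, p = sg_order,
                                            n = sg_window))
  }
  center
}

#' Convert a recording to percent dF/F0
#'
#' Normalizes raw fluorescence to percent change from a time-varying
#' baseline: `dff = 100 * (raw - baseline) / baseline`. When `baseline` is
#' `NULL` it is estimated per neuron with [estimate_baseline()].
#'
#' @param recording a `ca_recording` (or a bare neuron x frame matrix plus
#'   `frame_rate_hz`).
#' @param baseline optional neuron x frame baseline matrix; must be strictly
#'   positive.
#' @param ... passed to [estimate_baseline()].
#' @return a `dff_traces` object: list with `dff` (percent units),
#'   `baseline_f0`, `frame_rate_hz`, and (when available from the recording)
#'   `positions_um`, `speed_cm_s`, `schedule`, `ground_truth`.
#' @export
compute_dff <- function(recording, baseline = NULL, ...) {
  if (inherits(recording, "ca_recording")) {
    raw <- recording$raw_f
  } else {
    raw <- as.matrix(recording)
  }
  if (is.null(baseline)) {
    baseline <- t(apply(raw, 1, estimate_baseline, ...))
  }
  if (!all(dim(baseline) == dim(raw))) abort("baseline/raw shape mismatch")
  bad <- which(baseline <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-positive baseline at neuron %d, frame %d (and possibly others)",
      bad[1, 1], bad[1, 2]))
  }
  dff <- 100 * (raw - baseline) / baseline
  is_rec <- inherits(recording, "ca_recording")
  structure(
    list(dff = dff,
         baseline_f0 = baseline,
         frame_rate_hz = if (is_rec) recording$frame_rate_hz else NA_real_,
         positions_um = if (is_rec) recording$positions_um else NULL,
         speed_cm_s = if (is_rec) recording$speed_cm_s else NULL,
         schedule = if (is_rec) recording$schedule else NULL,
         ground_truth = if (is_rec) recording$ground_truth else NULL),
    class = "dff_traces")
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("<dff_traces> %d neurons x %d frames @ %.5g Hz (percent dF/F0)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate_hz))
  invisible(x)
}

#' Per-trial mean responses
#'
#' Computes each neuron's mean dF/F0 in every trial window: the full
#' presentation for gratings and only the final `grey_tail_s` seconds of
#' grey periods, so fluorescence from the preceding grating has decayed.
#'
#' @param dff a `dff_traces` object.
#' @param schedule a `stim_schedule`; defaults to the one carried by `dff`.
#' @param grey_tail_s length of the terminal grey window in seconds.
#' @return a `trial_responses` object: list with `responses` (neuron x
#'   trial matrix), `meta` (tibble: trial, block, kind, direction) and the
#'   window specification.
#' @export
trial_means <- function(dff, schedule = dff$schedule, grey_tail_s = 1.5) {
  fs <- schedule$frame_rate_hz
  tr <- schedule$trials
  if (max(tr$offset) > ncol(dff$dff)) abort("schedule extends past traces")
  tail_frames <- floor(grey_tail_s * fs)
  if (tail_frames < 1) abort("empty grey window after frame rounding")

  windows <- lapply(seq_len(nrow(tr)), function(k) {
    if (tr$kind[k] == "grating") {
      tr$onset[k]:tr$offset[k]
    } else {
      lo <- max(tr$onset[k], tr$offset[k] - tail_frames + 1L)
      lo:tr$offset[k]
    }
  })
  resp <- vapply(windows, function(w) rowMeans(dff$dff[, w, drop = FALSE]),
                 numeric(nrow(dff$dff)))
  structure(
    list(responses = resp,
         meta = tibble(trial = seq_len(nrow(tr)), block = tr$block,
                       kind = tr$kind, direction = tr$direction),
         windows = windows,
         grey_tail_s = grey_tail_s,
         schedule = schedule),
    class = "trial_responses")
}

#' @export
print.trial_responses <- function(x, ...) {
  cat(sprintf("<trial_responses> %d neurons x %d trials (%d grating, %d grey)\n",
              nrow(x$responses), ncol(x$responses),
              sum(x$meta$kind == "grating"), sum(x$meta$kind == "grey")))
  invisible(x)
}

#' @describeIn trial_means long-format tibble of per-trial responses.
#' @param x a `trial_responses` object.
#' @param ... unused.
#' @export
tidy.trial_responses <- function(x, ...) {
  long <- as_tibble(x$responses, .name_repair = ~ as.character(x$meta$trial))
  long$neuron <- seq_len(nrow(x$responses))
  out <- pivot_longer(long, -"neuron", names_to = "trial",
                      values_to = "response")
  out$trial <- as.integer(out$trial)
  left_join(out, x$meta, by = "trial")[, c("neuron", "trial", "block",
                                           "kind", "direction", "response")]
}

# per-neuron baseline-noise SD: SD of dff (percent) over the full recording
baseline_noise_sd <- function(dff) apply(dff$dff, 1, sd)

#' Flag neurons silent in a trial
#'
#' A neuron is silent in a trial when no frame of the trial window exceeds
#' `sd_factor` times its baseline-noise SD (the SD of its dF/F0 over the
#' whole recording).
#'
#' @param dff a `dff_traces` object.
#' @param trial trial index into the schedule's trial table.
#' @param sd_factor threshold multiplier.
#' @param noise_sd optional precomputed per-neuron noise SD.
#' @return logical vector, `TRUE` for silent neurons.
#' @export
silent_mask <- function(dff, trial, sd_factor = 2, noise_sd = NULL) {
  tr <- dff$schedule$trials[trial, ]
  w <- tr$onset:tr$offset
  if (is.null(noise_sd)) noise_sd <- baseline_noise_sd(dff)
  peak <- apply(dff$dff[, w, drop = FALSE], 1, max)
  peak <= sd_factor * noise_sd
}

#' Stimulus-locked population summary
#'
#' Time-locked median and quartiles of per-neuron z-scored dF/F0 around
#' grating presentations (with grey flanks), and z-scored single-trial
#' response distributions per tuning class and condition. Neurons silent in
#' a trial are removed from that trial before averaging.
#'
#' @param dff a `dff_traces` object.
#' @param classes character vector per neuron (e.g. `"tuned"`/`"untuned"`).
#' @param schedule defaults to the schedule carried by `dff`.
#' @param sd_factor silent-neuron threshold, see [silent_mask()].
#' @return list with `timecourse` (tibble: class, time_s, median, q25, q75)
#'   and `responses` (tibble: class, kind, z_response).
#' @export
population_summary <- function(dff, classes, schedule = dff$schedule,
                               sd_factor = 2) {
  fs <- schedule$frame_rate_hz
  z <- row_standardize(dff$dff)
  noise_sd <- baseline_noise_sd(dff)
  flank <- floor(schedule$grey_dur_s * fs)
  glen <- floor(schedule$grating_dur_s * fs)

  gr <- schedule$trials[schedule$trials$kind == "grating", ]
  cls <- unique(classes)
  tc <- list(); rs <- list()
  for (cl in cls) {
    members <- which(classes == cl)
    if (length(members) == 0) {
      warn(sprintf("class '%s' has no members; empty summary", cl))
      next
    }
    segs <- list()
    for (k in seq_len(nrow(gr))) {
      lo <- gr$onset[k] - flank; hi <- gr$onset[k] + glen + flank - 1L
      if (lo < 1 || hi > ncol(z)) next
      silent <- silent_mask(dff, which(dff$schedule$trials$onset == gr$onset[k]),
                            sd_factor, noise_sd)
      act <- members[!silent[members]]
      if (length(act) == 0) next
      segs[[length(segs) + 1]] <- z[act, lo:hi, drop = FALSE]
    }
    if (length(segs) == 0) next
    pooled <- do.call(rbind, segs)
    qs <- apply(pooled, 2, quantile, probs = c(0.25, 0.5, 0.75))
    tc[[cl]] <- tibble(class = cl,
                       time_s = (seq_len(ncol(pooled)) - 1 - flank) / fs,
                       q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ])
  }

  trm <- trial_means(dff, schedule)
  zresp <- row_standardize(trm$responses)
  for (cl in cls) {
    members <- which(classes == cl)
    if (length(members) == 0) next
    for (kd in c("grating", "grey")) {
      cols <- which(trm$meta$kind == kd)
      rs[[paste(cl, kd)]] <- tibble(
        class = cl, kind = kd,
        z_response = as.numeric(zresp[members, cols, drop = FALSE]))
    }
  }
  list(timecourse = bind_rows(tc), responses = bind_rows(rs))
}

#' Probability of running by population-activity quantile
#'
#' Bins frames into equal-count quantiles of total population dF/F0 and
#' reports, per bin, the fraction of frames on which the animal ran
#' (speed above `speed_threshold`).
#'
#' @param dff a `dff_traces` object carrying `speed_cm_s`.
#' @param speed_cm_s per-frame running speed; defaults to the one in `dff`.
#' @param n_quantiles number of equal-count bins.
#' @param speed_threshold running threshold in cm/s.
#' @return tibble with `quantile` (1 = least active frames),
#'   `mean_activity`, `p_running`.
#' @export
running_by_activity <- function(dff, speed_cm_s = dff$speed_cm_s,
                                n_quantiles = 10, speed_threshold = 0.1) {
  total <- colSums(dff$dff)
  if (length(speed_cm_s) != length(total)) abort("speed/frames misaligned")
  if (length(total) < n_quantiles) abort("fewer frames than quantiles")
  bin <- ceiling(rank(total, ties.method = "first") / length(total) *
                   n_quantiles)
  tibble(quantile = seq_len(n_quantiles)) |>
    mutate(mean_activity = vapply(.data$quantile,
                                  function(q) mean(total[bin == q]), 0),
           p_running = vapply(.data$quantile,
                              function(q) mean(speed_cm_s[bin == q] >
                                                 speed_threshold), 0))
}
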