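#' Build a drifting-grating stimulus schedule
#'
#' Constructs the frame-indexed trial structure of a blocked drifting-grating
#' experiment: each block presents `reps_per_block` repetitions of
#' `n_directions` evenly spaced directions in a pseudo-random order, every
#' grating preceded by a mean-luminance grey period. The direction order is
#' drawn once from `seed` and reused in every block, so blocks are
#' frame-aligned repetitions of the same stimulus movie.
#'
#' @param n_blocks number of stimulus blocks (movies).
#' @param n_directions number of evenly spaced grating directions.
#' @param reps_per_block repetitions of each direction within a block.
#' @param grating_dur_s grating presentation duration in seconds.
#' @param grey_dur_s grey-screen duration in seconds.
#' @param frame_rate_hz imaging frame rate in Hz.
#' @param seed integer seed for the direction shuffle.
#' @return A `stim_schedule` object: a list with `trials` (a tibble with
#'   columns `block`, `kind` (`"grey"`/`"grating"`), `direction` (degrees,
#'   `NA` for grey), `onset`, `offset` in 1-based inclusive frames),
#'   `frame_rate_hz`, `n_blocks`, `n_directions`, `reps_per_block`,
#'   `frames_per_block` and `n_frames`.
#' @examples
#' sched <- make_schedule(2, 12, 3, 5, 3, 30, seed = 1)
#' table(sched$trials$kind)
#' @export
make_schedule <- function(n_blocks, n_directions = 12, reps_per_block = 3,
                          grating_dur_s = 5, grey_dur_s = 3,
                          frame_rate_hz = 30, seed = 1) {
  for (nm in c("n_blocks", "n_directions", "reps_per_block",
               "grating_dur_s", "grey_dur_s", "frame_rate_hz")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (n_blocks < 1 || n_directions < 1 || reps_per_block < 1) {
    abort("counts must be >= 1")
  }

  directions <- seq(0, 360, length.out = n_directions + 1)[seq_len(n_directions)]
  # one pseudo-random order of all repetition slots, reused across blocks
  order_all <- with_seed(seed, sample(rep(directions, reps_per_block)))

  grating_frames <- floor(grating_dur_s * frame_rate_hz)
  grey_frames <- floor(grey_dur_s * frame_rate_hz)
  if (grating_frames < 1 || grey_frames < 1) {
    abort("durations too short for the frame rate (empty trial windows)")
  }

  n_slot <- length(order_all)                     # gratings per block
  frames_per_block <- n_slot * (grating_frames + grey_frames)

  block_trials <- function(b) {
    offset0 <- (b - 1L) * frames_per_block
    kind <- rep(c("grey", "grating"), n_slot)
    dur <- rep(c(grey_frames, grating_frames), n_slot)
    onset <- offset0 + cumsum(c(0L, dur[-length(dur)])) + 1L
    tibble(
      block = b,
      kind = kind,
      direction = as.numeric(rbind(NA_real_, order_all)),
      onset = as.integer(onset),
      offset = as.integer(onset + dur - 1L)
    )
  }
  trials <- bind_rows(lapply(seq_len(n_blocks), block_trials))

  structure(
    list(trials = trials,
         frame_rate_hz = frame_rate_hz,
         n_blocks = as.integer(n_blocks),
         n_directions = as.integer(n_directions),
         reps_per_block = as.integer(reps_per_block),
         grating_dur_s = grating_dur_s,
         grey_dur_s = grey_dur_s,
         frames_per_block = as.integer(frames_per_block),
         n_frames = as.integer(n_blocks * frames_per_block),
         direction_order = order_all,
         seed = as.integer(seed)),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %d block(s) x %d directions x %d reps @ %.5g Hz\n",
    x$n_blocks, x$n_directions, x$reps_per_block, x$frame_rate_hz))
  cat(sprintf("  %d frames (%d per block), %d trials\n",
              x$n_frames, x$frames_per_block, nrow(x$trials)))
  invisible(x)
}

# frame indices (relative to block start) of each trial kind; identical for
# every block because the direction order is preserved across blocks
block_relative_frames <- function(schedule, kind = c("all", "grating", "grey")) {
  kind <- match.arg(kind)
  tr <- schedule$trials[schedule$trials$block == 1L, ]
  if (kind != "all") tr <- tr[tr$kind == kind, ]
  unlist(lapply(seq_len(nrow(tr)), function(k) tr$onset[k]:tr$offset[k])) -
    0L  # block 1 onsets are already relative
}

# absolute frame indices of one block
block_frames <- function(schedule, b) {
  (b - 1L) * schedule$frames_per_block + seq_len(schedule$frames_per_block)
}
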