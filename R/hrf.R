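#' Canonical double-gamma hemodynamic response function
#'
#' Difference of a response gamma and a weighted undershoot gamma with
#' the conventional canonical parameterization: response delay 6 s,
#' undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6. The
#' curve is normalized so its peak (evaluated on a fine internal grid)
#' is exactly 1, making it sampling-grid independent.
#'
#' @param t Non-negative, increasing time grid in seconds.
#' @param peak_delay,undershoot_delay Gamma delays, seconds.
#' @param peak_disp,undershoot_disp Gamma dispersions, seconds.
#' @param ratio Undershoot ratio.
#' @return Numeric vector of the unit-peak response sampled at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  if (length(t) == 0L) stop("empty time grid")
  if (any(t < 0) || is.unsorted(t)) stop("time grid must be non-negative and increasing")
  g <- function(tt) {
    stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
      ratio * stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                            scale = undershoot_disp)
  }
  fine <- seq(0, max(32, max(t)), by = 0.01)
  g(t) / max(g(fine))
}

# Convolve a cue train with the canonical HRF on a fine grid and sample
# at frame times. The single-event response (one hold_duration boxcar
# convolved with the HRF) is normalized to unit peak, so an isolated cue
# at amplitude a%% peaks at a/100 in regressor units.
condition_regressor <- function(onsets, tr, n_volumes, hold_duration = 1,
                                dt = 0.1, kernel_duration = 32) {
  tk <- seq(0, kernel_duration, by = dt)
  h <- canonical_hrf(tk)
  box <- rep(1, max(1L, round(hold_duration / dt)))
  event <- stats::convolve(c(box, numeric(length(h))), rev(h), type = "open")
  event <- event / max(event)  # unit-peak single-event response
  run_len <- n_volumes * tr
  n_fine <- ceiling(run_len / dt) + length(event)
  x <- numeric(n_fine)
  for (o in onsets) {
    i0 <- round(o / dt) + 1L
    if (i0 >= 1L && i0 <= n_fine) x[i0] <- x[i0] + 1
  }
  y <- stats::convolve(x, rev(event), type = "open")[seq_len(n_fine)]
  frame_t <- (seq_len(n_volumes) - 1L) * tr
  y[round(frame_t / dt) + 1L]
}

#' Task regressors for both movement conditions
#'
#' @param events An `event_table`.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of acquired frames.
#' @param hold_duration Boxcar width per cue, seconds.
#' @return A `n_volumes` x 2 matrix with columns `extension`, `flexion`
#'   sampled at frame times `(i - 1) * tr`.
#' @export
task_regressors <- function(events, tr = attr(events, "tr"),
                            n_volumes = attr(events, "n_volumes"),
                            hold_duration = 1) {
  validate_events(events)
  sapply(c("extension", "flexion"), function(cond) {
    condition_regressor(events$onset[events$trial_type == cond],
                        tr, n_volumes, hold_duration)
  })
}
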