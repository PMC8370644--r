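#' Specify the noise and artifact model of the simulator
#'
#' The forward model is
#' `baseline * (1 + sum_condition amp%/100 * HRF-convolved cue train)`
#' plus a slow cosine drift, serially correlated (AR(1)) Gaussian noise,
#' and occasional artifact volumes injected as global-signal shifts
#' and/or motion spikes. Innovations have sd `white_sd`; the stationary
#' noise sd is `white_sd / sqrt(1 - ar1_coeff^2)`.
#'
#' @param baseline Mean signal level, scanner units.
#' @param white_sd Innovation sd, scanner units.
#' @param ar1_coeff AR(1) coefficient in `[0, 1)`.
#' @param drift_amp Amplitude of one slow cosine drift, scanner units.
#' @param drift_period Drift period, seconds.
#' @param artifact_rate Probability per acquired volume of an injected
#'   artifact.
#' @param artifact_global_z Size of a global-signal artifact in units of
#'   `white_sd` (an offset of `artifact_global_z * white_sd` is added to
#'   every voxel of the affected frame).
#' @param motion_spike_mm Size of a motion-spike artifact, mm.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(baseline = 1000, white_sd = 10, ar1_coeff = 0.3,
                       drift_amp = 10, drift_period = 1200,
                       artifact_rate = 0.01, artifact_global_z = 6,
                       motion_spike_mm = 1.5) {
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop("ar1_coeff must lie in [0, 1)")
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must lie in [0, 1]")
  structure(list(baseline = baseline, white_sd = white_sd,
                 ar1_coeff = ar1_coeff, drift_amp = drift_amp,
                 drift_period = drift_period, artifact_rate = artifact_rate,
                 artifact_global_z = artifact_global_z,
                 motion_spike_mm = motion_spike_mm),
            class = "noise_spec")
}

#' Construct a BOLD run container
#'
#' @param data 4-D numeric array (x, y, z, time).
#' @param tr Repetition time, seconds.
#' @param voxel_size Voxel edge lengths, mm (length 1 or 3).
#' @param run,subject Optional provenance indices.
#' @param n_dummy Number of leading dummy frames included in `data`.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr, voxel_size = 3, run = NA_integer_,
                     subject = NA_integer_, n_dummy = 0L) {
  if (length(dim(data)) != 4L) stop("BOLD data must be a 4-D array")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(data = data, tr = tr, voxel_size = voxel_size,
                 run = run, subject = subject, n_dummy = as.integer(n_dummy)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %d x %d x %d voxels x %d frames (TR %g s, %g mm%s)\n",
              d[1], d[2], d[3], d[4], x$tr, x$voxel_size[1],
              if (x$n_dummy > 0) sprintf(", %d dummy frame(s)", x$n_dummy) else ""))
  invisible(x)
}

#' Frames entering analysis (dummies stripped)
#'
#' @param run A `bold_run`.
#' @return A `bold_run` whose data contain acquired frames only.
#' @export
acquired_frames <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (run$n_dummy == 0L) return(run)
  d <- dim(run$data)
  run$data <- run$data[, , , (run$n_dummy + 1L):d[4L], drop = FALSE]
  run$n_dummy <- 0L
  run
}

# time x voxel matrix view of a bold run (acquired frames)
bold_matrix <- function(run) {
  run <- acquired_frames(run)
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4L]))
}

#' Simulate one BOLD run from events, ground truth and a noise model
#'
#' Seeded and bit-reproducible. The cue train of each condition is
#' convolved with the canonical HRF (unit-peak single-event response),
#' scaled by the voxel's ground-truth percent amplitude, and laid on the
#' baseline; drift, AR(1) noise and artifact volumes are then added.
#' Artifact volumes (the true injection log is returned for oracle
#' testing) receive a global-signal offset and/or a translational motion
#' spike, depending on which mechanisms are enabled in `noise`.
#'
#' @param events An `event_table` (onsets relative to the first acquired
#'   volume).
#' @param truth A `ground_truth` object on the grid to simulate.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param run Run index recorded in the output.
#' @param keep_dummies If `TRUE`, `n_dummy` leading steady-state frames
#'   (from the design attributes of `events`) are retained in the data.
#' @return A `sim_run` list: `bold` (a `bold_run`), `motion`
#'   (`n_volumes` x 6 matrix: 3 translations mm, 3 rotations rad),
#'   `artifacts` (data frame of injected volume indices and types),
#'   `regressors` (the condition regressors used, for forward-model
#'   oracles).
#' @export
simulate_run <- function(events, truth, noise = noise_spec(), seed = 1L,
                         run = 1L, keep_dummies = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  validate_events(events)
  set.seed(seed)
  tr <- attr(events, "tr")
  n_vol <- attr(events, "n_volumes")
  n_dummy <- if (keep_dummies) attr(events, "n_dummy") %||% 0L else 0L
  dim3 <- truth$params$grid_shape
  nvox <- prod(dim3)
  total <- n_dummy + n_vol

  reg <- task_regressors(events, tr, n_vol)
  amp <- cbind(as.vector(truth$amp_ext), as.vector(truth$amp_flex)) / 100
  active <- which(rowSums(amp) > 0)

  # acquired-frame signal matrix, time x voxel
  y <- matrix(noise$baseline, total, nvox)
  if (length(active) > 0L && n_vol > 0L) {
    task <- reg %*% t(amp[active, , drop = FALSE])  # n_vol x n_active
    y[(n_dummy + 1L):total, active] <-
      y[(n_dummy + 1L):total, active] + noise$baseline * task
  }
  tt <- ((1:total) - n_dummy - 1L) * tr  # dummy frames sit before t = 0
  if (noise$drift_amp != 0) {
    # one slow cosine per voxel with random phase: scanner/physiological
    # drift varies spatially, so coherence across voxels is not imposed
    phase <- stats::runif(nvox, 0, 2 * pi)
    y <- y + noise$drift_amp *
      cos(outer(2 * pi * tt / noise$drift_period, phase, `+`))
  }
  if (noise$white_sd > 0) {
    e <- matrix(stats::rnorm(total * nvox, 0, noise$white_sd), total, nvox)
    if (noise$ar1_coeff > 0)
      for (t in 2:total) e[t, ] <- noise$ar1_coeff * e[t - 1L, ] + e[t, ]
    y <- y + e
  }

  # gentle motion wander well below the artifact thresholds
  motion <- apply(matrix(stats::rnorm(n_vol * 6L, 0,
                                      rep(c(0.02, 0.0003), each = n_vol * 3L)),
                         n_vol, 6L), 2L, cumsum)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

  mechanisms <- c("global", "motion")[c(noise$artifact_global_z > 0,
                                        noise$motion_spike_mm > 0)]
  artifacts <- data.frame(volume = integer(0), type = character(0))
  if (noise$artifact_rate > 0 && length(mechanisms) > 0L) {
    hit <- which(stats::runif(n_vol) < noise$artifact_rate)
    # the first volume's framewise displacement is 0 by definition, so a
    # motion artifact there would be undetectable by construction
    hit <- hit[hit > 1L]
    if (length(hit) > 0L) {
      type <- sample(mechanisms, length(hit), replace = TRUE)
      artifacts <- data.frame(volume = hit, type = type)
      for (i in seq_along(hit)) {
        v <- hit[i]
        if (type[i] == "global")
          y[n_dummy + v, ] <- y[n_dummy + v, ] +
            noise$artifact_global_z * noise$white_sd
        else  # abrupt head repositioning: a step that persists
          motion[v:n_vol, "tx"] <- motion[v:n_vol, "tx"] + noise$motion_spike_mm
      }
    }
  }

  bold <- bold_run(array(t(y), c(dim3, total)), tr = tr,
                   voxel_size = truth$params$voxel_size, run = run,
                   subject = truth$subject, n_dummy = n_dummy)
  structure(list(bold = bold, motion = motion, artifacts = artifacts,
                 regressors = reg, events = events, seed = seed),
            class = "sim_run")
}

#' Simulate all runs of one subject
#'
#' @param spec A [design_spec()].
#' @param truth The subject's `ground_truth`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; run seeds are derived per run.
#' @return List of `sim_run` objects, one per run.
#' @export
simulate_subject <- function(spec, truth, noise = noise_spec(), seed = 1L) {
  events <- make_design(spec, seed = derive_seed(seed, "design"))
  lapply(seq_len(spec$n_runs), function(r) {
    simulate_run(events[[r]], truth, noise,
                 seed = derive_seed(seed, paste0("run", r)), run = r)
  })
}

#' Simulate a multi-subject dataset
#'
#' @param spec A [design_spec()].
#' @param params A [truth_params()].
#' @param noise A [noise_spec()].
#' @param n_subjects Number of subjects.
#' @param seed Integer global seed.
#' @return List with `truth` (per-subject ground truths) and `subjects`
#'   (per-subject lists of `sim_run`s).
#' @export
simulate_dataset <- function(spec = design_spec(), params = truth_params(),
                             noise = noise_spec(), n_subjects = 10L,
                             seed = 1L) {
  truth <- make_ground_truth(params, n_subjects,
                             seed = derive_seed(seed, "truth"))
  subjects <- lapply(seq_len(n_subjects), function(s) {
    simulate_subject(spec, truth[[s]], noise,
                     seed = derive_seed(seed, paste0("subject", s)))
  })
  list(truth = truth, subjects = subjects)
}
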