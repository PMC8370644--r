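#' Rest baseline from the flanking rest periods
#'
#' Baseline per voxel = (median of the preceding rest period + median of
#' the subsequent rest period) / 2, with the first `trim` volumes of
#' each rest discarded to let the hemodynamic response wash out.
#'
#' @param series Time x voxel matrix (or vector) of one run.
#' @param rest_pre,rest_post Numeric `c(start, end)` in seconds.
#' @param tr Repetition time, seconds.
#' @param trim Volumes trimmed from the start of each rest (default 2).
#' @return Numeric baseline per voxel.
#' @export
rest_baseline <- function(series, rest_pre, rest_post, tr, trim = 2L) {
  x <- as.matrix(series)
  window <- function(iv) {
    v <- which((seq_len(nrow(x)) - 1L) * tr >= iv[1L] &
               (seq_len(nrow(x)) - 1L) * tr < iv[2L])
    if (length(v) > trim) v <- v[-seq_len(trim)]
    if (length(v) < 3L) stop("rest window too short after transition trimming")
    v
  }
  pre <- apply(x[window(rest_pre), , drop = FALSE], 2L, stats::median)
  post <- apply(x[window(rest_post), , drop = FALSE], 2L, stats::median)
  b <- (pre + post) / 2
  if (is.null(dim(series))) b <- drop(b)
  b
}

#' Percent-signal-change maps for one run
#'
#' The run is linearly detrended (mean preserved); per condition, the
#' signal is the mean voxel time course over that condition's block
#' period and the baseline is [rest_baseline()] from the block's
#' flanking rests; PSC = 100 x (signal - baseline) / baseline. The
#' per-voxel difference is extension minus flexion. Voxels with
#' non-positive baseline are masked and logged.
#'
#' @param run A `bold_run` (or `sim_run`).
#' @param events The run's `event_table` (block and rest annotations
#'   required; taken from a `sim_run` automatically).
#' @param active_mask Logical mask of voxels to evaluate -- by
#'   convention the union of suprathreshold voxels from the two
#'   movement-versus-rest t maps at p < 0.001.
#' @param detrend Apply [linear_detrend()] first (default `TRUE`).
#' @param trim Rest volumes trimmed before the median.
#' @return A `psc_map`: 3-D arrays `psc_ext`, `psc_flex`, `diff`
#'   (`NA` outside the mask), plus `run` and the count of
#'   baseline-masked voxels.
#' @export
psc_maps <- function(run, events = NULL, active_mask, detrend = TRUE,
                     trim = 2L) {
  if (inherits(run, "sim_run")) {
    if (is.null(events)) events <- run$events
    run <- run$bold
  }
  stopifnot(inherits(run, "bold_run"))
  blocks <- event_blocks(events)
  rests <- event_rests(events)
  if (is.null(blocks) || is.null(rests))
    stop("events must carry block and rest annotations")
  run <- acquired_frames(run)
  dims <- dim(run$data)[1:3]
  vox <- which(as.vector(active_mask))
  if (length(vox) == 0L) stop("active mask is empty")
  y <- bold_matrix(run)[, vox, drop = FALSE]
  if (detrend) y <- linear_detrend(y)
  tr <- run$tr
  frame_t <- (seq_len(nrow(y)) - 1L) * tr
  psc <- matrix(NA_real_, length(vox), 2L,
                dimnames = list(NULL, c("extension", "flexion")))
  n_masked <- 0L
  for (b in seq_len(nrow(blocks))) {
    iv <- c(blocks$start[b], blocks$end[b])
    pre <- rests[rests$end <= iv[1L] + 1e-9, , drop = FALSE]
    post <- rests[rests$start >= iv[2L] - 1e-9, , drop = FALSE]
    if (nrow(pre) == 0L || nrow(post) == 0L)
      stop("block ", b, " lacks a flanking rest period")
    pre <- as.numeric(pre[which.max(pre$end), c("start", "end")])
    post <- as.numeric(post[which.min(post$start), c("start", "end")])
    base <- rest_baseline(y, pre, post, tr, trim)
    sig <- colMeans(y[frame_t >= iv[1L] & frame_t < iv[2L], , drop = FALSE])
    bad <- base <= 0
    n_masked <- n_masked + sum(bad & !is.na(base))
    val <- ifelse(bad, NA_real_, 100 * (sig - base) / base)
    psc[, blocks$condition[b]] <- val
  }
  as_map <- function(v) { a <- array(NA_real_, dims); a[vox] <- v; a }
  structure(list(psc_ext = as_map(psc[, "extension"]),
                 psc_flex = as_map(psc[, "flexion"]),
                 diff = as_map(psc[, "extension"] - psc[, "flexion"]),
                 run = run$run, n_baseline_masked = n_masked),
            class = "psc_map")
}

#' Session-average difference map across runs
#'
#' @param psc_list List of `psc_map`s from one subject's runs.
#' @return 3-D array: mean of per-run extension-minus-flexion
#'   differences.
#' @export
session_average <- function(psc_list) {
  stopifnot(length(psc_list) >= 1L)
  Reduce(`+`, lapply(psc_list, `[[`, "diff")) / length(psc_list)
}

#' Binary extension-preference labels for one run
#'
#' 1 iff the extension-minus-flexion PSC difference is strictly
#' positive, 0 otherwise (ties get 0).
#'
#' @param psc A `psc_map`, or a numeric difference array.
#' @return Integer array of 0/1 labels (`NA` outside the active mask).
#' @export
preference_labels <- function(psc) {
  d <- if (inherits(psc, "psc_map")) psc$diff else psc
  lab <- array(NA_integer_, dim(d) %||% length(d))
  lab[!is.na(d)] <- as.integer(d[!is.na(d)] > 0)
  lab
}

#' Run-to-run preference consistency against a binomial null
#'
#' Sums each voxel's binary extension-preference label across runs and
#' tabulates the observed frequency of sums 0..n_runs as percentages of
#' active-mask voxels, next to the binomial(n_runs, 1/2) null expected
#' under random assignment.
#'
#' @param binary_maps List (length >= 2) of per-run 0/1 label arrays on
#'   a common mask.
#' @return A `consistency_result`: per-voxel `sums`, `histogram` data
#'   frame (`k`, `observed_pct`, `null_pct`), `n_runs`, `n_voxels`.
#' @export
run_consistency <- function(binary_maps) {
  if (length(binary_maps) < 2L) stop("need at least 2 runs")
  masks <- lapply(binary_maps, function(m) which(!is.na(m)))
  if (!all(vapply(masks, identical, logical(1), masks[[1L]])))
    stop("runs must share a common active mask")
  vox <- masks[[1L]]
  n_runs <- length(binary_maps)
  sums <- Reduce(`+`, lapply(binary_maps, function(m) m[vox]))
  k <- 0:n_runs
  obs <- vapply(k, function(kk) mean(sums == kk), numeric(1)) * 100
  null <- stats::dbinom(k, n_runs, 0.5) * 100
  structure(list(sums = sums,
                 histogram = data.frame(k = k, observed_pct = obs,
                                        null_pct = null),
                 n_runs = n_runs, n_voxels = length(vox)),
            class = "consistency_result")
}

#' Kolmogorov-Smirnov comparison of observed sums to the binomial null
#'
#' One-sample KS of the observed sums' empirical CDF against the
#' binomial(n_runs, 1/2) CDF: the statistic is the maximum CDF gap over
#' the discrete support. The p-value uses the asymptotic Kolmogorov
#' distribution, which is conservative on discrete data; an exact
#' multinomial goodness-of-fit (chi-square with simulated p) is
#' reported as a cross-check.
#'
#' @param result A `consistency_result`.
#' @param n_sim Simulation count for the chi-square cross-check.
#' @return List with `statistic`, `p_value`, `p_chisq`, `n`.
#' @export
ks_vs_binomial <- function(result, n_sim = 2000L) {
  stopifnot(inherits(result, "consistency_result"))
  if (result$n_runs < 2L) stop("degenerate support: need >= 2 runs")
  k <- 0:result$n_runs
  n <- result$n_voxels
  obs_cdf <- vapply(k, function(kk) mean(result$sums <= kk), numeric(1))
  null_cdf <- stats::pbinom(k, result$n_runs, 0.5)
  d <- max(abs(obs_cdf - null_cdf))
  counts <- vapply(k, function(kk) sum(result$sums == kk), numeric(1))
  chisq <- suppressWarnings(
    stats::chisq.test(counts, p = stats::dbinom(k, result$n_runs, 0.5),
                      simulate.p.value = TRUE, B = n_sim))
  list(statistic = d, p_value = kolmogorov_p(d, n),
       p_chisq = chisq$p.value, n = n)
}

#' Signed preference image and per-ROI preference counts
#'
#' @param session_avg Session-average difference array (from
#'   [session_average()]).
#' @param rois Named list of logical masks.
#' @return List with `image` (the signed difference restricted to the
#'   active mask) and `table` (per-ROI counts of extension- and
#'   flexion-preferring voxels).
#' @export
heatmap_export <- function(session_avg, rois) {
  tab <- do.call(rbind, lapply(names(rois), function(nm) {
    v <- session_avg[rois[[nm]]]
    v <- v[!is.na(v)]
    data.frame(roi = nm, n_active = length(v),
               n_extension = sum(v > 0), n_flexion = sum(v < 0))
  }))
  list(image = session_avg, table = tab)
}
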