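#' Flag artifact volumes from global signal and motion
#'
#' A volume is flagged iff its global-mean standard score exceeds 3 in
#' absolute value, or its framewise translational displacement exceeds
#' 0.9 mm, or its framewise rotational displacement exceeds 0.01 rad.
#' Framewise displacement is the absolute difference between consecutive
#' volumes (maximum over the three translation or the three rotation
#' parameters); the first volume's displacement is defined as 0.
#' Standard scores are computed on the within-run global-mean time
#' series after removing its own mean and sd.
#'
#' @param run A `bold_run` (dummy frames, if present, are ignored).
#' @param motion `n_volumes` x 6 matrix: translations (mm) then
#'   rotations (rad).
#' @param z_thresh,trans_thresh_mm,rot_thresh_rad Flagging thresholds.
#' @return An `artifact_report`: data frame `flags` (`volume`,
#'   `reason` in `{global_z, translation, rotation}`), plus per-volume
#'   traces `global_z`, `fd_trans`, `fd_rot` and `n_volumes`.
#' @export
detect_artifacts <- function(run, motion, z_thresh = 3,
                             trans_thresh_mm = 0.9, rot_thresh_rad = 0.01) {
  y <- bold_matrix(run)
  n <- nrow(y)
  if (!is.matrix(motion) || ncol(motion) != 6L || nrow(motion) != n)
    stop("motion trace must have 6 columns and one row per acquired volume")
  g <- rowMeans(y)
  # robust center/scale (median, 1.4826*MAD) so a handful of large
  # outliers cannot mask themselves by inflating the scale estimate
  s <- stats::mad(g)
  if (is.na(s) || s == 0) s <- stats::sd(g)
  gz <- if (is.na(s) || s == 0) rep(0, n) else (g - stats::median(g)) / s
  fd <- function(m) c(0, apply(abs(diff(m)), 1L, max))
  fd_t <- fd(motion[, 1:3, drop = FALSE])
  fd_r <- fd(motion[, 4:6, drop = FALSE])
  # reason priority: global signal, then translation, then rotation
  reason <- rep(NA_character_, n)
  reason[fd_r > rot_thresh_rad] <- "rotation"
  reason[fd_t > trans_thresh_mm] <- "translation"
  reason[abs(gz) > z_thresh] <- "global_z"
  flagged <- which(!is.na(reason))
  structure(list(flags = data.frame(volume = flagged, reason = reason[flagged]),
                 global_z = gz, fd_trans = fd_t, fd_rot = fd_r,
                 n_volumes = n),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("artifact report: %d/%d volume(s) flagged\n",
              nrow(x$flags), x$n_volumes))
  invisible(x)
}

#' Run and subject exclusion by artifact load
#'
#' A run is excluded iff its flagged fraction reaches
#' `threshold_fraction` (default 46/116, so 46 flagged volumes of 116
#' excludes the run); a subject is excluded iff every run is excluded.
#'
#' @param reports List of `artifact_report`s (one subject's runs), or a
#'   list of such lists (several subjects).
#' @param threshold_fraction Exclusion threshold in `(0, 1]`.
#' @return For one subject: data frame with per-run `n_flagged`,
#'   `fraction`, `excluded`, plus attribute `subject_excluded`. For
#'   several subjects: list of these.
#' @export
exclude_runs <- function(reports, threshold_fraction = 46 / 116) {
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]")
  if (length(reports) > 0L && !inherits(reports[[1L]], "artifact_report"))
    return(lapply(reports, exclude_runs, threshold_fraction = threshold_fraction))
  frac <- vapply(reports, function(r) nrow(r$flags) / r$n_volumes, numeric(1))
  out <- data.frame(run = seq_along(reports),
                    n_flagged = vapply(reports, function(r) nrow(r$flags), integer(1)),
                    fraction = frac,
                    excluded = frac >= threshold_fraction)
  attr(out, "subject_excluded") <- all(out$excluded)
  out
}

#' Discrete-cosine-transform high-pass filter
#'
#' Removes the span of the low-frequency cosine basis with period longer
#' than `cutoff_s` (`k = floor(2 * n * tr / cutoff_s)` regressors) plus
#' the mean, by residualization -- equivalent to including the basis as
#' confounds in a GLM, which is how the univariate arm consumes it.
#'
#' @param series Numeric vector, or time x voxel matrix.
#' @param tr Repetition time, seconds.
#' @param cutoff_s High-pass cutoff period, seconds (default 128).
#' @return List with `filtered` (same shape as input), `basis`
#'   (n x k matrix of retained drift regressors, without intercept) and
#'   `k`.
#' @export
dct_highpass <- function(series, tr, cutoff_s = 128) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 2L) stop("series must have length >= 2")
  if (cutoff_s <= 2 * tr) stop("cutoff must exceed 2 * tr for a valid basis")
  k <- floor(2 * n * tr / cutoff_s)
  basis <- dct_basis(n, k)
  q <- qr.Q(qr(cbind(1, basis)))
  filt <- x - q %*% crossprod(q, x)
  if (is.null(dim(series))) filt <- drop(filt)
  list(filtered = filt, basis = basis, k = k)
}

# DCT-II drift regressors r = 1..k (unit-norm up to scaling)
dct_basis <- function(n, k) {
  if (k < 1L) return(matrix(numeric(0), n, 0))
  t0 <- 0:(n - 1L)
  sapply(seq_len(k), function(r) cos(pi * (2 * t0 + 1) * r / (2 * n)))
}

#' Gaussian running-line high-pass filter
#'
#' At each time point a straight line is fitted to the whole series by
#' weighted least squares with Gaussian weights centered at that point
#' (FWHM = `fwhm_trs` TRs, 80 by default, i.e. 240 s at TR 3 s), and the
#' fitted value is subtracted; weights renormalize automatically at the
#' edges. This is the nonlinear running-line detrend used before
#' multivariate feature extraction.
#'
#' @param series Numeric vector, or time x voxel matrix.
#' @param tr Repetition time, seconds (retained for interface symmetry;
#'   the width is specified in TRs).
#' @param fwhm_trs Full width at half maximum of the weight kernel, TRs.
#' @return Filtered series, same shape as input.
#' @export
gaussian_runline_detrend <- function(series, tr = 3, fwhm_trs = 80) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) stop("series must have length >= 3")
  s <- runline_smoother(n, fwhm_trs)
  filt <- x - s %*% x
  if (is.null(dim(series))) filt <- drop(filt)
  filt
}

# n x n local-linear smoother matrix with Gaussian weights
runline_smoother <- function(n, fwhm_trs) {
  sd <- fwhm_to_sd(fwhm_trs)
  tt <- seq_len(n)
  s <- matrix(0, n, n)
  for (i in tt) {
    w <- stats::dnorm(tt, i, sd)
    w <- w / sum(w)
    d <- tt - i
    sw_d <- sum(w * d); sw_d2 <- sum(w * d^2)
    denom <- sw_d2 - sw_d^2
    # fitted value at center of a weighted straight-line fit
    s[i, ] <- w * (1 + (0 - sw_d) * (d - sw_d) / denom)
  }
  s
}

#' Ordinary linear detrend, mean preserved
#'
#' Removes the least-squares straight line per voxel and re-adds the
#' mean, so percent-signal-change baselines remain meaningful.
#'
#' @param series Numeric vector, or time x voxel matrix.
#' @return Detrended series, same shape as input.
#' @export
linear_detrend <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  t0 <- seq_len(n) - (n + 1) / 2           # centered time
  slope <- crossprod(t0, x) / sum(t0^2)
  out <- x - outer(t0, drop(slope))
  if (is.null(dim(series))) out <- drop(out)
  out
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3-D volume with a separable Gaussian kernel
#' (sd = fwhm / (2 sqrt(2 ln 2)) per axis, in mm). Boundaries are
#' handled by reflection, which conserves the volume sum.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Full width at half maximum, mm; 0 is the identity.
#' @param voxel_size Voxel edge lengths, mm (length 1 or 3).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_spatial <- function(volume, fwhm_mm = 6, voxel_size = 3) {
  stopifnot(length(dim(volume)) == 3L)
  if (fwhm_mm == 0) return(volume)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  out <- volume
  for (axis in 1:3) {
    sd_vox <- fwhm_to_sd(fwhm_mm) / voxel_size[axis]
    r <- max(1L, ceiling(4 * sd_vox))
    kern <- stats::dnorm(-r:r, 0, sd_vox)
    kern <- kern / sum(kern)
    out <- smooth_axis(out, kern, axis)
  }
  out
}

smooth_axis <- function(arr, kern, axis) {
  n <- dim(arr)[axis]
  r <- (length(kern) - 1L) / 2L
  out <- array(0, dim(arr))
  for (o in -r:r) {
    idx <- seq_len(n) + o
    # half-sample reflection: with a symmetric kernel this conserves the
    # volume sum exactly (every kernel tap folds back into the grid)
    idx <- ifelse(idx < 1L, 1L - idx, ifelse(idx > n, 2L * n + 1L - idx, idx))
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kern[o + r + 1L] * shifted
  }
  out
}
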