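#' Assemble a first-level GLM design matrix
#'
#' Columns, in order: HRF-convolved extension and flexion regressors
#' (boxcar cue trains convolved with the canonical HRF, sampled at frame
#' times), six motion confounds (if supplied), one one-hot spike column
#' per artifact-flagged volume, the DCT drift basis (if `hp = "dct"`),
#' and an intercept.
#'
#' @param events An `event_table`.
#' @param motion Optional `n_volumes` x 6 motion-parameter matrix.
#' @param artifact_report Optional `artifact_report` whose flagged
#'   volumes become spike regressors.
#' @param tr,n_volumes Sampling parameters (default from `events`).
#' @param hp `"dct"` (default) or `"none"`.
#' @param cutoff_s DCT high-pass cutoff, seconds.
#' @param hold_duration Cue boxcar width, seconds.
#' @return A `design_matrix`: list with `X`, `labels`, `frame_times`.
#' @export
build_design_matrix <- function(events, motion = NULL, artifact_report = NULL,
                                tr = attr(events, "tr"),
                                n_volumes = attr(events, "n_volumes"),
                                hp = c("dct", "none"), cutoff_s = 128,
                                hold_duration = 1) {
  hp <- match.arg(hp)
  reg <- task_regressors(events, tr, n_volumes, hold_duration)
  parts <- list(extension = reg[, "extension"], flexion = reg[, "flexion"])
  if (!is.null(motion)) {
    if (nrow(motion) != n_volumes || ncol(motion) != 6L)
      stop("motion trace must be n_volumes x 6")
    m <- as.matrix(motion)
    colnames(m) <- paste0("motion", 1:6)
    parts$motion <- m
  }
  if (!is.null(artifact_report) && nrow(artifact_report$flags) > 0L) {
    vols <- artifact_report$flags$volume
    spikes <- matrix(0, n_volumes, length(vols))
    spikes[cbind(vols, seq_along(vols))] <- 1
    colnames(spikes) <- sprintf("spike%03d", vols)
    parts$spikes <- spikes
  }
  if (hp == "dct") {
    k <- floor(2 * n_volumes * tr / cutoff_s)
    if (k > 0L) {
      b <- dct_basis(n_volumes, k)
      colnames(b) <- paste0("dct", seq_len(k))
      parts$dct <- b
    }
  }
  parts$intercept <- rep(1, n_volumes)
  X <- do.call(cbind, parts)
  colnames(X)[1:2] <- c("extension", "flexion")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, labels = colnames(X),
                 frame_times = (seq_len(n_volumes) - 1L) * tr),
            class = "design_matrix")
}

#' Fit the mass-univariate GLM by ordinary least squares
#'
#' @param Y A `bold_run`, or a time x voxel numeric matrix.
#' @param X A `design_matrix` or plain numeric matrix with column names.
#' @param mask Optional logical analysis mask (3-D array or vector).
#'   For `bold_run` input, defaults to the implicit mask: voxels whose
#'   mean signal exceeds 10% of the grand mean. For matrix input,
#'   defaults to all voxels.
#' @return A `glm_fit`: per-voxel coefficients, residual variance
#'   (`RSS / df`), degrees of freedom `n - rank(X)`, and geometry
#'   metadata used by downstream maps.
#' @export
fit_glm <- function(Y, X, mask = NULL) {
  geom <- NULL
  if (inherits(Y, "bold_run")) {
    geom <- list(dim = dim(Y$data)[1:3], voxel_size = Y$voxel_size)
    y <- bold_matrix(Y)
  } else {
    y <- as.matrix(Y)
  }
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (nrow(Xm) != nrow(y)) stop("rows of Y and X must match")
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qrx$pivot[(qrx$rank + 1L):ncol(Xm)]] %||% "unnamed"
    stop("singular design matrix; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(mask)) {
    mask <- if (!is.null(geom)) colMeans(y) > 0.1 * mean(y)
            else rep(TRUE, ncol(y))
  }
  mask <- as.logical(mask)
  beta <- qr.coef(qrx, y)
  resid <- y - Xm %*% beta
  df <- nrow(Xm) - qrx$rank
  sigma2 <- colSums(resid^2) / df
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  structure(list(coef = beta, sigma2 = sigma2, df = df,
                 xtx_inv = xtx_inv, labels = colnames(Xm),
                 mask = mask, geom = geom, n = nrow(Xm)),
            class = "glm_fit")
}

# resolve a named contrast to a numeric vector over design columns
contrast_vector <- function(fit, contrast) {
  if (is.numeric(contrast)) {
    if (length(contrast) != length(fit$labels))
      stop("contrast length must equal the number of design columns")
    return(contrast)
  }
  cv <- numeric(length(fit$labels))
  names(cv) <- fit$labels
  switch(contrast,
         "ext>rest"  = { cv["extension"] <- 1 },
         "flex>rest" = { cv["flexion"] <- 1 },
         "ext>flex"  = { cv["extension"] <- 1; cv["flexion"] <- -1 },
         "flex>ext"  = { cv["flexion"] <- 1; cv["extension"] <- -1 },
         stop("unknown contrast: ", contrast))
  cv
}

#' Contrast t-statistic map
#'
#' Computes `t = c'b / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel. Voxels
#' outside the analysis mask, or with zero residual variance, are set to
#' t = 0 and recorded in the `masked_voxels` attribute rather than
#' propagating non-finite values. Movement-versus-rest contrasts are
#' one-sided (`greater`); the two between-movement contrasts are
#' two-sided.
#'
#' @param fit A `glm_fit`.
#' @param contrast One of `"ext>rest"`, `"flex>rest"`, `"ext>flex"`,
#'   `"flex>ext"`, or a numeric contrast vector.
#' @return A `stat_map`: `t` (3-D array when geometry is known, else a
#'   vector), `df`, `contrast`, `alternative`.
#' @export
contrast_tmap <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  cv <- contrast_vector(fit, contrast)
  label <- if (is.character(contrast)) contrast else "custom"
  eff <- drop(cv %*% fit$coef)
  quad <- drop(t(cv) %*% fit$xtx_inv %*% cv)
  se <- sqrt(fit$sigma2 * quad)
  bad <- se == 0 | !is.finite(se) | !fit$mask
  t <- ifelse(bad, 0, eff / ifelse(se == 0, 1, se))
  alternative <- if (label %in% c("ext>rest", "flex>rest")) "greater" else "two.sided"
  new_stat_map(t, fit$df, label, alternative, fit$geom,
               masked_voxels = which(se == 0 & fit$mask))
}

new_stat_map <- function(t, df, contrast, alternative, geom,
                         masked_voxels = integer(0)) {
  if (!is.null(geom)) t <- array(t, geom$dim)
  structure(list(t = t, df = df, contrast = contrast,
                 alternative = alternative,
                 voxel_size = geom$voxel_size %||% NA_real_,
                 dim = geom$dim %||% NULL),
            masked_voxels = masked_voxels, class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat map '%s' (%s), df = %g, %d voxel(s), t range [%.2f, %.2f]\n",
              x$contrast, x$alternative, x$df, length(x$t),
              min(x$t), max(x$t)))
  invisible(x)
}

# forming t threshold for a stat map at voxel-level p
forming_threshold <- function(df, forming_p, alternative = "greater") {
  if (alternative == "greater") stats::qt(1 - forming_p, df)
  else stats::qt(1 - forming_p / 2, df)
}

suprathreshold_idx <- function(map, forming_p) {
  thr <- forming_threshold(map$df, forming_p, map$alternative)
  if (map$alternative == "greater") which(map$t > thr) else which(abs(map$t) > thr)
}

#' One-sample group t map across subjects
#'
#' @param maps List (length >= 2) of per-subject contrast maps: 3-D
#'   arrays or numeric vectors on a common grid.
#' @param contrast,alternative Labels attached to the output.
#' @param voxel_size Voxel edge, mm, used by cluster extent reporting.
#' @return A `stat_map` with `df = n_subjects - 1`. Voxels with zero
#'   between-subject variance are set to t = 0 and listed in the
#'   `zero_variance` attribute.
#' @export
group_ttest <- function(maps, contrast = "group", alternative = "greater",
                        voxel_size = 3) {
  if (length(maps) < 2L) stop("group t-test needs at least 2 subjects")
  dims <- dim(maps[[1L]])
  m <- do.call(rbind, lapply(maps, as.vector))
  n <- nrow(m)
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1L))
  zero <- s == 0
  t <- ifelse(zero, 0, mu / (ifelse(zero, 1, s) / sqrt(n)))
  geom <- if (!is.null(dims)) list(dim = dims, voxel_size = rep(voxel_size, 3L)) else NULL
  out <- new_stat_map(t, n - 1L, contrast, alternative, geom)
  attr(out, "zero_variance") <- which(zero)
  out
}

#' Cluster-extent thresholding with permutation FWE control
#'
#' Suprathreshold voxels (voxel-level p < `forming_p` under the map's
#' sidedness) are grouped into 18-connected components. The critical
#' extent is the smallest cluster size whose probability under the
#' max-cluster-extent null distribution is at most `alpha`. The null is
#' obtained by sign-flipping the per-subject contrast maps (exact under
#' exchangeability; the identity flip is included), or, when no subject
#' maps are available, by simulating Gaussian null fields of matched
#' smoothness (an approximation for single-subject maps).
#'
#' @param map A `stat_map` on a 3-D grid (e.g. from [group_ttest()]).
#' @param forming_p Cluster-forming voxel-level p (default 0.001).
#' @param alpha Family-wise error level for cluster extent.
#' @param n_perm Number of sign-flip permutations (warns below 100).
#' @param seed Integer seed for the permutation stream.
#' @param subject_maps List of per-subject contrast maps; when supplied,
#'   `map` may be omitted and is recomputed as the group one-sample t.
#' @param connectivity 6, 18 (default) or 26.
#' @param smoothness_fwhm_vox Smoothness (voxels) for the simulated
#'   single-subject null; estimated from the map when `NULL`.
#' @return A `cluster_result`: `clusters` data frame (size, extent mm^3,
#'   peak t, cluster p, survives), `critical_extent_mm3`,
#'   `forming_p`, `alpha`, `method`, and the null max-extent sample.
#' @export
cluster_threshold <- function(map = NULL, forming_p = 0.001, alpha = 0.05,
                              n_perm = 1000L, seed = 1L, subject_maps = NULL,
                              connectivity = 18L, smoothness_fwhm_vox = NULL) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null distribution")
  if (is.null(map) && is.null(subject_maps))
    stop("either a stat map or subject-level maps must be supplied")
  if (is.null(map))
    map <- group_ttest(subject_maps)
  if (is.null(map$dim)) stop("cluster analysis needs a 3-D map")
  dims <- map$dim
  vox_mm3 <- prod(if (all(is.na(map$voxel_size))) rep(3, 3) else map$voxel_size)
  two_sided <- map$alternative != "greater"

  obs_idx <- suprathreshold_idx(map, forming_p)
  clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                         extent_mm3 = numeric(0), peak_t = numeric(0),
                         p_fwe = numeric(0), survives = logical(0))
  if (length(obs_idx) > 0L) {
    lab <- label_clusters(obs_idx, dims, connectivity)
    peak <- tapply(abs(map$t[obs_idx]), lab, max)
    size <- tabulate(lab)
    clusters <- data.frame(cluster = seq_along(size), n_voxels = size,
                           extent_mm3 = size * vox_mm3, peak_t = as.numeric(peak))
  }

  set.seed(seed)
  if (!is.null(subject_maps)) {
    method <- "sign-flip permutation"
    m <- do.call(rbind, lapply(subject_maps, as.vector))
    n <- nrow(m)
    df <- n - 1L
    thr <- forming_threshold(df, forming_p,
                             if (two_sided) "two.sided" else "greater")
    ss <- colSums(m^2)  # invariant under sign flips
    signs <- matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
                    n_perm - 1L, n)
    signs <- rbind(rep(1, n), signs)  # identity flip first
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      mu <- drop(signs[p, ] %*% m) / n
      v <- pmax(ss - n * mu^2, 0) / (n - 1L)
      tp <- ifelse(v == 0, 0, mu / sqrt(v / n))
      idx <- if (two_sided) which(abs(tp) > thr) else which(tp > thr)
      null_max[p] <- max_cluster_size(idx, dims, connectivity)
    }
  } else {
    method <- "smoothness-matched Gaussian simulation"
    fwhm <- smoothness_fwhm_vox %||% estimate_smoothness(map$t)
    zthr <- if (two_sided) stats::qnorm(1 - forming_p / 2) else stats::qnorm(1 - forming_p)
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      f <- smooth_spatial(array(stats::rnorm(prod(dims)), dims),
                          fwhm_mm = fwhm, voxel_size = 1)
      f <- f / stats::sd(f)
      idx <- if (two_sided) which(abs(f) > zthr) else which(f > zthr)
      null_max[p] <- max_cluster_size(idx, dims, connectivity)
    }
  }

  # smallest extent with null max-cluster probability <= alpha
  sizes <- sort(unique(c(0L, null_max))) + 1L
  exceed <- vapply(sizes, function(s) mean(null_max >= s), numeric(1))
  crit_vox <- if (any(exceed <= alpha)) min(sizes[exceed <= alpha]) else Inf
  if (nrow(clusters) > 0L) {
    clusters$p_fwe <- vapply(clusters$n_voxels,
                             function(s) mean(null_max >= s), numeric(1))
    clusters$survives <- clusters$p_fwe <= alpha
  }
  structure(list(clusters = clusters,
                 critical_extent_mm3 = crit_vox * vox_mm3,
                 critical_extent_voxels = crit_vox,
                 forming_p = forming_p, alpha = alpha, method = method,
                 null_max_extent = null_max, connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster result (%s): %d cluster(s), %d surviving; critical extent %s mm^3\n",
              x$method, nrow(x$clusters), sum(x$clusters$survives %||% FALSE),
              format(x$critical_extent_mm3)))
  invisible(x)
}

# Gaussian-field smoothness (FWHM, voxels) from gradient variance
estimate_smoothness <- function(vol) {
  v <- stats::var(as.vector(vol))
  if (v == 0) return(1)
  fw <- numeric(3)
  for (axis in 1:3) {
    d <- diff(aperm(vol, c(axis, setdiff(1:3, axis))))
    r <- stats::var(as.vector(d)) / (2 * v)
    r <- min(max(r, 1e-6), 0.9999)
    fw[axis] <- sqrt(-2 * log(2) / log(1 - r))
  }
  mean(fw)
}

#' Activated volume inside regions of interest
#'
#' @param map A `stat_map`.
#' @param rois Named list of logical masks on the map's grid.
#' @param forming_p Voxel-level threshold (default 0.001).
#' @return Data frame with per-ROI suprathreshold voxel counts and
#'   volumes in mm^3 (voxel count x voxel volume).
#' @export
roi_activation_volume <- function(map, rois, forming_p = 0.001) {
  stopifnot(inherits(map, "stat_map"))
  if (length(rois) == 0L || any(!vapply(rois, any, logical(1))))
    stop("each ROI mask must contain at least one voxel")
  vox_mm3 <- prod(if (all(is.na(map$voxel_size))) rep(3, 3) else map$voxel_size)
  supra <- logical(length(map$t))
  supra[suprathreshold_idx(map, forming_p)] <- TRUE
  data.frame(roi = names(rois),
             n_voxels = vapply(rois, function(m) sum(supra[as.vector(m)]), numeric(1)),
             volume_mm3 = vapply(rois, function(m) sum(supra[as.vector(m)]) * vox_mm3,
                                 numeric(1)),
             row.names = NULL)
}

#' Across-subject activation-volume table
#'
#' Tabulates [roi_activation_volume()] per subject and appends the
#' across-subject mean and SD per ROI -- the shape of a within-subject
#' regional activation summary.
#'
#' @param maps_by_subject List of `stat_map`s, one per subject.
#' @param rois Named list of logical masks.
#' @param forming_p Voxel-level threshold.
#' @return List with `per_subject` (long data frame) and `summary`
#'   (per-ROI mean and SD of volume in mm^3).
#' @export
activation_volume_table <- function(maps_by_subject, rois, forming_p = 0.001) {
  per <- do.call(rbind, lapply(seq_along(maps_by_subject), function(s) {
    v <- roi_activation_volume(maps_by_subject[[s]], rois, forming_p)
    v$subject <- s
    v
  }))
  agg <- do.call(rbind, lapply(split(per, per$roi), function(d) {
    data.frame(roi = d$roi[1L], mean_mm3 = mean(d$volume_mm3),
               sd_mm3 = stats::sd(d$volume_mm3))
  }))
  rownames(agg) <- NULL
  list(per_subject = per, summary = agg)
}
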