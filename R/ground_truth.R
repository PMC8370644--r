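#' Parameters of the spatial activation ground truth
#'
#' The simulated brain contains shared high-amplitude clusters recruited
#' by both wrist movements, plus small condition-unique clusters placed
#' closely adjacent to a shared-cluster boundary -- the spatial structure
#' that makes discriminating the two movements hard. Unique-cluster
#' centers sit `unique_offset` voxels beyond the shared boundary
#' (default 2, i.e. within two voxels of it), and unique clusters are
#' smaller than shared ones.
#'
#' @param grid_shape Voxel counts per axis (default 40 x 48 x 34 at 3 mm,
#'   a desk-scale stand-in for an 80 x 80 x 43 acquisition matrix).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param amp_common Percent-signal amplitude in shared clusters.
#' @param amp_unique_ext,amp_unique_flex Percent-signal amplitude in the
#'   extension-/flexion-unique clusters.
#' @param shared_centers Integer matrix (clusters x 3) of shared-cluster
#'   centers; defaults to two clusters in the grid interior.
#' @param shared_radius,unique_radius Sphere radii in voxels.
#' @param unique_offset Distance (voxels) from shared boundary to a
#'   unique-cluster center; must be <= 2 by default convention.
#' @param subject_jitter_sd Between-subject center jitter sd, voxels.
#' @return A `truth_params` object.
#' @export
truth_params <- function(grid_shape = c(40L, 48L, 34L), voxel_size = 3,
                         amp_common = 1, amp_unique_ext = 0.5,
                         amp_unique_flex = 0.5,
                         shared_centers = rbind(c(14, 24, 20), c(27, 24, 14)),
                         shared_radius = 3, unique_radius = 1.2,
                         unique_offset = 2, subject_jitter_sd = 1) {
  if (any(c(amp_common, amp_unique_ext, amp_unique_flex) < 0))
    stop("amplitudes must be non-negative")
  if (unique_radius > shared_radius)
    stop("unique clusters must not exceed shared clusters in size")
  shared_centers <- matrix(as.numeric(shared_centers), ncol = 3L)
  reach <- shared_radius + unique_offset + unique_radius
  if (any(shared_centers - reach < 1) ||
      any(sweep(shared_centers + reach, 2L, grid_shape) > 0))
    stop("cluster geometry does not fit inside the grid")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 amp_common = amp_common, amp_unique_ext = amp_unique_ext,
                 amp_unique_flex = amp_unique_flex,
                 shared_centers = shared_centers,
                 shared_radius = shared_radius, unique_radius = unique_radius,
                 unique_offset = unique_offset,
                 subject_jitter_sd = subject_jitter_sd),
            class = "truth_params")
}

sphere_mask <- function(dim, center, radius) {
  half <- ceiling(radius)
  xs <- max(1, floor(center[1] - half)):min(dim[1], ceiling(center[1] + half))
  ys <- max(1, floor(center[2] - half)):min(dim[2], ceiling(center[2] + half))
  zs <- max(1, floor(center[3] - half)):min(dim[3], ceiling(center[3] + half))
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  ijk_to_idx(as.matrix(g), dim)
}

box_mask <- function(dim, center, half) {
  m <- array(FALSE, dim)
  xs <- max(1, round(center[1] - half)):min(dim[1], round(center[1] + half))
  ys <- max(1, round(center[2] - half)):min(dim[2], round(center[2] + half))
  zs <- max(1, round(center[3] - half)):min(dim[3], round(center[3] + half))
  m[xs, ys, zs] <- TRUE
  m
}

#' Generate per-subject activation ground truth
#'
#' Each subject receives the template cluster geometry with every
#' cluster center displaced by a seeded normal jitter
#' (sd = `subject_jitter_sd` voxels, rounded to the lattice); centers
#' jittered outside the grid are clipped to it and flagged. Amplitude
#' maps are returned per condition, and a companion set of box ROI
#' masks (stand-ins for motor-area template regions: one box around
#' each shared cluster and one distal control box) is attached.
#'
#' @param params A [truth_params()].
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return List of `ground_truth` objects, one per subject, each with
#'   elements `amp_ext`, `amp_flex` (3-D percent-signal arrays),
#'   `clusters` (data frame of realized centers), `rois` (named list of
#'   logical arrays) and `params`.
#' @export
make_ground_truth <- function(params = truth_params(), n_subjects = 10L,
                              seed = 1L) {
  stopifnot(inherits(params, "truth_params"))
  set.seed(seed)
  dim <- params$grid_shape
  # template: unique-extension off shared cluster 1, unique-flexion off
  # shared cluster 2, both along +x just beyond the shared boundary
  off <- params$shared_radius + params$unique_offset
  template <- rbind(
    data.frame(type = "shared", condition = "both",
               x = params$shared_centers[, 1], y = params$shared_centers[, 2],
               z = params$shared_centers[, 3], radius = params$shared_radius),
    data.frame(type = "unique", condition = "extension",
               x = params$shared_centers[1, 1] + off,
               y = params$shared_centers[1, 2], z = params$shared_centers[1, 3],
               radius = params$unique_radius),
    data.frame(type = "unique", condition = "flexion",
               x = params$shared_centers[2, 1] + off,
               y = params$shared_centers[2, 2], z = params$shared_centers[2, 3],
               radius = params$unique_radius))
  margin <- params$shared_radius + params$unique_offset +
    params$unique_radius + 3
  rois <- list(
    M1 = box_mask(dim, params$shared_centers[1, ], margin),
    S1 = box_mask(dim, params$shared_centers[2, ], margin),
    PMd = box_mask(dim, round(c(dim[1] * 0.75, dim[2] * 0.17, dim[3] * 0.8)),
                   margin))
  lapply(seq_len(n_subjects), function(s) {
    cl <- template
    jit <- matrix(stats::rnorm(nrow(cl) * 3, 0, params$subject_jitter_sd),
                  ncol = 3)
    centers <- round(as.matrix(cl[, c("x", "y", "z")]) + jit)
    clipped <- centers < 1 | sweep(centers, 2L, dim) > 0
    centers <- pmin(pmax(centers, 1), matrix(dim, nrow(cl), 3, byrow = TRUE))
    cl[, c("x", "y", "z")] <- centers
    cl$clipped <- rowSums(clipped) > 0
    if (any(cl$clipped))
      message(sprintf("subject %d: %d cluster center(s) clipped to the grid",
                      s, sum(cl$clipped)))
    amp_ext <- array(0, dim); amp_flex <- array(0, dim)
    for (i in seq_len(nrow(cl))) {
      idx <- sphere_mask(dim, centers[i, ], cl$radius[i])
      if (cl$condition[i] %in% c("both", "extension")) {
        a <- if (cl$type[i] == "shared") params$amp_common else params$amp_unique_ext
        amp_ext[idx] <- pmax(amp_ext[idx], a)
      }
      if (cl$condition[i] %in% c("both", "flexion")) {
        a <- if (cl$type[i] == "shared") params$amp_common else params$amp_unique_flex
        amp_flex[idx] <- pmax(amp_flex[idx], a)
      }
    }
    structure(list(subject = s, amp_ext = amp_ext, amp_flex = amp_flex,
                   clusters = cl, rois = rois, params = params),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth, subject %d: %d cluster(s), %d ext / %d flex active voxel(s)\n",
              x$subject, nrow(x$clusters), sum(x$amp_ext > 0), sum(x$amp_flex > 0)))
  invisible(x)
}

#' Voxel sets of the realized clusters
#'
#' @param truth A `ground_truth` object.
#' @param which `"shared"`, `"unique_ext"` or `"unique_flex"`.
#' @return Integer vector of linear voxel indices.
#' @export
truth_cluster_voxels <- function(truth, which = c("shared", "unique_ext", "unique_flex")) {
  which <- match.arg(which)
  cl <- truth$clusters
  sel <- switch(which,
                shared = cl$type == "shared",
                unique_ext = cl$type == "unique" & cl$condition == "extension",
                unique_flex = cl$type == "unique" & cl$condition == "flexion")
  idx <- integer(0)
  for (i in which(sel))
    idx <- c(idx, sphere_mask(truth$params$grid_shape,
                              as.numeric(cl[i, c("x", "y", "z")]), cl$radius[i]))
  sort(unique(idx))
}
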