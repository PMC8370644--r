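sim_one <- function(seed = 1, n_runs = 1L, noise = quiet_noise(), ...) {
  truth <- make_ground_truth(small_truth_params(...), 1L, seed = 1)[[1L]]
  list(truth = truth,
       runs = simulate_subject(small_design(n_runs), truth, noise, seed = seed))
}

test_that("design matrix has the documented column structure", {
  ev <- make_design(design_spec(), seed = 1)[[1L]]
  X <- build_design_matrix(ev)
  k <- floor(2 * 116 * 3 / 128)
  expect_equal(ncol(X$X), 2 + k + 1)            # no motion, no spikes
  motion <- matrix(stats::rnorm(116 * 6, 0, 0.05), 116, 6)
  X2 <- build_design_matrix(ev, motion = motion)
  expect_equal(ncol(X2$X), 2 + 6 + k + 1)
  # spike columns are one-hot, one per flagged volume
  rep <- structure(list(flags = data.frame(volume = c(4L, 50L, 99L, 100L, 101L),
                                           reason = "global_z"),
                        n_volumes = 116L), class = "artifact_report")
  X3 <- build_design_matrix(ev, motion = motion, artifact_report = rep)
  expect_equal(ncol(X3$X), 2 + 6 + 5 + k + 1)
  spikes <- X3$X[, grepl("^spike", colnames(X3$X)), drop = FALSE]
  expect_equal(colSums(spikes), rep(1, 5), ignore_attr = TRUE)
  expect_equal(which(spikes[, 1L] == 1), 4L)
})

test_that("condition regressor for an isolated cue peaks 4-6 s after onset", {
  ev <- make_design(design_spec(), seed = 1)[[1L]]
  X <- build_design_matrix(ev)
  first_onset <- ev$onset[1L]
  reg <- X$X[, "extension"]
  # restrict to the first response before the next cue piles on
  w <- which(X$frame_times <= first_onset + 8)
  lag <- X$frame_times[w][which.max(reg[w])] - first_onset
  expect_gte(lag, 4 - 1.5); expect_lte(lag, 6 + 1.5)  # TR-3 sampling slack
})

test_that("exact linear data are recovered with zero residual variance", {
  ev <- make_design(design_spec(), seed = 2)[[1L]]
  X <- build_design_matrix(ev)$X
  set.seed(3)
  b <- matrix(stats::rnorm(ncol(X) * 5), ncol(X), 5)
  fit <- fit_glm(X %*% b, X)
  expect_equal(unname(fit$coef), unname(b), tolerance = 1e-8)
  expect_lt(max(fit$sigma2), 1e-16)
  expect_equal(fit$df, 116L - ncol(X))
})

test_that("white-noise residual variance is unbiased", {
  ev <- make_design(design_spec(), seed = 2)[[1L]]
  X <- build_design_matrix(ev)$X
  set.seed(4)
  y <- matrix(stats::rnorm(116 * 1000, 0, 2), 116, 1000)
  fit <- fit_glm(y, X)
  expect_equal(mean(fit$sigma2), 4, tolerance = 0.05)
})

test_that("t statistics match a brute-force OLS oracle to 1e-6", {
  ev <- make_design(design_spec(), seed = 5)[[1L]]
  X <- build_design_matrix(ev)$X
  set.seed(6)
  y <- matrix(stats::rnorm(116 * 200), 116, 200)
  fit <- fit_glm(y, X)
  tm <- contrast_tmap(fit, "ext>flex")
  cv <- numeric(ncol(X)); cv[1:2] <- c(1, -1)
  # independent oracle: solve(t(X) X) per voxel, textbook formulas
  xtxi <- solve(t(X) %*% X)
  for (v in c(1L, 7L, 50L, 123L, 200L)) {
    bhat <- xtxi %*% t(X) %*% y[, v]
    res <- y[, v] - X %*% bhat
    s2 <- sum(res^2) / (116 - ncol(X))
    t_ref <- (cv %*% bhat) / sqrt(s2 * t(cv) %*% xtxi %*% cv)
    expect_equal(tm$t[v], as.numeric(t_ref), tolerance = 1e-6)
  }
})

test_that("contrast antisymmetry and degenerate contrasts", {
  s <- sim_one(seed = 7)
  X <- build_design_matrix(s$runs[[1L]]$events, motion = s$runs[[1L]]$motion)
  fit <- fit_glm(s$runs[[1L]]$bold, X)
  t_ef <- contrast_tmap(fit, "ext>flex")
  t_fe <- contrast_tmap(fit, "flex>ext")
  expect_equal(as.vector(t_ef$t), -as.vector(t_fe$t))
  zero <- contrast_tmap(fit, numeric(length(fit$labels)))
  expect_true(all(zero$t == 0))
})

test_that("a spike regressor makes the fit invariant to that volume's data", {
  ev <- make_design(design_spec(), seed = 8)[[1L]]
  rep <- structure(list(flags = data.frame(volume = 30L, reason = "global_z"),
                        n_volumes = 116L), class = "artifact_report")
  X <- build_design_matrix(ev, artifact_report = rep)$X
  set.seed(9)
  y <- stats::rnorm(116)
  y2 <- y; y2[30L] <- y[30L] + 1000
  f1 <- fit_glm(matrix(y), X)
  f2 <- fit_glm(matrix(y2), X)
  keep <- !grepl("^spike", colnames(X))
  expect_equal(f1$coef[keep, 1L], f2$coef[keep, 1L], tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
})

test_that("singular designs are rejected naming the offending column", {
  ev <- make_design(design_spec(), seed = 1)[[1L]]
  X <- build_design_matrix(ev)$X
  X2 <- cbind(X, dup = X[, "extension"])
  expect_error(fit_glm(matrix(stats::rnorm(116)), X2), "dup|extension")
})

test_that("group t map follows Student t under the null and negates exactly", {
  set.seed(10)
  maps <- lapply(1:10, function(i) array(stats::rnorm(5000), c(50, 10, 10)))
  g <- group_ttest(maps)
  expect_equal(g$df, 9)
  ks <- suppressWarnings(stats::ks.test(as.vector(g$t), stats::pt, df = 9))
  expect_gt(ks$p.value, 0.01)
  flipped <- group_ttest(lapply(maps, function(m) -m))
  expect_equal(as.vector(flipped$t), -as.vector(g$t))
  # degenerate: identical maps -> zero variance guard
  same <- lapply(1:3, function(i) array(2, c(4, 4, 4)))
  gs <- group_ttest(same)
  expect_true(all(gs$t == 0))
  expect_length(attr(gs, "zero_variance"), 64L)
  expect_error(group_ttest(maps[1L]), "at least 2")
})

test_that("voxelwise type-I rate matches the forming threshold", {
  set.seed(11)
  maps <- lapply(1:10, function(i) stats::rnorm(20000))
  g <- group_ttest(maps)
  frac <- mean(g$t > stats::qt(0.999, 9))
  se <- sqrt(0.001 * 0.999 / 20000)
  expect_lt(abs(frac - 0.001), 4 * se)
})

test_that("cluster connectivity distinguishes corner from edge contact", {
  dim3 <- c(5L, 5L, 5L)
  # voxels touching only at a corner: 26-neighbours but not 18-neighbours
  a <- ijk_to_idx_test <- function(ijk) (ijk[3] - 1) * 25 + (ijk[2] - 1) * 5 + ijk[1]
  corner <- c(a(c(2, 2, 2)), a(c(3, 3, 3)))
  expect_equal(max(label_clusters(corner, dim3, 18L)), 2L)
  expect_equal(max(label_clusters(corner, dim3, 26L)), 1L)
  edge <- c(a(c(2, 2, 2)), a(c(3, 3, 2)))                 # share an edge
  expect_equal(max(label_clusters(edge, dim3, 18L)), 1L)
  expect_equal(max(label_clusters(edge, dim3, 6L)), 2L)
})

test_that("cluster extents are reported in mm^3 (26 voxels -> 702)", {
  # a bar of 26 suprathreshold voxels at 3 mm isotropic
  dims <- c(40L, 8L, 8L)
  t_map <- array(0, dims)
  t_map[3:28, 4, 4] <- 10
  map <- structure(list(t = t_map, df = 9, contrast = "ext>rest",
                        alternative = "greater", voxel_size = rep(3, 3),
                        dim = dims), class = "stat_map")
  set.seed(1)
  null_subjects <- lapply(1:10, function(i) array(stats::rnorm(prod(dims)), dims))
  cr <- cluster_threshold(map, subject_maps = NULL, n_perm = 200, seed = 1,
                          smoothness_fwhm_vox = 1.5)
  expect_equal(cr$clusters$n_voxels, 26L)
  expect_equal(cr$clusters$extent_mm3, 26 * 27)            # 702 mm^3
})

test_that("ROI activation volumes count suprathreshold voxels times 27 mm^3", {
  dims <- c(10L, 10L, 10L)
  t_map <- array(0, dims)
  t_map[1:10] <- 10                                        # 10 hot voxels
  map <- structure(list(t = t_map, df = 20, contrast = "ext>rest",
                        alternative = "greater", voxel_size = rep(3, 3),
                        dim = dims), class = "stat_map")
  roi_all <- array(TRUE, dims)
  roi_cold <- array(FALSE, dims); roi_cold[500:600] <- TRUE
  v <- roi_activation_volume(map, list(all = roi_all, cold = roi_cold))
  expect_equal(v$volume_mm3[v$roi == "all"], 270)
  expect_equal(v$volume_mm3[v$roi == "cold"], 0)
  expect_error(roi_activation_volume(map, list(empty = array(FALSE, dims))),
               "at least one voxel")
})

test_that("high-SNR recovery: unique-extension ROI activates for extension only", {
  s <- sim_one(seed = 12, n_runs = 2L, noise = quiet_noise(white_sd = 5),
               amp_unique_ext = 2, amp_unique_flex = 2, subject_jitter_sd = 0)
  ys <- lapply(s$runs, function(r) bold_matrix(r$bold))
  xs <- lapply(s$runs, function(r) build_design_matrix(r$events)$X)
  X <- wristbold:::block_design(xs)
  fit <- fit_glm(do.call(rbind, ys), X)
  fit$geom <- list(dim = dim(s$truth$amp_ext), voxel_size = rep(3, 3))
  cv_e <- wristbold:::contrast_named(colnames(X), "ext>rest")
  cv_f <- wristbold:::contrast_named(colnames(X), "flex>rest")
  t_e <- contrast_tmap(fit, cv_e); t_e$alternative <- "greater"
  t_f <- contrast_tmap(fit, cv_f); t_f$alternative <- "greater"
  ue <- truth_cluster_voxels(s$truth, "unique_ext")
  roi <- array(FALSE, dim(s$truth$amp_ext)); roi[ue] <- TRUE
  v_e <- roi_activation_volume(t_e, list(ue = roi))$volume_mm3
  v_f <- roi_activation_volume(t_f, list(ue = roi))$volume_mm3
  expect_gt(v_e, 0)
  expect_equal(v_f, 0)
})
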